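# Chromatin-profile sequence model.
#
# A small convolutional network mapping one-hot DNA windows of length L to
# per-profile peak probabilities at the window center.  Architecture, in
# three sections: (1) stages of dual linear/nonlinear convolution blocks
# with mean-pooling; (2) residual dilated convolutions at the pooled
# resolution; (3) a B-spline spatial basis transform followed by fully
# connected and sigmoid output layers.  Implemented directly on BLAS
# matrix operations (no deep-learning framework is assumed); convolutions
# are expressed as sums of shifted matrix products.

#' Cubic B-spline spatial basis
#'
#' Normalized (partition-of-unity) cubic B-spline basis evaluated at the
#' midpoints of `n_bins` uniformly spaced bins on `[0, 1]`, with `df`
#' basis functions (clamped uniform knots).  Each row sums to 1.
#'
#' @param n_bins number of spatial bins (rows).
#' @param df degrees of freedom (columns); cubic, so `df >= 4`.
#' @return `n_bins x df` matrix.
#' @export
spline_basis <- function(n_bins, df) {
  if (df < 4) stop("df must be >= 4 (cubic splines)")
  if (df > n_bins) stop("df must not exceed n_bins")
  x <- (seq_len(n_bins) - 0.5) / n_bins
  n_interior <- df - 4L
  interior <- if (n_interior > 0)
    seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric(0)
  knots <- c(rep(0, 4), interior, rep(1, 4))
  B <- splines::splineDesign(knots, x, ord = 4L)
  B / rowSums(B)  # exact partition of unity up to fp error
}

#' Model configuration
#'
#' @param L input sequence length (bp, even).
#' @param n_targets number of chromatin profiles `T`.
#' @param channels convolutional channel width `C`.
#' @param kernel convolution kernel width (odd).
#' @param pool per-stage pooling factors; one dual-path block precedes
#'   each pooling step, so `length(pool)` is the number of dual blocks and
#'   `L / prod(pool)` the number of spatial bins `B`.
#' @param pool_type `"max"` (default; sharp credit assignment for motif
#'   detection) or `"mean"`.
#' @param dropout training-time channel-dropout probability applied after
#'   each pooled stage and dilated block (0 disables).
#' @param dilations dilation factors of the residual dilated blocks.
#' @param spline_df B-spline degrees of freedom (`<= B`).
#' @param hidden width of the fully connected layer.
#' @param init_seed RNG seed for weight initialization.
#' @return an object of class `chrom_config`.
#' @export
chrom_config <- function(L = 4096L, n_targets, channels = 64L, kernel = 9L,
                         pool = c(4L, 4L), dilations = c(2L, 4L),
                         spline_df = 16L, hidden = 256L,
                         pool_type = c("max", "mean"), dropout = 0,
                         init_seed = 1L) {
  pool_type <- match.arg(pool_type)
  stopifnot(dropout >= 0, dropout < 1)
  if (L %% 2L != 0L) stop("L must be even")
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  B <- L / prod(pool)
  if (B != as.integer(B))
    stop("L must be divisible by prod(pool); got L=", L,
         " pool=", paste(pool, collapse = "x"))
  B <- as.integer(B)
  if (spline_df > B)
    stop("spline_df (", spline_df, ") must not exceed the number of ",
         "spatial bins B=", B)
  structure(list(L = as.integer(L), n_targets = as.integer(n_targets),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = as.integer(pool), dilations = as.integer(dilations),
                 n_bins = B, spline_df = as.integer(spline_df),
                 hidden = as.integer(hidden), pool_type = pool_type,
                 dropout = dropout,
                 init_seed = as.integer(init_seed)),
            class = "chrom_config")
}

#' Miniature configuration used in tests and desk-scale runs
#'
#' @param n_targets number of profiles.
#' @param init_seed weight-initialization seed.
#' @return a [chrom_config()].
#' @export
chrom_config_miniature <- function(n_targets, dropout = 0,
                                   init_seed = 1L) {
  chrom_config(L = 512L, n_targets = n_targets, channels = 16L, kernel = 9L,
               pool = c(4L, 4L), dilations = c(2L, 4L), spline_df = 16L,
               hidden = 64L, dropout = dropout, init_seed = init_seed)
}

# He-scaled gaussian init for a (k, Cin, Cout) conv kernel
.init_conv <- function(k, cin, cout, scale = 1) {
  array(rnorm(k * cin * cout, sd = scale * sqrt(2 / (k * cin))),
        dim = c(k, cin, cout))
}

#' Build an untrained model from a configuration
#'
#' @param config a [chrom_config()].
#' @param profile_meta optional data.frame of per-profile metadata
#'   (`profile_id`, `assay_class`, ...) carried along for downstream use
#'   (e.g. the histone mask).
#' @return an object of class `chrom_model`.
#' @export
build_model <- function(config, profile_meta = NULL) {
  stopifnot(inherits(config, "chrom_config"))
  if (!is.null(profile_meta) && nrow(profile_meta) != config$n_targets)
    stop("profile_meta rows (", nrow(profile_meta),
         ") must equal n_targets (", config$n_targets, ")")
  set.seed(config$init_seed)
  C <- config$channels; k <- config$kernel
  p <- list()
  cin <- 4L
  for (s in seq_along(config$pool)) {
    # linear path has no activation: unit gain; nonlinear path: He gain
    p[[paste0("Wl", s)]] <- .init_conv(k, cin, C, scale = sqrt(0.5))
    p[[paste0("bl", s)]] <- numeric(C)
    p[[paste0("Wn", s)]] <- .init_conv(k, C, C)
    p[[paste0("bn", s)]] <- numeric(C)
    p[[paste0("gn", s)]] <- rep(1, C)   # batch-norm scale (nonlinear path)
    p[[paste0("hn", s)]] <- numeric(C)  # batch-norm shift
    cin <- C
  }
  for (d in seq_along(config$dilations)) {
    p[[paste0("Wd", d)]] <- .init_conv(k, C, C, scale = 0.5)
    p[[paste0("bd", d)]] <- numeric(C)
    p[[paste0("gd", d)]] <- rep(1, C)
    p[[paste0("hd", d)]] <- numeric(C)
  }
  Fdim <- C * config$spline_df
  p$W1 <- matrix(rnorm(Fdim * config$hidden, sd = sqrt(1 / Fdim)),
                 Fdim, config$hidden)
  p$b1 <- numeric(config$hidden)
  # small output layer keeps initial logits near zero (no saturated
  # sigmoids at the start of training)
  p$W2 <- matrix(rnorm(config$hidden * config$n_targets, sd = 0.01),
                 config$hidden, config$n_targets)
  p$b2 <- numeric(config$n_targets)
  C <- config$channels
  bn_stats <- list()
  for (s in seq_along(config$pool))
    bn_stats[[paste0("n", s)]] <- list(mu = numeric(C), var = rep(1, C),
                                       n = 0)
  for (d in seq_along(config$dilations))
    bn_stats[[paste0("d", d)]] <- list(mu = numeric(C), var = rep(1, C),
                                       n = 0)
  structure(list(config = config, params = p,
                 basis = spline_basis(config$n_bins, config$spline_df),
                 bn_stats = bn_stats, profile_meta = profile_meta),
            class = "chrom_model")
}

#' @export
print.chrom_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("chrom_model: L=%d -> %d targets | C=%d, %d dual ",
                     "block(s), dilations [%s], B=%d bins, spline df=%d\n"),
              cfg$L, cfg$n_targets, cfg$channels, length(cfg$pool),
              paste(cfg$dilations, collapse = ","), cfg$n_bins,
              cfg$spline_df))
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total trainable parameter count
#' @param model a `chrom_model`.
#' @return integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- convolution primitives -------------------------------------------------
# X is a (n*L x Cin) matrix, samples stacked row-wise.

.conv_rows <- function(n, L, pad) {
  # row indices of the unpadded positions inside the padded layout
  rep((seq_len(n) - 1L) * (L + 2L * pad), each = L) + pad +
    rep.int(seq_len(L), n)
}

.conv_fwd <- function(X, W, b, dil, n, L) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  pad <- dil * (k - 1L) %/% 2L
  Xp <- matrix(0, n * (L + 2L * pad), cin)
  rows0 <- .conv_rows(n, L, pad)
  Xp[rows0, ] <- X
  Y <- matrix(0, n * L, cout)
  base <- rows0 - pad
  for (j in seq_len(k))
    Y <- Y + Xp[base + (j - 1L) * dil, , drop = FALSE] %*% W[j, , ]
  Y <- Y + matrix(b, nrow(Y), cout, byrow = TRUE)
  list(Y = Y, Xp = Xp, base = base, pad = pad)
}

.conv_bwd <- function(dY, cache, W, dil, n, L) {
  k <- dim(W)[1]; cin <- dim(W)[2]
  dW <- array(0, dim(W)); db <- colSums(dY)
  dXp <- matrix(0, nrow(cache$Xp), cin)
  for (j in seq_len(k)) {
    rows <- cache$base + (j - 1L) * dil
    dW[j, , ] <- crossprod(cache$Xp[rows, , drop = FALSE], dY)
    dXp[rows, ] <- dXp[rows, ] + dY %*% t(W[j, , ])
  }
  rows0 <- cache$base + cache$pad
  list(dX = dXp[rows0, , drop = FALSE], dW = dW, db = db)
}

.pool_fwd <- function(X, f, n, L, type = "mean") {
  Lp <- L %/% f
  grp <- rep((seq_len(n) - 1L) * Lp, each = L) +
    rep.int(rep(seq_len(Lp), each = f), n)
  if (type == "mean")
    return(list(Y = rowsum(X, grp, reorder = FALSE) / f, grp = grp,
                type = type))
  ng <- n * Lp
  C <- ncol(X)
  Y <- matrix(0, ng, C)
  amax <- matrix(0L, ng, C)  # winning row index into X, per group/channel
  for (c in seq_len(C)) {
    M <- matrix(X[, c], nrow = f)           # f x ng (groups are contiguous)
    win <- max.col(t(M), ties.method = "first")
    Y[, c] <- M[cbind(win, seq_len(ng))]
    amax[, c] <- (seq_len(ng) - 1L) * f + win
  }
  list(Y = Y, grp = grp, amax = amax, type = type)
}

.pool_bwd <- function(dY, cache, f) {
  if (cache$type == "mean")
    return(dY[cache$grp, , drop = FALSE] / f)
  dX <- matrix(0, length(cache$grp), ncol(dY))
  for (c in seq_len(ncol(dY)))
    dX[cache$amax[, c], c] <- dY[, c]
  dX
}

.relu <- function(x) x * (x > 0)

# batch normalization over rows (positions x samples), per channel
.bn_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2L, mu)
  v <- colMeans(xc^2)
  sdv <- sqrt(v + eps)
  xhat <- sweep(xc, 2L, sdv, "/")
  Y <- sweep(xhat, 2L, gamma, "*")
  Y <- sweep(Y, 2L, beta, "+")
  list(Y = Y, xhat = xhat, sd = sdv, mu = mu, var = v)
}

.bn_fwd_eval <- function(X, gamma, beta, rmu, rvar, eps = 1e-5) {
  xhat <- sweep(sweep(X, 2L, rmu), 2L, sqrt(rvar + eps), "/")
  sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
}

.bn_bwd <- function(dY, cache, gamma) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  # dX = gamma/sd * (dY - mean(dY) - xhat * mean(dY*xhat))
  dX <- sweep(dY, 2L, dbeta / m)
  dX <- dX - sweep(cache$xhat, 2L, dgamma / m, "*")
  dX <- sweep(dX, 2L, gamma / cache$sd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward -----------------------------------------------------

# forward pass; if want_cache, retains intermediates for backprop
.forward <- function(model, X, n, want_cache = FALSE, training = FALSE) {
  cfg <- model$config; p <- model$params
  L <- cfg$L
  cache <- list()
  H <- X
  for (s in seq_along(cfg$pool)) {
    cl <- .conv_fwd(H, p[[paste0("Wl", s)]], p[[paste0("bl", s)]], 1L, n, L)
    cn <- .conv_fwd(cl$Y, p[[paste0("Wn", s)]], p[[paste0("bn", s)]], 1L, n, L)
    if (training) {
      bn <- .bn_fwd(cn$Y, p[[paste0("gn", s)]], p[[paste0("hn", s)]])
    } else {
      st <- model$bn_stats[[paste0("n", s)]]
      bn <- list(Y = .bn_fwd_eval(cn$Y, p[[paste0("gn", s)]],
                                  p[[paste0("hn", s)]], st$mu, st$var))
    }
    out <- .relu(bn$Y) + cl$Y
    pl <- .pool_fwd(out, cfg$pool[s], n, L, cfg$pool_type)
    H <- pl$Y
    L <- L %/% cfg$pool[s]
    dmask <- NULL
    if (training && isTRUE(cfg$dropout > 0)) {
      keep <- matrix(runif(n * ncol(H)) >= cfg$dropout, n, ncol(H))
      dmask <- keep[rep(seq_len(n), each = L), , drop = FALSE] /
        (1 - cfg$dropout)
      H <- H * dmask
    }
    if (want_cache)
      cache[[paste0("stage", s)]] <- list(cl = cl, cn = cn, bn = bn,
                                          L = L * cfg$pool[s], pool = pl,
                                          dmask = dmask)
  }
  for (d in seq_along(cfg$dilations)) {
    cd <- .conv_fwd(H, p[[paste0("Wd", d)]], p[[paste0("bd", d)]],
                    cfg$dilations[d], n, L)
    if (training) {
      bn <- .bn_fwd(cd$Y, p[[paste0("gd", d)]], p[[paste0("hd", d)]])
    } else {
      st <- model$bn_stats[[paste0("d", d)]]
      bn <- list(Y = .bn_fwd_eval(cd$Y, p[[paste0("gd", d)]],
                                  p[[paste0("hd", d)]], st$mu, st$var))
    }
    H <- H + .relu(bn$Y)
    dmask <- NULL
    if (training && isTRUE(cfg$dropout > 0)) {
      keep <- matrix(runif(n * ncol(H)) >= cfg$dropout, n, ncol(H))
      dmask <- keep[rep(seq_len(n), each = L), , drop = FALSE] /
        (1 - cfg$dropout)
      H <- H * dmask
    }
    if (want_cache) cache[[paste0("dil", d)]] <- list(cd = cd, bn = bn,
                                                      L = L, dmask = dmask)
  }
  # spline transform: H (n*B x C) -> Z (n x df*C)
  B <- cfg$n_bins; C <- cfg$channels; df <- cfg$spline_df
  M <- matrix(aperm(array(H, c(B, n, C)), c(1, 3, 2)), B, C * n)
  Z0 <- crossprod(model$basis, M)                 # df x (C*n)
  Z <- t(matrix(array(Z0, c(df, C, n)), df * C, n))
  A1 <- Z %*% p$W1 + matrix(p$b1, n, cfg$hidden, byrow = TRUE)
  R1 <- .relu(A1)
  logits <- R1 %*% p$W2 + matrix(p$b2, n, cfg$n_targets, byrow = TRUE)
  P <- 1 / (1 + exp(-logits))
  if (want_cache) {
    cache$H_final <- H; cache$Z <- Z; cache$A1 <- A1; cache$R1 <- R1
  }
  list(P = P, cache = cache)
}

# mean binary cross-entropy and gradient wrt logits
.bce <- function(P, Y) {
  eps <- 1e-9
  -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}

# full backward pass; returns gradients named like params
.backward <- function(model, X, Y, fw, n) {
  cfg <- model$config; p <- model$params
  P <- fw$P; cache <- fw$cache
  grads <- list()
  dlogits <- (P - Y) / (n * cfg$n_targets)
  grads$W2 <- crossprod(cache$R1, dlogits)
  grads$b2 <- colSums(dlogits)
  dR1 <- dlogits %*% t(p$W2)
  dA1 <- dR1 * (cache$A1 > 0)
  grads$W1 <- crossprod(cache$Z, dA1)
  grads$b1 <- colSums(dA1)
  dZ <- dA1 %*% t(p$W1)
  # spline backward
  B <- cfg$n_bins; C <- cfg$channels; df <- cfg$spline_df
  dZ0 <- matrix(array(t(dZ), c(df, C, n)), df, C * n)
  dM <- model$basis %*% dZ0                       # B x (C*n)
  dH <- matrix(aperm(array(dM, c(B, C, n)), c(1, 3, 2)), n * B, C)
  for (d in rev(seq_along(cfg$dilations))) {
    cc <- cache[[paste0("dil", d)]]
    if (!is.null(cc$dmask)) dH <- dH * cc$dmask
    dbnY <- dH * (cc$bn$Y > 0)
    bb <- .bn_bwd(dbnY, cc$bn, p[[paste0("gd", d)]])
    grads[[paste0("gd", d)]] <- bb$dgamma
    grads[[paste0("hd", d)]] <- bb$dbeta
    bk <- .conv_bwd(bb$dX, cc$cd, p[[paste0("Wd", d)]], cfg$dilations[d],
                    n, cc$L)
    grads[[paste0("Wd", d)]] <- bk$dW
    grads[[paste0("bd", d)]] <- bk$db
    dH <- dH + bk$dX
  }
  for (s in rev(seq_along(cfg$pool))) {
    cc <- cache[[paste0("stage", s)]]
    if (!is.null(cc$dmask)) dH <- dH * cc$dmask
    dout <- .pool_bwd(dH, cc$pool, cfg$pool[s])
    dbnY <- dout * (cc$bn$Y > 0)
    bb <- .bn_bwd(dbnY, cc$bn, p[[paste0("gn", s)]])
    grads[[paste0("gn", s)]] <- bb$dgamma
    grads[[paste0("hn", s)]] <- bb$dbeta
    bkn <- .conv_bwd(bb$dX, cc$cn, p[[paste0("Wn", s)]], 1L, n, cc$L)
    grads[[paste0("Wn", s)]] <- bkn$dW
    grads[[paste0("bn", s)]] <- bkn$db
    dlin <- dout + bkn$dX
    bkl <- .conv_bwd(dlin, cc$cl, p[[paste0("Wl", s)]], 1L, n, cc$L)
    grads[[paste0("Wl", s)]] <- bkl$dW
    grads[[paste0("bl", s)]] <- bkl$db
    dH <- bkl$dX
  }
  grads
}

#' Apply one dual linear/nonlinear block (reference semantics)
#'
#' `output = relu(conv_n(conv_l(x))) + conv_l(x)`: the linear convolution
#' has no activation, the nonlinear path adds a rectified convolution on
#' top of it via a residual connection.  Exposed for testing and
#' inspection; the training path uses the same primitives.
#'
#' @param X `(n*L x Cin)` input feature map.
#' @param Wl,bl linear-path kernel `(k, Cin, C)` and bias.
#' @param Wn,bn nonlinear-path kernel `(k, C, C)` and bias.
#' @param n,L batch layout.
#' @return `(n*L x C)` output feature map.
#' @export
dual_path_block <- function(X, Wl, bl, Wn, bn, n, L) {
  if (ncol(X) != dim(Wl)[2])
    stop("channel mismatch: input has ", ncol(X), " channels, kernel expects ",
         dim(Wl)[2])
  lin <- .conv_fwd(X, Wl, bl, 1L, n, L)$Y
  nl <- .relu(.conv_fwd(lin, Wn, bn, 1L, n, L)$Y)
  nl + lin
}

# ---- prediction -------------------------------------------------------------

#' Predict chromatin-profile probabilities for sequences
#'
#' @param object a `chrom_model`.
#' @param seqs character vector of sequences, each of length `L`.
#' @param batch_size sequences per forward pass.
#' @param ... unused.
#' @return `length(seqs) x n_targets` matrix of probabilities in `(0, 1)`;
#'   columns named by `profile_meta$profile_id` when available.
#' @export
predict.chrom_model <- function(object, seqs, batch_size = 64L, ...) {
  cfg <- object$config
  bad <- which(nchar(seqs) != cfg$L)
  if (length(bad))
    stop("sequence ", bad[1L], " has length ", nchar(seqs)[bad[1L]],
         ", expected L=", cfg$L)
  out <- matrix(NA_real_, length(seqs), cfg$n_targets)
  i <- 1L
  while (i <= length(seqs)) {
    j <- min(i + batch_size - 1L, length(seqs))
    X <- one_hot(seqs[i:j])
    out[i:j, ] <- .forward(object, X, j - i + 1L)$P
    i <- j + 1L
  }
  if (!is.null(object$profile_meta))
    colnames(out) <- object$profile_meta$profile_id
  out
}

# ---- labels -----------------------------------------------------------------

#' Binary center-bp labels for windows against a profile compendium
#'
#' `label[w, t] = 1` iff the center base of window `w` lies inside some
#' peak of profile `t`.
#'
#' @param windows a `WindowSet` from [tile_genome()] (or any data.frame
#'   with `contig`, `start`, `end`).
#' @param profiles a `ProfileCompendium`.
#' @return `n x T` binary matrix with profile ids as column names.
#' @export
make_labels <- function(windows, profiles) {
  ctr <- windows$start + (windows$end - windows$start) %/% 2L
  n <- nrow(windows)
  ids <- names(profiles$peaks)
  lab <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  ir_all <- lapply(profiles$peaks, .iranges_by_contig)
  for (t in seq_along(ids)) {
    ir <- ir_all[[t]]
    for (cn in unique(windows$contig)) {
      w <- windows$contig == cn
      lab[w, t] <- as.integer(.pos_in_intervals(ir, cn, ctr[w]))
    }
  }
  lab
}

# labels for sampled center positions (0-based), by contig
.labels_at <- function(contig, centers, ir_all, ids) {
  lab <- matrix(0L, length(centers), length(ids),
                dimnames = list(NULL, ids))
  for (t in seq_along(ids)) {
    for (cn in unique(contig)) {
      w <- contig == cn
      lab[w, t] <- as.integer(.pos_in_intervals(ir_all[[t]], cn, centers[w]))
    }
  }
  lab
}

# ---- training ---------------------------------------------------------------

#' Train the sequence model with on-the-fly uniform sampling
#'
#' Each step draws a fresh batch of window centers uniformly from the
#' training contigs (excluding `blacklist` overlaps and windows containing
#' `N`), builds center-bp labels from the compendium, and takes one SGD
#' step (momentum, mean binary cross-entropy over targets).  Validation
#' loss is tracked on a fixed window sample from the validation contig(s);
#' the best-validation parameters are restored at the end.
#'
#' @param model a `chrom_model` from [build_model()].
#' @param genome a [GenomeSequence].
#' @param compendium a `ProfileCompendium`; column order defines targets.
#' @param holdout list with `test` and `validation` contig-name vectors;
#'   training uses all remaining contigs.
#' @param steps number of optimization steps.
#' @param batch_size sequences per step.
#' @param optimizer `"adam"` (default; adaptive moments, robust at desk
#'   scale) or `"sgd"` (momentum).
#' @param lr,momentum learning rate and SGD momentum; `lr` decays by
#'   `lr_decay` at each milestone in `lr_milestones` (fractions of
#'   `steps`).  Default lr: 0.002 for adam, 0.03 for sgd.
#' @param lr_decay,lr_milestones step-decay schedule.
#' @param clip global gradient-norm clipping threshold (`Inf` to disable).
#' @param weight_decay decoupled L2 penalty applied with the update
#'   (AdamW-style); discourages memorization of small training genomes.
#' @param blacklist optional [IntervalSet] excluded from sampling.
#' @param seed sampler RNG seed.
#' @param n_val number of validation windows.
#' @param eval_every validation cadence (steps).
#' @param shuffle_labels if `TRUE`, labels are permuted across the batch
#'   (negative control).
#' @param augment_rc if `TRUE`, half of each batch is reverse-complemented
#'   (off by default).
#' @param verbose print progress.
#' @return the trained `chrom_model` with a `history` data.frame attached
#'   (`step`, `train_loss`, `val_loss`).
#' @export
train_chromnet <- function(model, genome, compendium,
                           holdout = list(test = character(),
                                          validation = character()),
                           steps = 300L, batch_size = 32L,
                           optimizer = c("adam", "sgd"), lr = NULL,
                           momentum = 0.9, lr_decay = 0.3,
                           lr_milestones = c(0.6, 0.85), clip = 5,
                           weight_decay = 0, blacklist = NULL, seed = 1L, n_val = 256L,
                           eval_every = 25L, shuffle_labels = FALSE,
                           augment_rc = FALSE, verbose = FALSE) {
  cfg <- model$config
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 0.002 else 0.03
  train_ctgs <- setdiff(names(genome$contigs),
                        c(holdout$test, holdout$validation))
  miss <- setdiff(c(holdout$test, holdout$validation), names(genome$contigs))
  if (length(miss)) stop("holdout contig(s) not in genome: ",
                         paste(miss, collapse = ", "))
  if (!length(train_ctgs)) stop("no training contigs left")
  ids <- names(compendium$peaks)
  if (length(ids) != cfg$n_targets)
    stop("compendium has ", length(ids), " profiles, model expects ",
         cfg$n_targets)
  ir_all <- lapply(compendium$peaks, .iranges_by_contig)
  half <- cfg$L %/% 2L
  sample_centers <- function(ctgs, n) {
    lens <- genome$lengths[ctgs] - cfg$L
    lens <- lens[lens >= 0]
    if (!length(lens)) stop("no contig can host an L-bp window")
    cn <- sample(names(lens), n, replace = TRUE,
                 prob = as.numeric(lens + 1) / sum(lens + 1))
    ctr <- vapply(cn, function(x)
      sample.int(genome$lengths[[x]] - cfg$L + 1L, 1L) - 1L + half,
      integer(1))
    keep <- rep(TRUE, n)
    if (!is.null(blacklist) && nrow(blacklist)) {
      ir_bl <- .iranges_by_contig(blacklist)
      for (x in unique(cn)) {
        w <- cn == x
        ir <- ir_bl[[x]]
        if (!is.null(ir)) {
          q <- IRanges::IRanges(start = ctr[w] - half + 1L,
                                end = ctr[w] + half)
          keep[w] <- keep[w] & !IRanges::overlapsAny(q, ir)
        }
      }
    }
    list(contig = cn[keep], center = ctr[keep])
  }
  fetch_seqs <- function(contig, center) {
    vapply(seq_along(center), function(i)
      get_seq(genome, contig[i], center[i] - half, center[i] + half),
      character(1))
  }
  # sanity: any positives at all on training contigs?
  probe <- sample_centers(train_ctgs, 512L)
  probe_lab <- .labels_at(probe$contig, probe$center, ir_all, ids)
  if (sum(probe_lab) == 0)
    stop("no positive labels found on training contigs; check the compendium")
  set.seed(seed)
  val <- NULL
  if (length(holdout$validation)) {
    vs <- sample_centers(holdout$validation, n_val)
    val <- list(X = one_hot(fetch_seqs(vs$contig, vs$center)),
                Y = .labels_at(vs$contig, vs$center, ir_all, ids),
                n = length(vs$center))
  }
  zeros <- lapply(model$params, function(w)
    array(0, dim = if (is.null(dim(w))) length(w) else dim(w)))
  vel <- zeros; m1 <- zeros; m2 <- zeros
  adam_b1 <- 0.9; adam_b2 <- 0.999; adam_eps <- 1e-8
  history <- list()
  best <- list(loss = Inf, params = model$params)
  cur_lr <- lr
  miles <- ceiling(lr_milestones * steps)
  rc <- function(s) chartr("ACGT", "TGCA",
                           vapply(strsplit(s, NULL),
                                  function(x) paste(rev(x), collapse = ""),
                                  character(1)))
  for (step in seq_len(steps)) {
    if (step %in% miles) cur_lr <- cur_lr * lr_decay
    b <- sample_centers(train_ctgs, batch_size)
    n <- length(b$center)
    seqs <- fetch_seqs(b$contig, b$center)
    if (augment_rc) {
      flip <- runif(n) < 0.5
      if (any(flip)) seqs[flip] <- rc(seqs[flip])
    }
    X <- one_hot(seqs)
    Y <- .labels_at(b$contig, b$center, ir_all, ids)
    if (shuffle_labels) Y <- Y[sample.int(n), , drop = FALSE]
    fw <- .forward(model, X, n, want_cache = TRUE, training = TRUE)
    loss <- .bce(fw$P, Y)
    # running batch-norm statistics (momentum 0.9)
    for (s in seq_along(cfg$pool)) {
      bnc <- fw$cache[[paste0("stage", s)]]$bn
      st <- model$bn_stats[[paste0("n", s)]]
      model$bn_stats[[paste0("n", s)]] <-
        list(mu = 0.9 * st$mu + 0.1 * bnc$mu,
             var = 0.9 * st$var + 0.1 * bnc$var, n = st$n + 1)
    }
    for (d in seq_along(cfg$dilations)) {
      bnc <- fw$cache[[paste0("dil", d)]]$bn
      st <- model$bn_stats[[paste0("d", d)]]
      model$bn_stats[[paste0("d", d)]] <-
        list(mu = 0.9 * st$mu + 0.1 * bnc$mu,
             var = 0.9 * st$var + 0.1 * bnc$var, n = st$n + 1)
    }
    grads <- .backward(model, X, Y, fw, n)
    if (is.finite(clip)) {
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(gnorm) && gnorm > clip)
        grads <- lapply(grads, function(g) g * (clip / gnorm))
    }
    if (optimizer == "adam") {
      for (nm in names(grads)) {
        m1[[nm]] <- adam_b1 * m1[[nm]] + (1 - adam_b1) * grads[[nm]]
        m2[[nm]] <- adam_b2 * m2[[nm]] + (1 - adam_b2) * grads[[nm]]^2
        mhat <- m1[[nm]] / (1 - adam_b1^step)
        vhat <- m2[[nm]] / (1 - adam_b2^step)
        model$params[[nm]] <- model$params[[nm]] -
          cur_lr * (mhat / (sqrt(vhat) + adam_eps) +
                      weight_decay * model$params[[nm]])
      }
    } else {
      for (nm in names(grads)) {
        vel[[nm]] <- momentum * vel[[nm]] + grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] -
          cur_lr * (vel[[nm]] + weight_decay * model$params[[nm]])
      }
    }
    if (step %% eval_every == 0L || step == steps) {
      vloss <- NA_real_
      if (!is.null(val)) {
        vloss <- .bce(.forward(model, val$X, val$n)$P, val$Y)
        if (is.finite(vloss) && vloss < best$loss)
          best <- list(loss = vloss, params = model$params,
                       bn = model$bn_stats)
      }
      history[[length(history) + 1L]] <-
        data.frame(step = step, train_loss = loss, val_loss = vloss)
      if (verbose)
        message(sprintf("step %d: train %.4f val %.4f", step, loss, vloss))
    }
  }
  if (!is.null(val) && is.finite(best$loss)) {
    model$params <- best$params
    model$bn_stats <- best$bn
  }
  model$history <- do.call(rbind, history)
  model
}

# ---- evaluation -------------------------------------------------------------

#' AUROC by the rank statistic (midrank tie convention)
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUROC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUPRC by precision-recall step integration (average precision)
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return average precision, or `NA` if there are no positives.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / n1
}

#' Per-profile AUROC/AUPRC with the small-positive-count exclusion
#'
#' Profiles with fewer than `min_pos` positives (or with no negatives) are
#' excluded from the reported averages.
#'
#' @param predictions `n x T` probability matrix.
#' @param labels `n x T` binary matrix.
#' @param min_pos minimum positive count for inclusion (default 25).
#' @return data.frame (`profile`, `n_pos`, `auroc`, `auprc`, `included`)
#'   with attributes `mean_auroc` and `mean_auprc` over included profiles.
#' @export
evaluate_predictions <- function(predictions, labels, min_pos = 25L) {
  stopifnot(all(dim(predictions) == dim(labels)))
  Tn <- ncol(predictions)
  ids <- colnames(predictions)
  if (is.null(ids)) ids <- paste0("profile", seq_len(Tn))
  res <- data.frame(profile = ids, n_pos = colSums(labels == 1),
                    auroc = NA_real_, auprc = NA_real_, included = FALSE,
                    stringsAsFactors = FALSE)
  for (t in seq_len(Tn)) {
    res$auroc[t] <- auroc(predictions[, t], labels[, t])
    res$auprc[t] <- auprc(predictions[, t], labels[, t])
  }
  res$included <- res$n_pos >= min_pos & !is.na(res$auroc)
  attr(res, "mean_auroc") <- mean(res$auroc[res$included])
  attr(res, "mean_auprc") <- mean(res$auprc[res$included])
  res
}

#' Profile-profile Spearman correlation structure of predictions vs labels
#'
#' @param pred_matrix `n x T` predictions.
#' @param label_matrix `n x T` labels.
#' @return list with `pred_cor`, `label_cor` (T x T Spearman matrices;
#'   `NA` where a column is constant) and `agreement` (Spearman correlation
#'   of the two upper triangles, complete pairs only).
#' @export
prediction_correlation_structure <- function(pred_matrix, label_matrix) {
  if (nrow(pred_matrix) < 3) stop("need >= 3 evaluation points")
  safe_cor <- function(M) {
    cc <- suppressWarnings(cor(M, method = "spearman"))
    const <- apply(M, 2, function(x) length(unique(x)) == 1L)
    cc[const, ] <- NA; cc[, const] <- NA
    cc
  }
  pc <- safe_cor(pred_matrix)
  lc <- safe_cor(label_matrix)
  up <- upper.tri(pc)
  ok <- is.finite(pc[up]) & is.finite(lc[up])
  agreement <- if (any(ok))
    suppressWarnings(cor(pc[up][ok], lc[up][ok], method = "spearman"))
  else NA_real_
  list(pred_cor = pc, label_cor = lc, agreement = agreement)
}

# ---- serialization ----------------------------------------------------------

#' Save a model to a single JSON checkpoint (text container)
#'
#' The configuration and all parameter arrays are embedded; the spline
#' basis is recomputed on load.
#'
#' @param model a `chrom_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, function(w)
                list(dim = dim(w), data = as.numeric(w))),
              bn_stats = model$bn_stats,
              profile_meta = model$profile_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path checkpoint path.
#' @return a `chrom_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(chrom_config,
                 obj$config[c("L", "n_targets", "channels", "kernel",
                              "pool", "dilations", "spline_df", "hidden",
                              "pool_type", "init_seed")])
  params <- lapply(obj$params, function(w) {
    if (is.null(w$dim) || length(w$dim) < 2) as.numeric(w$data)
    else array(as.numeric(w$data), dim = w$dim)
  })
  bn <- lapply(obj$bn_stats, function(st)
    list(mu = as.numeric(st$mu), var = as.numeric(st$var), n = st$n))
  structure(list(config = cfg, params = params,
                 basis = spline_basis(cfg$n_bins, cfg$spline_df),
                 bn_stats = bn, profile_meta = obj$profile_meta),
            class = "chrom_model")
}
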