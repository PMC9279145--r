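# Sequence-class discovery.
#
# Genome-wide prediction vectors are reduced with single-pass incremental
# PCA (components scaled to unit variance), connected into a k-nearest-
# neighbor graph by Euclidean distance, and partitioned with Louvain
# community detection.  The largest clusters become the sequence-class
# vocabulary; each class is summarized by the unit vector pointing at the
# mean prediction of its members, and cluster membership of tiled windows
# yields a nonoverlapping 100-bp genome annotation.

# ---- incremental PCA --------------------------------------------------------

#' Fit a PCA reduction incrementally over shuffled batches
#'
#' Single pass over the data: rows are randomly permuted into batches of
#' `batch_size` and the principal subspace is updated per batch by SVD
#' merging (mean-corrected, as in standard incremental PCA).  The
#' transform projects onto the components and scales each to unit
#' variance.
#'
#' @param X `n x T` matrix.
#' @param n_components number of components to keep (default 180, capped
#'   at `min(n, T)` with an error if infeasible).
#' @param batch_size rows per batch.
#' @param seed RNG seed for the row permutation.
#' @return an object of class `ReductionModel` with fields `components`
#'   (`n_components x T`, orthonormal rows), `mean`, `explained_var`,
#'   `scale` (s.d. per component) and `n_seen`.
#' @export
fit_reduction <- function(X, n_components = 180L, batch_size = 1e6L,
                          seed = 1L) {
  n <- nrow(X); Tn <- ncol(X)
  if (n_components > min(n, Tn))
    stop("n_components (", n_components, ") exceeds min(n, T) = ",
         min(n, Tn))
  if (batch_size < n_components)
    stop("batch_size must be >= n_components")
  set.seed(seed)
  perm <- sample.int(n)
  n_seen <- 0L
  mean_vec <- numeric(Tn)
  comps <- NULL; sv <- NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    B <- X[perm[i:j], , drop = FALSE]
    m <- nrow(B)
    bmean <- colMeans(B)
    if (n_seen == 0L) {
      M <- sweep(B, 2L, bmean)
      new_mean <- bmean
    } else {
      new_mean <- (n_seen * mean_vec + m * bmean) / (n_seen + m)
      corr <- sqrt(n_seen * m / (n_seen + m)) * (mean_vec - bmean)
      M <- rbind(comps * sv, sweep(B, 2L, bmean), matrix(corr, 1L))
    }
    sv_dec <- svd(M, nu = 0L, nv = n_components)
    k <- min(n_components, length(sv_dec$d))
    comps <- t(sv_dec$v[, seq_len(k), drop = FALSE])
    sv <- sv_dec$d[seq_len(k)]
    mean_vec <- new_mean
    n_seen <- n_seen + m
    i <- j + 1L
  }
  # deterministic sign convention: largest-|.| loading positive
  for (r in seq_len(nrow(comps))) {
    jmax <- which.max(abs(comps[r, ]))
    if (comps[r, jmax] < 0) comps[r, ] <- -comps[r, ]
  }
  ev <- sv^2 / (n_seen - 1L)
  if (any(ev <= 0))
    stop("n_components exceeds the feasible rank of the data")
  structure(list(components = comps, mean = mean_vec, explained_var = ev,
                 scale = sqrt(ev), n_seen = n_seen,
                 n_components = nrow(comps)),
            class = "ReductionModel")
}

#' Project data through a fitted reduction
#'
#' @param model a `ReductionModel`.
#' @param X `n x T` matrix.
#' @return `n x n_components` matrix with unit-variance components.
#' @export
transform_reduction <- function(model, X) {
  Z <- sweep(X, 2L, model$mean) %*% t(model$components)
  sweep(Z, 2L, model$scale, "/")
}

# ---- kNN graph and clustering ----------------------------------------------

#' Exact k-nearest-neighbor graph (Euclidean)
#'
#' Undirected, unweighted union of the directed kNN relations (a node
#' keeps an edge if either endpoint lists the other among its `k` nearest
#' neighbors); no self-loops.  Exact search, computed blockwise.
#'
#' @param X `n x d` matrix of points.
#' @param k neighbors per node (`0 < k < n`).
#' @param block_size rows per distance block.
#' @return an [igraph::graph] with `n` vertices.
#' @export
knn_graph <- function(X, k = 14L, block_size = 512L) {
  n <- nrow(X)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be < number of points")
  sq <- rowSums(X^2)
  from <- integer(n * k); to <- integer(n * k)
  i <- 1L
  while (i <= n) {
    j <- min(i + block_size - 1L, n)
    D2 <- outer(sq[i:j], sq, "+") - 2 * X[i:j, , drop = FALSE] %*% t(X)
    for (r in seq_len(j - i + 1L)) {
      d <- D2[r, ]
      d[i + r - 1L] <- Inf  # exclude self
      nn <- order(d)[seq_len(k)]
      idx <- ((i + r - 2L) * k + 1L):((i + r - 1L) * k)
      from[idx] <- i + r - 1L
      to[idx] <- nn
    }
    i <- j + 1L
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Louvain community clustering
#'
#' Modularity maximization with resolution 1 (default parameters) on an
#' unweighted graph; the R RNG is seeded so runs are reproducible.
#'
#' @param graph an igraph object.
#' @param seed RNG seed.
#' @return integer vector of community labels (1-based).
#' @export
louvain_cluster <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = 1)
  as.integer(igraph::membership(cl))
}

#' Rank clusters by size and keep the largest
#'
#' Clusters are ranked by member count, descending (ties broken by smaller
#' original cluster id).  `keep` is either an integer count of classes to
#' retain or `list(min_fraction = f)`: the smallest clusters whose joint
#' share of points stays below `f` are dropped.
#'
#' @param labels integer cluster labels.
#' @param keep integer count, or `list(min_fraction = f)`.
#' @return data.frame (`class`, `cluster`, `size`, `fraction`) in rank
#'   order; `class` is the rank-based id `"C1"`, `"C2"`, ...  Attribute
#'   `dropped` lists excluded cluster ids.
#' @export
select_classes <- function(labels, keep = 40L) {
  if (!length(labels)) stop("labels must be nonempty")
  tab <- table(labels)
  sizes <- as.integer(tab)
  ids <- as.integer(names(tab))
  o <- order(-sizes, ids)
  sizes <- sizes[o]; ids <- ids[o]
  n_cl <- length(ids)
  if (is.list(keep)) {
    frac <- sizes / length(labels)
    # drop the smallest clusters whose cumulative share stays < min_fraction
    cum_from_tail <- rev(cumsum(rev(frac)))
    n_keep <- sum(cum_from_tail >= keep$min_fraction)
    if (n_keep == 0L) n_keep <- 1L
  } else {
    n_keep <- as.integer(keep)
    if (n_keep > n_cl) {
      warning("keep (", n_keep, ") exceeds cluster count (", n_cl,
              "); keeping all")
      n_keep <- n_cl
    }
  }
  kept <- data.frame(class = paste0("C", seq_len(n_keep)),
                     cluster = ids[seq_len(n_keep)],
                     size = sizes[seq_len(n_keep)],
                     fraction = sizes[seq_len(n_keep)] / length(labels),
                     stringsAsFactors = FALSE)
  attr(kept, "dropped") <- if (n_keep < n_cl) ids[(n_keep + 1L):n_cl]
                           else integer(0)
  kept
}

#' Unit class vectors from member predictions
#'
#' For each kept class, `v_i` is the mean prediction vector of its members
#' normalized to unit Euclidean length, pointing in the direction of the
#' class's average prediction.
#'
#' @param pred_matrix `n x T` prediction matrix.
#' @param labels cluster labels aligned with rows.
#' @param kept data.frame from [select_classes()].
#' @return `n_classes x T` matrix with class ids as row names; every row
#'   has unit norm.
#' @export
class_vectors <- function(pred_matrix, labels, kept) {
  V <- matrix(NA_real_, nrow(kept), ncol(pred_matrix),
              dimnames = list(kept$class, colnames(pred_matrix)))
  for (r in seq_len(nrow(kept))) {
    members <- labels == kept$cluster[r]
    if (!any(members)) stop("class ", kept$class[r], " has no members")
    m <- colMeans(pred_matrix[members, , drop = FALSE])
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) stop("class ", kept$class[r],
                       " has an all-zero mean prediction")
    V[r, ] <- m / nrm
  }
  V
}

#' Fit the full sequence-class model from a prediction matrix
#'
#' Runs reduction, kNN graph construction, Louvain clustering, class
#' selection and class-vector computation; a single `seed` drives the
#' whole pipeline deterministically.
#'
#' @param pred_matrix `n x T` prediction matrix in `[0, 1]`.
#' @param n_components PCA components (capped at `min(n, T)`; default 180).
#' @param k nearest neighbors (default 14).
#' @param keep class-retention rule for [select_classes()] (default 40).
#' @param batch_size incremental-PCA batch size.
#' @param profile_meta optional per-profile metadata (for the histone
#'   mask used by variant-effect scoring).
#' @param seed pipeline seed.
#' @return an object of class `SequenceClassModel`: `reduction`, `labels`,
#'   `kept`, `vectors`, `histone_mask`, `seed`.
#' @export
fit_sequence_classes <- function(pred_matrix, n_components = 180L, k = 14L,
                                 keep = 40L, batch_size = 1e6L,
                                 profile_meta = NULL, seed = 1L) {
  n_components <- min(n_components, nrow(pred_matrix) - 1L,
                      ncol(pred_matrix))
  red <- fit_reduction(pred_matrix, n_components = n_components,
                       batch_size = batch_size, seed = seed)
  Z <- transform_reduction(red, pred_matrix)
  g <- knn_graph(Z, k = k)
  labels <- louvain_cluster(g, seed = seed)
  kept <- select_classes(labels, keep = keep)
  V <- class_vectors(pred_matrix, labels, kept)
  hmask <- if (!is.null(profile_meta)) profile_meta$assay_class == "histone"
           else rep(FALSE, ncol(pred_matrix))
  structure(list(reduction = red, labels = labels, kept = kept,
                 vectors = V, histone_mask = hmask,
                 profile_meta = profile_meta, seed = seed),
            class = "SequenceClassModel")
}

#' @export
print.SequenceClassModel <- function(x, ...) {
  cat("SequenceClassModel:", nrow(x$kept), "classes from",
      length(x$labels), "points\n")
  print(utils::head(x$kept, 10))
  invisible(x)
}

#' Annotate the genome at fixed-bin resolution
#'
#' Each tiled window contributes its center `bin`-bp bin, labeled with the
#' window's class (or `"unassigned"` for dropped clusters).  Windows must
#' come from [tile_genome()] with `step == bin` so bins are nonoverlapping.
#'
#' @param windows a `WindowSet` aligned with `labels`.
#' @param labels cluster labels per window.
#' @param kept data.frame from [select_classes()].
#' @param bin bin width in bp (default 100).
#' @return data.frame of class `GenomeAnnotation` with `contig`, `start`,
#'   `end`, `class`.
#' @export
annotate_genome <- function(windows, labels, kept, bin = 100L) {
  if (nrow(windows) != length(labels))
    stop("windows and labels must align")
  ctr <- windows$start + (windows$end - windows$start) %/% 2L
  start <- ctr - bin %/% 2L
  map <- setNames(kept$class, as.character(kept$cluster))
  cls <- map[as.character(labels)]
  cls[is.na(cls)] <- "unassigned"
  ann <- data.frame(contig = windows$contig, start = start,
                    end = start + bin, class = unname(cls),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann[, c("contig", "start")]))
    stop("duplicate bins: windows do not form a non-overlapping tiling ",
         "(was tile_genome run with step == bin?)")
  class(ann) <- c("GenomeAnnotation", "data.frame")
  attr(ann, "bin") <- as.integer(bin)
  ann
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 for chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must align")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Save a sequence-class model to a JSON archive (text container)
#'
#' @param scm a `SequenceClassModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_scm <- function(scm, path) {
  obj <- list(reduction = unclass(scm$reduction),
              labels = scm$labels,
              kept = scm$kept,
              vectors = list(dim = dim(scm$vectors),
                             rownames = rownames(scm$vectors),
                             data = as.numeric(scm$vectors)),
              histone_mask = scm$histone_mask,
              profile_meta = scm$profile_meta, seed = scm$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a sequence-class model saved by [save_scm()]
#'
#' @param path archive path.
#' @return a `SequenceClassModel`.
#' @export
load_scm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  red <- obj$reduction
  red$components <- matrix(unlist(red$components),
                           nrow = red$n_components, byrow = FALSE)
  class(red) <- "ReductionModel"
  V <- array(as.numeric(obj$vectors$data), dim = obj$vectors$dim)
  rownames(V) <- obj$vectors$rownames
  structure(list(reduction = red, labels = as.integer(obj$labels),
                 kept = as.data.frame(obj$kept), vectors = V,
                 histone_mask = as.logical(obj$histone_mask),
                 profile_meta = obj$profile_meta, seed = obj$seed),
            class = "SequenceClassModel")
}
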