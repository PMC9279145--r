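test_that("spline_basis is a partition-of-unity cubic basis", {
  S <- spline_basis(256, 16)
  expect_equal(dim(S), c(256L, 16L))
  expect_true(all(abs(rowSums(S) - 1) < 1e-9))
  expect_true(all(S >= 0))
  # square basis has full rank
  expect_equal(qr(spline_basis(16, 16))$rank, 16L)
  expect_error(spline_basis(8, 16), "exceed")
  expect_error(spline_basis(16, 3), ">= 4")
})

test_that("chrom_config validates its invariants", {
  expect_error(chrom_config(L = 513, n_targets = 5), "even")
  expect_error(chrom_config(L = 500, n_targets = 5, pool = c(4, 4)),
               "divisible")
  expect_error(chrom_config(L = 64, n_targets = 5, pool = c(4, 4),
                            spline_df = 32), "spline_df")
  cfg <- chrom_config_miniature(20)
  expect_equal(cfg$n_bins, 512L / 16L)
})

test_that("dual_path_block reduces exactly to its linear path", {
  set.seed(1)
  n <- 2L; L <- 16L; k <- 3L; Cin <- 4L; C <- 5L
  X <- matrix(rnorm(n * L * Cin), n * L, Cin)
  Wl <- array(rnorm(k * Cin * C), c(k, Cin, C)); bl <- rnorm(C)
  Wn0 <- array(0, c(k, C, C)); bn0 <- numeric(C)
  lin_only <- seqclass:::.conv_fwd(X, Wl, bl, 1L, n, L)$Y
  out <- dual_path_block(X, Wl, bl, Wn0, bn0, n, L)
  expect_identical(out, lin_only)  # bit-level: relu(0) + lin == lin

  # identity linear convolution + zero nonlinear -> output == input
  Wid <- array(0, c(k, Cin, Cin))
  Wid[2, , ] <- diag(Cin)  # center tap passes channels through
  Wn0b <- array(0, c(k, Cin, Cin))
  expect_equal(dual_path_block(X, Wid, numeric(Cin), Wn0b, numeric(Cin),
                               n, L), X)
  expect_error(dual_path_block(X[, 1:2], Wl, bl, Wn0, bn0, n, L),
               "channel mismatch")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- chrom_config(L = 32, n_targets = 3, channels = 4, kernel = 3,
                      pool = c(2, 2), dilations = c(2), spline_df = 4,
                      hidden = 6, init_seed = 2)
  m <- build_model(cfg)
  set.seed(3)
  n <- 2L
  X <- one_hot(c(rand_dna(32), rand_dna(32)))
  Y <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  fw <- seqclass:::.forward(m, X, n, want_cache = TRUE, training = TRUE)
  gr <- seqclass:::.backward(m, X, Y, fw, n)
  eps <- 1e-6
  for (nm in names(gr)) {
    w <- m$params[[nm]]
    idx <- sample(length(w), min(4, length(w)))
    for (i in idx) {
      m2 <- m
      m2$params[[nm]][i] <- w[i] + eps
      lp <- seqclass:::.bce(seqclass:::.forward(m2, X, n,
                                                training = TRUE)$P, Y)
      m2$params[[nm]][i] <- w[i] - eps
      lm_ <- seqclass:::.bce(seqclass:::.forward(m2, X, n,
                                                 training = TRUE)$P, Y)
      num <- (lp - lm_) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][i])), 1e-4)
    }
    # both paths of every dual block receive gradient
    if (grepl("^W", nm)) expect_gt(sum(abs(gr[[nm]])), 0)
  }
})

test_that("build_model output has the right shape and range", {
  cfg <- chrom_config(L = 256, n_targets = 7, channels = 6, kernel = 5,
                      pool = c(4, 4), dilations = 2, spline_df = 4,
                      hidden = 8, init_seed = 4)
  m <- build_model(cfg)
  P <- predict(m, c(rand_dna(256), rand_dna(256)))
  expect_equal(dim(P), c(2L, 7L))
  expect_true(all(P > 0 & P < 1))
  # all-N input: finite, in (0,1)
  Pn <- predict(m, strrep("N", 256))
  expect_true(all(is.finite(Pn) & Pn > 0 & Pn < 1))
  # doubling spline_df changes the parameter count by C*df*hidden
  cfg2 <- chrom_config(L = 256, n_targets = 7, channels = 6, kernel = 5,
                       pool = c(4, 4), dilations = 2, spline_df = 2 * 4,
                       hidden = 8, init_seed = 4)
  expect_equal(n_params(build_model(cfg2)) - n_params(m),
               6L * 4L * 8L)
  expect_error(build_model(cfg, profile_meta = data.frame(x = 1)),
               "n_targets")
})

test_that("predict is deterministic, batch-invariant, length-checked", {
  cfg <- chrom_config(L = 64, n_targets = 4, channels = 6, kernel = 5,
                      pool = c(4, 4), dilations = 2, spline_df = 4,
                      hidden = 8, init_seed = 5)
  m <- build_model(cfg)
  set.seed(6)
  seqs <- vapply(1:7, function(i) rand_dna(64), character(1))
  P1 <- predict(m, seqs, batch_size = 7)
  P2 <- predict(m, seqs, batch_size = 7)
  expect_identical(P1, P2)
  P3 <- predict(m, seqs, batch_size = 1)
  expect_lt(max(abs(P1 - P3)), 1e-6)
  expect_error(predict(m, "ACGT"), "length")
})

test_that("make_labels agrees with a brute-force position scan", {
  sg <- gen_genome(n_contigs = 2, contig_len = 20000, seed = 3,
                   elements_per_contig = 10)
  comp <- gen_profiles(sg, noise = 1, seed = 4)
  w <- tile_genome(sg$genome, 1000, step = 37)
  set.seed(5)
  w <- w[sample(nrow(w), 200), ]
  lab <- make_labels(w, comp)
  expect_equal(dim(lab), c(200L, length(comp$peaks)))
  # oracle: literal scan over every peak record
  for (t in seq_along(comp$peaks)) {
    pk <- comp$peaks[[t]]
    ctr <- w$start + (w$end - w$start) %/% 2L
    oracle <- vapply(seq_len(nrow(w)), function(i)
      any(pk$contig == w$contig[i] & pk$start <= ctr[i] & ctr[i] < pk$end),
      logical(1))
    expect_equal(lab[, t], as.integer(oracle))
  }
  # empty compendium -> all-zero labels
  empty <- structure(list(peaks = list(p1 = IntervalSet()),
                          meta = data.frame(profile_id = "p1",
                                            target = "x",
                                            assay_class = "TF",
                                            cell_type = "y")),
                     class = "ProfileCompendium")
  expect_true(all(make_labels(w, empty) == 0L))
})

test_that("zero training steps leave the model at initialization", {
  sg <- gen_genome(n_contigs = 2, contig_len = 20000, seed = 3,
                   elements_per_contig = 10)
  comp <- gen_profiles(sg, noise = 0, seed = 4)
  cfg <- chrom_config(L = 512, n_targets = length(comp$peaks),
                      channels = 4, kernel = 5, pool = c(4, 4),
                      dilations = 2, spline_df = 8, hidden = 8,
                      init_seed = 7)
  m0 <- build_model(cfg, profile_meta = comp$meta)
  m1 <- train_chromnet(m0, sg$genome, comp,
                       holdout = list(test = "ctg2",
                                      validation = character()),
                       steps = 0, seed = 1)
  expect_identical(m0$params, m1$params)
  # a compendium with no positives aborts with a diagnostic
  none <- structure(list(peaks = list(p1 = IntervalSet()),
                         meta = data.frame(profile_id = "p1", target = "x",
                                           assay_class = "TF",
                                           cell_type = "y")),
                    class = "ProfileCompendium")
  cfg1 <- chrom_config(L = 512, n_targets = 1, channels = 4, kernel = 5,
                       pool = c(4, 4), dilations = 2, spline_df = 8,
                       hidden = 8)
  expect_error(train_chromnet(build_model(cfg1), sg$genome, none,
                              steps = 1),
               "no positive labels")
})

test_that("auroc/auprc match definitions and handle ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(1:3, c(1, 1, 1))))
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  ev <- evaluate_predictions(cbind(c(0.9, 0.8, 0.4, 0.1)),
                             cbind(c(1, 0, 1, 0)), min_pos = 1)
  expect_equal(ev$auroc, 0.75)
  expect_true(ev$included)
  ev2 <- evaluate_predictions(cbind(c(0.9, 0.8, 0.4, 0.1)),
                              cbind(c(1, 0, 1, 0)), min_pos = 25)
  expect_false(ev2$included)
  expect_true(is.nan(attr(ev2, "mean_auroc")))
})

test_that("prediction_correlation_structure recovers shared structure", {
  set.seed(8)
  Y <- matrix(rbinom(300, 1, 0.4), 100, 3)
  r <- prediction_correlation_structure(Y, Y)
  expect_equal(r$agreement, 1.0)
  # two identical profiles correlate at 1 in both matrices
  P <- matrix(runif(300), 100, 3)
  P[, 2] <- P[, 1]
  r2 <- prediction_correlation_structure(P, cbind(Y[, 1], Y[, 1], Y[, 3]))
  expect_equal(r2$pred_cor[1, 2], 1.0)
  expect_equal(r2$label_cor[1, 2], 1.0)
  # independent columns: off-diagonals near zero
  set.seed(9)
  Pn <- matrix(runif(4000), 1000, 4)
  rn <- prediction_correlation_structure(Pn, matrix(rbinom(4000, 1, 0.5),
                                                    1000, 4))
  off <- rn$pred_cor[upper.tri(rn$pred_cor)]
  expect_true(all(abs(off) < 0.1))
  # constant column reported as missing
  Pc <- cbind(rep(0.5, 100), runif(100), runif(100))
  rc <- prediction_correlation_structure(Pc, Y)
  expect_true(all(is.na(rc$pred_cor[1, ])))
  expect_error(prediction_correlation_structure(Pn[1:2, ], Pn[1:2, ]),
               ">= 3")
})

test_that("model checkpoints round-trip through JSON", {
  cfg <- chrom_config(L = 64, n_targets = 3, channels = 4, kernel = 3,
                      pool = c(4, 4), dilations = 2, spline_df = 4,
                      hidden = 6, init_seed = 11)
  meta <- data.frame(profile_id = c("a", "b", "c"),
                     target = "t", assay_class = "TF", cell_type = "x")
  m <- build_model(cfg, profile_meta = meta)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  s <- rand_dna(64)
  expect_equal(predict(m, s), predict(m2, s), tolerance = 1e-12)
})
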