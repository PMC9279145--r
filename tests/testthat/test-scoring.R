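# a minimal hand-built SequenceClassModel for projection tests
toy_scm <- function(V, histone_mask = rep(FALSE, ncol(V))) {
  structure(list(
    vectors = V,
    kept = data.frame(class = rownames(V),
                      cluster = seq_len(nrow(V)),
                      size = 1L, fraction = 1 / nrow(V)),
    histone_mask = histone_mask, labels = NULL, reduction = NULL),
    class = "SequenceClassModel")
}

test_that("class_score is the projection onto class vectors", {
  V <- rbind(C1 = c(0.6, 0.8, 0), C2 = c(0, 0, 1))
  scm <- toy_scm(V)
  # self-projection of a unit vector
  expect_equal(unname(class_score(c(0.6, 0.8, 0), scm)["C1"]), 1.0)
  # orthogonal vector scores zero
  expect_equal(unname(class_score(c(0.6, 0.8, 0), scm)["C2"]), 0.0)
  # linearity
  p <- c(0.3, 0.5, 0.7)
  expect_equal(class_score(0.5 * p, scm), 0.5 * class_score(p, scm))
  # matrix form agrees with vector form
  P <- rbind(p, 2 * p)
  expect_equal(unname(class_score(P, scm)[1, ]),
               unname(class_score(p, scm)))
  expect_error(class_score(c(1, 2), scm), "targets")
})

test_that("adjust_histone implements the occupancy normalization", {
  mask <- c(TRUE, TRUE, FALSE)
  # equal alleles are unchanged (scale factor 1)
  p <- c(0.5, 1.5, 0.9)
  eq <- adjust_histone(p, p, mask)
  expect_equal(eq$p_ref, p)
  expect_equal(eq$p_alt, p)
  # worked example: S_R = 2, S_A = 4
  p_ref <- c(0.5, 1.5, 0.2); p_alt <- c(1, 3, 0.7)
  adj <- adjust_histone(p_ref, p_alt, mask)
  expect_equal(adj$p_ref[1:2], c(0.5, 1.5) * 1.5)
  expect_equal(adj$p_alt[1:2], c(1, 3) * 0.75)
  expect_equal(sum(adj$p_ref[mask]), 3)
  expect_equal(sum(adj$p_alt[mask]), 3)
  # non-histone entries untouched
  expect_equal(adj$p_ref[3], 0.2)
  expect_equal(adj$p_alt[3], 0.7)
  # conservation identity on random inputs
  set.seed(1)
  for (i in 1:200) {
    a <- runif(6); b <- runif(6)
    m <- sample(c(TRUE, FALSE), 6, TRUE)
    if (!any(m)) m[1] <- TRUE
    r <- adjust_histone(a, b, m)
    target <- (sum(a[m]) + sum(b[m])) / 2
    expect_lt(abs(sum(r$p_ref[m]) - target), 1e-9)
    expect_lt(abs(sum(r$p_alt[m]) - target), 1e-9)
  }
  expect_error(adjust_histone(c(0, 0, 1), p, mask), "zero")
  # no histone profiles: identity
  none <- adjust_histone(p_ref, p_alt, rep(FALSE, 3))
  expect_identical(none$p_ref, p_ref)
})

test_that("variant_effect: ref==alt gives exact zeros; errors are named", {
  set.seed(2)
  g <- GenomeSequence(c(c1 = rand_dna(300)))
  cfg <- chrom_config(L = 64, n_targets = 4, channels = 4, kernel = 3,
                      pool = c(4, 4), dilations = 2, spline_df = 4,
                      hidden = 6, init_seed = 3)
  meta <- data.frame(profile_id = paste0("p", 1:4), target = "t",
                     assay_class = c("TF", "histone", "histone",
                                     "accessibility"),
                     cell_type = "x")
  m <- build_model(cfg, profile_meta = meta)
  V <- matrix(rnorm(8), 2, 4, dimnames = list(c("C1", "C2"), NULL))
  V <- V / sqrt(rowSums(V^2))
  scm <- toy_scm(V, histone_mask = meta$assay_class == "histone")
  ref_base <- get_seq(g, "c1", 149, 150)
  v_same <- VariantTable("c1", 150L, ref_base, ref_base)
  eff <- variant_effect(m, scm, v_same, g)
  expect_equal(unname(unlist(eff[, c("delta_C1", "delta_C2")])), c(0, 0))
  # mismatching ref allele is caught with the position named
  wrong <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  expect_error(variant_effect(m, scm, VariantTable("c1", 150L, wrong, "A"),
                              g), "150")
  # window out of bounds
  expect_error(variant_effect(m, scm,
                              VariantTable("c1", 5L,
                                           get_seq(g, "c1", 4, 5), "A"),
                              g), "out of bounds")
})

test_that("variant_effect decomposes into predict/adjust/score", {
  set.seed(4)
  g <- GenomeSequence(c(c1 = rand_dna(300)))
  cfg <- chrom_config(L = 64, n_targets = 4, channels = 4, kernel = 3,
                      pool = c(4, 4), dilations = 2, spline_df = 4,
                      hidden = 6, init_seed = 5)
  meta <- data.frame(profile_id = paste0("p", 1:4), target = "t",
                     assay_class = c("TF", "histone", "histone", "TF"),
                     cell_type = "x")
  m <- build_model(cfg, profile_meta = meta)
  V <- matrix(rnorm(8), 2, 4, dimnames = list(c("C1", "C2"), NULL))
  V <- V / sqrt(rowSums(V^2))
  scm <- toy_scm(V, histone_mask = meta$assay_class == "histone")
  p0 <- 150L
  ref <- get_seq(g, "c1", p0 - 1L, p0)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- VariantTable("c1", p0, ref, alt)
  eff <- variant_effect(m, scm, v, g)
  # manual composition
  half <- 32L
  rs <- get_seq(g, "c1", p0 - 1L - half, p0 - 1L + half)
  as_ <- rs; substr(as_, half + 1L, half + 1L) <- alt
  pr <- predict(m, rs)[1, ]; pa <- predict(m, as_)[1, ]
  adj <- adjust_histone(pr, pa, scm$histone_mask)
  d_manual <- class_score(adj$p_alt, scm) - class_score(adj$p_ref, scm)
  expect_identical(unname(unlist(eff[, c("delta_C1", "delta_C2")])),
                   unname(d_manual))
  # indel path: windows stay length L and deltas are finite
  vin <- VariantTable("c1", p0, ref, paste0(ref, "ACG"))
  ein <- variant_effect(m, scm, vin, g)
  expect_true(all(is.finite(unlist(ein[, c("delta_C1", "delta_C2")]))))
})

test_that("assign_mutation_class applies the gap-and-fold rule", {
  ann <- structure(data.frame(contig = "c1", start = 0, end = 1000,
                              class = "C1"),
                   class = c("GenomeAnnotation", "data.frame"))
  mk <- function(d1, d2) fake_effects(cbind(C1 = d1, C2 = d2), pos = 500L)
  pick <- function(d1, d2, ...) {
    r <- assign_mutation_class(mk(d1, d2), ann, ...)
    c(r$assigned_class, r$provenance)
  }
  # gap 1.3 > 1 and ratio 7.5 > 2.5: reassigned
  expect_equal(pick(0.2, 1.5), c("C2", "reassigned"))
  # gap 0.9 <= 1: stays positional
  expect_equal(pick(1.0, 1.9), c("C1", "positional"))
  # ratio 2.4 <= 2.5 despite large gap: stays positional
  expect_equal(pick(1.2, 2.88), c("C1", "positional"))
  # zero-denominator limit: |orig| = 0, |best| > 1 reassigns
  expect_equal(pick(0, 1.2), c("C2", "reassigned"))
  expect_equal(pick(0, 0.8), c("C1", "positional"))
  # negative deltas count by absolute value
  expect_equal(pick(-0.2, -1.5), c("C2", "reassigned"))
  # best class == positional class
  expect_equal(pick(2.0, 0.1), c("C1", "positional"))
  # excluded classes are no candidates
  r <- assign_mutation_class(mk(0.2, 9), ann, exclude_classes = "C2")
  expect_equal(r$assigned_class, "C1")
  # unassigned position without qualifying effect stays unassigned
  far <- fake_effects(cbind(C1 = 0.1, C2 = 0.2), pos = 5000L)
  expect_equal(assign_mutation_class(far, ann)$assigned_class,
               "unassigned")
  # ... but a strong effect off-annotation is adopted
  far2 <- fake_effects(cbind(C1 = 0.1, C2 = 1.8), pos = 5000L)
  expect_equal(assign_mutation_class(far2, ann)$assigned_class, "C2")
  # idempotence
  once <- assign_mutation_class(mk(0.2, 1.5), ann)
  twice <- assign_mutation_class(once, ann)
  expect_equal(once$assigned_class, twice$assigned_class)
})
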