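# exact hypergeometric enumeration oracle for a 2x2 Fisher test
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("logfc_enrichment computes proportions, Fisher p and BH q", {
  # 100 bins: class A = 30 bins fully inside the feature, class B = 70
  # bins of which 10 are inside
  ann <- structure(data.frame(
    contig = "c1", start = (0:99) * 100, end = (0:99) * 100 + 100,
    class = rep(c("A", "B"), times = c(30, 70))),
    class = c("GenomeAnnotation", "data.frame"))
  feat <- IntervalSet("c1", c(0, 3100), c(3000, 4100))  # A:30, B:10
  res <- logfc_enrichment(ann, list(f = feat))
  a_row <- res[res$class == "A", ]
  b_row <- res[res$class == "B", ]
  expect_equal(a_row$n_class_in, 30)
  expect_equal(b_row$n_class_in, 10)
  # proportions: A 100% vs background 40%
  expect_equal(a_row$logfc, log(1 / 0.4))
  # Fisher p agrees with exact hypergeometric enumeration
  expect_equal(a_row$p, fisher_oracle(matrix(c(30, 0, 10, 60), 2)),
               tolerance = 1e-9)
  # feature covering all bins: logFC = 0 everywhere
  all_feat <- IntervalSet("c1", 0, 10000)
  res0 <- logfc_enrichment(ann, list(f = all_feat))
  expect_true(all(res0$logfc == 0))
  # class 100% in feature vs 10% background
  ann2 <- structure(data.frame(
    contig = "c1", start = (0:99) * 100, end = (0:99) * 100 + 100,
    class = rep(c("A", "B"), times = c(10, 90))),
    class = c("GenomeAnnotation", "data.frame"))
  feat2 <- IntervalSet("c1", 0, 1000)  # exactly class A's 10 bins
  res2 <- logfc_enrichment(ann2, list(f = feat2))
  expect_equal(res2$logfc[res2$class == "A"], log(10))
})

test_that("Fisher p matches enumeration on random small tables", {
  set.seed(1)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    while (sum(tab) > 200) tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment in enrichment is monotone in raw p", {
  ann <- structure(data.frame(
    contig = "c1", start = (0:199) * 100, end = (0:199) * 100 + 100,
    class = rep(c("A", "B"), 100)),
    class = c("GenomeAnnotation", "data.frame"))
  set.seed(2)
  feats <- lapply(1:6, function(i) {
    sel <- sort(sample(0:199, 50))
    IntervalSet("c1", sel * 100, sel * 100 + 100)
  })
  names(feats) <- paste0("f", 1:6)
  res <- logfc_enrichment(ann, feats)
  for (cl in unique(res$class)) {
    sub <- res[res$class == cl, ]
    o <- order(sub$p)
    expect_true(all(diff(sub$q[o]) >= -1e-12))
  }
})

test_that("expression_correlation transforms and correlates per tissue", {
  sg <- gen_genome(n_contigs = 3, contig_len = 50000, seed = 3,
                   elements_per_contig = 30)
  # annotation directly from planted truth: one bin per element center,
  # class = cell type of the element
  tr <- sg$truth
  ann <- structure(data.frame(
    contig = tr$contig, start = (tr$center %/% 100) * 100,
    end = (tr$center %/% 100) * 100 + 100,
    class = tr$cell_type), class = c("GenomeAnnotation", "data.frame"))
  ann <- ann[!duplicated(ann[, c("contig", "start")]), ]
  ex <- gen_expression(sg, n_genes = 400, effect_size = 2,
                       noise_sd = 0.1, seed = 4)
  res <- expression_correlation(ann, ex$tss, ex$expr)
  # per-gene transformed expression sums to zero across tissues
  E <- log(ex$expr + 1e-4); E <- E - rowMeans(E)
  expect_true(all(abs(rowSums(E)) < 1e-10))
  # matched tissue correlates higher than mismatched for liver class
  liv <- res[res$class == "liver", ]
  skip_if(all(is.na(liv$rho)))
  expect_gt(liv$rho[liv$tissue == "liver"],
            max(liv$rho[liv$tissue != "liver"]))
  # null cohort: correlations near zero
  ex0 <- gen_expression(sg, n_genes = 400, effect_size = 0, seed = 5)
  res0 <- expression_correlation(ann, ex0$tss, ex0$expr)
  expect_true(all(abs(res0$rho) < 0.15, na.rm = TRUE))
})

test_that("eqtl_correlation selects top effects and adjusts across classes", {
  set.seed(6)
  n <- 500
  delta <- cbind(C1 = rnorm(n), C2 = rnorm(n))
  eff <- fake_effects(delta)
  # slopes identical to C1 deltas: rho = 1 for C1
  eq <- data.frame(id = eff$id, slope = delta[, "C1"])
  res <- suppressWarnings(eqtl_correlation(eff, eq, top_n = 1e5))
  expect_equal(res$rho[res$class == "C1"], 1.0)
  expect_true(all(c("p", "q") %in% colnames(res)))
  # independent slopes: |rho| small (n = 2000)
  n2 <- 2000
  eff2 <- fake_effects(cbind(C1 = rnorm(n2)))
  eq2 <- data.frame(id = eff2$id, slope = rnorm(n2))
  res2 <- suppressWarnings(eqtl_correlation(eff2, eq2, top_n = 1e5))
  expect_lt(abs(res2$rho), 0.07)
  # top_n above availability warns and uses all
  expect_warning(eqtl_correlation(eff2, eq2, top_n = 1e6), "using all")
  # exclusion flag drops classes
  res3 <- suppressWarnings(eqtl_correlation(eff, eq, top_n = 1e5,
                                            exclude_classes = "C2"))
  expect_false("C2" %in% res3$class)
  # top_n selection really subsets by |delta|
  res4 <- suppressWarnings(eqtl_correlation(eff2, eq2, top_n = 100))
  expect_equal(res4$n, 100L)
})

test_that("bin_effects follows the 1% / 1-10% / 10-100% arm scheme", {
  set.seed(7)
  pos <- runif(1000, 0.1, 5)
  b <- bin_effects(pos)
  expect_equal(as.vector(table(b)[c("3", "2", "1")]), c(10L, 90L, 900L))
  # the top-1% bin holds the largest values
  expect_true(min(pos[b == 3]) >= max(pos[b == 1]))
  # single positive variant is the top 1%
  expect_equal(bin_effects(2.5), 3L)
  # symmetric deltas mirror
  sym <- c(pos, -pos)
  bs <- bin_effects(sym)
  expect_equal(as.vector(table(bs)[c("-3", "-2", "-1")]), c(10L, 90L, 900L))
  expect_equal(as.vector(table(bs)[c("3", "2", "1")]), c(10L, 90L, 900L))
  # zeros go to +1; all-zero warns
  expect_warning(bz <- bin_effects(rep(0, 5)), "zero")
  expect_equal(bz, rep(1L, 5))
  mix <- bin_effects(c(0, 0.5, -0.5))
  expect_equal(mix[1], 1L)
  expect_error(bin_effects(numeric(0)), "nonempty")
})

test_that("constraint_zscore combines arm z-scores by Stouffer", {
  expect_equal(stouffer(-2, -2), -4 / sqrt(2))
  set.seed(8)
  n <- 20000
  deltas <- rnorm(n)
  # planted depletion: strong negative selection at large |effect|
  af_dep <- sim_variant_af(deltas, b = 1.5, seed = 9)
  r <- constraint_zscore(deltas, af_dep)
  expect_lt(r$z_pos, -3); expect_lt(r$z_neg, -3)
  expect_equal(r$z, -(r$z_pos + r$z_neg) / sqrt(2))
  expect_gt(r$z, 3)
  # per-bin summary: frequencies fall toward extreme bins
  expect_equal(sum(r$bins$n), n)
  expect_true(all(r$bins$se >= 0))  # extreme bins may be pure
  f <- setNames(r$bins$freq, r$bins$bin)
  expect_lt(f["3"], f["1"])
  expect_lt(f["-3"], f["-1"])
  # null model: modest z
  af_null <- sim_variant_af(deltas, b = 0, seed = 10)
  r0 <- constraint_zscore(deltas, af_null)
  expect_lt(abs(r0$z), 3.5)
  # degenerate arm flagged
  one_arm <- constraint_zscore(abs(deltas[1:100]) + 0.1,
                               rep(c(0.005, 0.2), 50))
  expect_equal(unname(one_arm$arm_flags["neg"]), "empty")
  expect_true(is.na(one_arm$z))
})

test_that("constraint_scan reports per-class rows with BH q", {
  set.seed(11)
  n <- 5000
  delta <- cbind(C1 = rnorm(n), C2 = rnorm(n), L1 = rnorm(n))
  af <- sim_variant_af(delta[, 1], b = 1, seed = 12)
  res <- constraint_scan(delta, af, exclude_classes = "L1")
  expect_setequal(res$class, c("C1", "C2"))
  expect_gt(res$z[res$class == "C1"], 2)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("export_ldsc_annot emits a one-hot class partition", {
  ann <- structure(data.frame(
    contig = c("c1", "c1", "c2"), start = c(0, 100, 0),
    end = c(100, 200, 100), class = c("C1", "C2", "C1")),
    class = c("GenomeAnnotation", "data.frame"))
  sites <- data.frame(contig = c("c1", "c1", "c2", "c2", "c3"),
                      pos = c(50L, 150L, 50L, 950L, 1L),
                      id = paste0("rs", 1:5))
  tab <- export_ldsc_annot(ann, sites)
  expect_equal(colnames(tab), c("CHR", "BP", "SNP", "CM", "base",
                                "C1", "C2"))
  expect_equal(tab$base, rep(1L, 5))
  M <- as.matrix(tab[, c("C1", "C2")])
  expect_equal(unname(M),
               rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 0L),
                     c(0L, 0L)))
  expect_true(all(rowSums(M) %in% c(0L, 1L)))
  expect_equal(attr(tab, "n_unannotated"), 2L)
})

test_that("conservative_h2 subtracts one s.e. and floors at zero", {
  expect_equal(conservative_h2(0.10, 0.15), 0)
  expect_equal(conservative_h2(0.10, 0.02), 0.08)
  expect_equal(conservative_h2(-0.05, 0.01), 0)
  expect_equal(conservative_h2(c(0.3, 0.1), c(0.1, 0.2)), c(0.2, 0))
  expect_error(conservative_h2(0.1, -0.01), "nonnegative")
})

test_that("parse_ldsc_results applies the conservative estimator", {
  f <- withr::local_tempfile(fileext = ".results")
  writeLines(c("Category\tProp._h2\tProp._h2_std_error",
               "C1\t0.30\t0.05", "C2\t0.02\t0.04"), f)
  r <- parse_ldsc_results(f)
  expect_equal(r$conservative, c(0.25, 0))
  writeLines("Category\tother", f)
  expect_error(parse_ldsc_results(f), "lacks columns")
})
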