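# Downstream population-genetics statistics over sequence classes:
# annotation enrichment (Fisher + BH), tissue-expression and eQTL
# correlations, allele-frequency constraint z-scores, and construction of
# nonoverlapping annotations for partitioned-heritability regression.

# assigned bins of an annotation (the background convention: all regions
# assigned to any sequence class)
.assigned_bins <- function(annotation) {
  annotation[annotation$class != "unassigned", , drop = FALSE]
}

#' Log fold-change enrichment of features in sequence classes
#'
#' For each class and feature interval set: the proportion of the class's
#' bins intersecting the feature is compared to the background proportion
#' over all assigned bins (or over supplied random positions), giving
#' `logFC = log(prop_class / prop_background)`.  A two-sided Fisher exact
#' test on the 2x2 bin table yields p-values, BH-adjusted across features
#' within each class; the `top` flag marks the `top_n` features per class
#' by logFC among those with `q < q_max`.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param features named list of [IntervalSet]s.
#' @param background `"assigned"` (default: all bins assigned to any
#'   class) or an [IntervalSet] of random background positions.
#' @param q_max BH threshold for the top-feature selection.
#' @param top_n features flagged per class (default 25).
#' @return data.frame of class `EnrichmentResult` with columns `class`,
#'   `feature`, `n_class`, `n_class_in`, `n_bg`, `n_bg_in`, `logfc`, `p`,
#'   `q`, `top`.
#' @export
logfc_enrichment <- function(annotation, features, background = "assigned",
                             q_max = 0.05, top_n = 25L) {
  bins <- .assigned_bins(annotation)
  if (!nrow(bins)) stop("annotation has no assigned bins")
  if (identical(background, "assigned")) {
    bg <- bins
  } else {
    stopifnot(inherits(background, "IntervalSet") ||
                is.data.frame(background))
    bg <- background
  }
  bins_iv <- IntervalSet(bins$contig, bins$start, bins$end)
  bg_iv <- IntervalSet(bg$contig, bg$start, bg$end)
  classes <- unique(bins$class)
  rows <- list()
  for (feat_name in names(features)) {
    f_ir <- .iranges_by_contig(features[[feat_name]])
    in_feat <- function(iv) {
      hit <- logical(nrow(iv))
      for (cn in unique(iv$contig)) {
        w <- iv$contig == cn
        ir <- f_ir[[cn]]
        if (is.null(ir)) next
        q <- IRanges::IRanges(start = iv$start[w] + 1L, end = iv$end[w])
        hit[w] <- IRanges::overlapsAny(q, ir)
      }
      hit
    }
    bins_hit <- in_feat(bins_iv)
    bg_hit <- in_feat(bg_iv)
    n_bg <- nrow(bg); n_bg_in <- sum(bg_hit)
    for (cl in classes) {
      sel <- bins$class == cl
      n_cl <- sum(sel)
      if (n_cl == 0) next
      a <- sum(bins_hit[sel])
      prop_cl <- a / n_cl
      prop_bg <- n_bg_in / n_bg
      logfc <- if (prop_bg == 0) NA_real_ else log(prop_cl / prop_bg)
      # 2x2: class bins vs background-excluding-class bins
      if (identical(background, "assigned")) {
        tab <- matrix(c(a, n_cl - a,
                        n_bg_in - a, (n_bg - n_cl) - (n_bg_in - a)), 2L)
      } else {
        tab <- matrix(c(a, n_cl - a, n_bg_in, n_bg - n_bg_in), 2L)
      }
      p <- fisher.test(tab, alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, feature = feat_name, n_class = n_cl, n_class_in = a,
        n_bg = n_bg, n_bg_in = n_bg_in, logfc = logfc, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$top <- FALSE
  for (cl in unique(res$class)) {
    w <- which(res$class == cl)
    res$q[w] <- p.adjust(res$p[w], method = "BH")
    sig <- w[res$q[w] < q_max & is.finite(res$logfc[w])]
    if (length(sig)) {
      keep <- sig[order(-res$logfc[sig])][seq_len(min(top_n, length(sig)))]
      res$top[keep] <- TRUE
    }
  }
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Sequence-class coverage near TSS vs tissue-specific expression
#'
#' Expression is transformed to `log(x + pseudocount)` and the per-gene
#' mean across tissues is subtracted, so values are log fold changes over
#' the tissue average.  Per class, a gene's coverage is the fraction of
#' annotation bins within `+/- window` of its TSS assigned to that class.
#' A Spearman correlation over genes is reported per (class, tissue).
#'
#' @param annotation a `GenomeAnnotation`.
#' @param tss data.frame with `gene`, `contig`, `pos` (0-based TSS).
#' @param expr gene x tissue nonnegative expression matrix (row names =
#'   genes).
#' @param window TSS window half-width in bp (default 10 kb).
#' @param pseudocount added before log (default 1e-4, the convention for
#'   individual-averaged RPKM tables; use 0.01 for coarser compendia).
#' @param classes classes to report (default: all kept classes present).
#' @return data.frame (`class`, `tissue`, `rho`, `n`) of class
#'   `ExpressionCorrelation`; `rho` is `NA` when coverage is constant.
#' @export
expression_correlation <- function(annotation, tss, expr, window = 10000L,
                                   pseudocount = 1e-4, classes = NULL) {
  stopifnot(all(rownames(expr) %in% tss$gene))
  tss <- tss[match(rownames(expr), tss$gene), , drop = FALSE]
  E <- log(expr + pseudocount)
  E <- E - rowMeans(E)
  if (is.null(classes))
    classes <- setdiff(unique(annotation$class), "unassigned")
  ann_by_contig <- split(seq_len(nrow(annotation)), annotation$contig)
  n_genes <- nrow(tss)
  cov <- matrix(0, n_genes, length(classes),
                dimnames = list(tss$gene, classes))
  for (g in seq_len(n_genes)) {
    rows <- ann_by_contig[[tss$contig[g]]]
    if (is.null(rows)) next
    lo <- tss$pos[g] - window; hi <- tss$pos[g] + window
    inw <- rows[annotation$end[rows] > lo & annotation$start[rows] < hi]
    if (!length(inw)) next
    cls <- annotation$class[inw]
    for (ci in seq_along(classes))
      cov[g, ci] <- sum(cls == classes[ci]) / length(inw)
  }
  rows <- list()
  for (ci in seq_along(classes)) {
    constant <- length(unique(cov[, ci])) == 1L
    for (t in colnames(E)) {
      rho <- if (constant) NA_real_ else
        suppressWarnings(cor(cov[, ci], E[, t], method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[ci], tissue = t, rho = rho, n = n_genes,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("ExpressionCorrelation", "data.frame")
  attr(res, "coverage") <- cov
  res
}

#' Correlate predicted class-level variant effects with eQTL slopes
#'
#' Per class, the `top_n` variants by absolute predicted effect are
#' selected and the Spearman correlation between their signed effects and
#' matched eQTL slopes is computed, with a two-sided test and BH
#' adjustment across classes.
#'
#' @param effects a `VariantEffectTable` (needs an `id` column).
#' @param eqtl data.frame with `id` and `slope` (tissue-averaged effect
#'   sizes), or a named numeric vector.
#' @param top_n variants per class (default 15000; uses all with a
#'   warning when fewer are available).
#' @param exclude_classes classes skipped (e.g. low-signal and
#'   heterochromatin classes).
#' @param min_n classes with fewer matched variants are skipped.
#' @return data.frame (`class`, `n`, `rho`, `p`, `q`) of class
#'   `EqtlCorrelation`.
#' @export
eqtl_correlation <- function(effects, eqtl, top_n = 15000L,
                             exclude_classes = character(), min_n = 10L) {
  if (!is.data.frame(eqtl))
    eqtl <- data.frame(id = names(eqtl), slope = as.numeric(eqtl),
                       stringsAsFactors = FALSE)
  delta <- effect_deltas(effects)
  slope <- eqtl$slope[match(effects$id, eqtl$id)]
  ok <- !is.na(slope)
  delta <- delta[ok, , drop = FALSE]; slope <- slope[ok]
  classes <- setdiff(colnames(delta), exclude_classes)
  rows <- list()
  for (cl in classes) {
    d <- delta[, cl]
    if (length(d) < min_n) next
    if (top_n < length(d)) {
      sel <- order(-abs(d))[seq_len(top_n)]
    } else {
      if (top_n > length(d))
        warning("top_n (", top_n, ") exceeds available variants (",
                length(d), ") for class ", cl, "; using all")
      sel <- seq_along(d)
    }
    ct <- suppressWarnings(
      cor.test(d[sel], slope[sel], method = "spearman",
               alternative = "two.sided", exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, n = length(sel), rho = unname(ct$estimate),
      p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no class had >= ", min_n, " matched variants")
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  class(res) <- c("EqtlCorrelation", "data.frame")
  res
}

#' Bin signed variant effects into the six-bin scheme
#'
#' Within each sign arm, empirical quantiles split variants into top 1%
#' (`+3`/`-3`), top 1-10% (`+2`/`-2`) and the remaining 10-100%
#' (`+1`/`-1`).  Exact zeros go to `+1`.  Ties are broken by stable rank
#' order.
#'
#' @param deltas signed per-variant effects for one class.
#' @return integer vector of bin labels in `{-3, -2, -1, 1, 2, 3}` (the
#'   sign encodes the arm, the magnitude the quantile tier).
#' @export
bin_effects <- function(deltas) {
  if (!length(deltas)) stop("deltas must be nonempty")
  bins <- integer(length(deltas))
  if (all(deltas == 0)) {
    warning("all deltas are zero; assigning every variant to +1")
    return(rep(1L, length(deltas)))
  }
  arm_bins <- function(idx, decreasing) {
    n <- length(idx)
    r <- rank(if (decreasing) -deltas[idx] else deltas[idx],
              ties.method = "first")
    tier <- ifelse(r <= ceiling(0.01 * n), 3L,
                   ifelse(r <= ceiling(0.10 * n), 2L, 1L))
    tier
  }
  pos <- which(deltas > 0)
  neg <- which(deltas < 0)
  zero <- which(deltas == 0)
  if (length(pos)) bins[pos] <- arm_bins(pos, decreasing = TRUE)
  if (length(neg)) bins[neg] <- -arm_bins(neg, decreasing = FALSE)
  bins[zero] <- 1L
  bins
}

#' Bidirectional allele-frequency constraint z-score
#'
#' Logistic regressions, fit separately for positive- and negative-effect
#' variants, predict common-variant status (`AF > common_threshold`) from
#' `|delta|`; each arm contributes the Wald z of its slope.  The combined
#' constraint score is the negated equal-weight Stouffer combination
#' `z = -(z_pos + z_neg) / sqrt(2)`: positive values mean common variants
#' are depleted at large predicted effects.  Per-bin common-variant
#' frequencies (six-bin scheme, binomial standard errors) are attached.
#'
#' @param deltas signed per-variant effects for one class.
#' @param af allele frequencies aligned with `deltas`.
#' @param common_threshold AF threshold for "common" (default 0.01).
#' @return list of class `ConstraintResult`: `z_pos`, `z_neg`, `z`
#'   (combined; `NA` if either arm failed), `arm_flags`, and `bins`
#'   (data.frame `bin`, `n`, `freq`, `se`).
#' @export
constraint_zscore <- function(deltas, af, common_threshold = 0.01) {
  stopifnot(length(deltas) == length(af))
  is_common <- af > common_threshold
  arm_fit <- function(idx) {
    if (!length(idx)) return(list(z = NA_real_, flag = "empty"))
    y <- is_common[idx]
    if (all(y) || !any(y)) return(list(z = NA_real_, flag = "one-class"))
    x <- abs(deltas[idx])
    if (length(unique(x)) < 2L) return(list(z = NA_real_, flag = "constant"))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial(),
          control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (sep || abs(co["x", "Estimate"]) > 15)
      return(list(z = NA_real_, flag = "separation"))
    list(z = unname(co["x", "z value"]), flag = "ok")
  }
  pos <- arm_fit(which(deltas >= 0))
  neg <- arm_fit(which(deltas < 0))
  z <- if (is.na(pos$z) || is.na(neg$z)) NA_real_
       else -(pos$z + neg$z) / sqrt(2)
  b <- bin_effects(deltas)
  bins <- do.call(rbind, lapply(sort(unique(b)), function(bb) {
    idx <- b == bb
    p <- mean(is_common[idx])
    data.frame(bin = bb, n = sum(idx), freq = p,
               se = sqrt(p * (1 - p) / sum(idx)))
  }))
  structure(list(z_pos = pos$z, z_neg = neg$z, z = z,
                 arm_flags = c(pos = pos$flag, neg = neg$flag),
                 bins = bins),
            class = "ConstraintResult")
}

#' Constraint scan across sequence classes
#'
#' Applies [constraint_zscore()] per class and BH-adjusts the one-sided
#' p-values `P(Z > z)` across classes (constraint is directional:
#' positive z means depletion of common variants at strong effects).
#'
#' @param delta_matrix `n x n_classes` signed effect matrix.
#' @param af allele frequencies aligned with rows.
#' @param common_threshold AF threshold.
#' @param exclude_classes classes skipped.
#' @return data.frame (`class`, `z_pos`, `z_neg`, `z`, `p`, `q`).
#' @export
constraint_scan <- function(delta_matrix, af, common_threshold = 0.01,
                            exclude_classes = character()) {
  classes <- setdiff(colnames(delta_matrix), exclude_classes)
  rows <- lapply(classes, function(cl) {
    r <- constraint_zscore(delta_matrix[, cl], af, common_threshold)
    data.frame(class = cl, z_pos = r$z_pos, z_neg = r$z_neg, z = r$z,
               p = if (is.na(r$z)) NA_real_ else pnorm(-r$z),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Export a nonoverlapping per-class annotation table (ldsc-style)
#'
#' Each variant site receives exactly one class indicator (or all zeros
#' when it falls outside the annotation) plus an all-ones `base` column.
#' Columns follow the `.annot` convention: `CHR`, `BP`, `SNP`, `CM`, then
#' annotations.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param variant_sites data.frame with `contig`, `pos` (1-based) and
#'   optionally `id`.
#' @param classes annotation columns to emit (default: classes present).
#' @return data.frame; attribute `n_unannotated` counts variants with
#'   all-zero class indicators.
#' @export
export_ldsc_annot <- function(annotation, variant_sites, classes = NULL) {
  if (is.null(classes))
    classes <- setdiff(unique(annotation$class), "unassigned")
  ann_by_contig <- split(seq_len(nrow(annotation)), annotation$contig)
  n <- nrow(variant_sites)
  out <- data.frame(
    CHR = variant_sites$contig, BP = variant_sites$pos,
    SNP = if ("id" %in% colnames(variant_sites)) variant_sites$id
          else sprintf("snp%d", seq_len(n)),
    CM = 0, base = 1L, stringsAsFactors = FALSE)
  M <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    p0 <- variant_sites$pos[i] - 1L
    rows <- ann_by_contig[[variant_sites$contig[i]]]
    if (is.null(rows)) next
    hit <- rows[annotation$start[rows] <= p0 & p0 < annotation$end[rows]]
    if (length(hit)) {
      cl <- annotation$class[hit[1L]]
      if (cl %in% classes) M[i, cl] <- 1L
    }
  }
  out <- cbind(out, as.data.frame(M))
  attr(out, "n_unannotated") <- sum(rowSums(M) == 0)
  out
}

#' Conservative heritability-proportion estimator
#'
#' `max(0, estimate - se)`: one standard error below the point estimate,
#' lower-bounded by zero.
#'
#' @param estimate estimated proportion(s) of h2.
#' @param se standard error(s), nonnegative.
#' @return conservative proportion(s).
#' @export
conservative_h2 <- function(estimate, se) {
  if (any(se < 0)) stop("se must be nonnegative")
  pmax(0, estimate - se)
}

#' Parse partitioned-heritability results into conservative estimates
#'
#' Reads the standard `.results` table of an LD-score-regression run
#' (columns `Category`, `Prop._h2`, `Prop._h2_std_error`, optionally
#' `Enrichment_p`) and applies [conservative_h2()].
#'
#' @param path path to the results TSV.
#' @return data.frame (`class`, `estimate`, `se`, `conservative`).
#' @export
parse_ldsc_results <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Category", "Prop._h2", "Prop._h2_std_error")
  if (!all(need %in% colnames(df)))
    stop("results file lacks columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  data.frame(class = df$Category, estimate = df$Prop._h2,
             se = df$Prop._h2_std_error,
             conservative = conservative_h2(df$Prop._h2,
                                            df$Prop._h2_std_error),
             stringsAsFactors = FALSE)
}

#' Stouffer combination of two z-scores (equal weights)
#'
#' @param z1,z2 z-scores.
#' @return `(z1 + z2) / sqrt(2)`.
#' @export
stouffer <- function(z1, z2) (z1 + z2) / sqrt(2)
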