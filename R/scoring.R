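# Sequence-class scores and directional variant effects.
#
# score_{s,i} = p_s . v_i projects a prediction vector onto class i's
# unit vector; a variant's class-level effect is score_Alt - score_Ref
# computed on variant-centered windows, after rescaling histone-mark
# predictions so that allele-level shifts in total nucleosome occupancy
# do not masquerade as histone-mark changes.

#' Sequence-class scores of prediction vectors
#'
#' @param p a prediction vector of length `T`, or an `n x T` matrix.
#' @param scm a `SequenceClassModel`.
#' @return named score vector (or `n x n_classes` matrix): dot products
#'   with each kept class vector.
#' @export
class_score <- function(p, scm) {
  V <- scm$vectors
  if (is.matrix(p)) {
    if (ncol(p) != ncol(V))
      stop("prediction has ", ncol(p), " targets, model expects ", ncol(V))
    return(p %*% t(V))
  }
  if (length(p) != ncol(V))
    stop("prediction has ", length(p), " targets, model expects ", ncol(V))
  # same multiplication order as the matrix branch, so a row of the
  # matrix form and the vector form agree bit-for-bit
  drop(matrix(p, 1L) %*% t(V))
}

#' Nucleosome-occupancy normalization of histone-mark predictions
#'
#' The summed histone predictions of an allele approximate its nucleosome
#' occupancy.  With `S_R` and `S_A` the histone sums of the Ref and Alt
#' alleles, histone entries are rescaled as
#' `p_ref* = p_ref * (S_R + S_A) / (2 S_R)` and
#' `p_alt* = p_alt * (S_R + S_A) / (2 S_A)`, so both adjusted alleles have
#' histone sum `(S_R + S_A) / 2`; non-histone entries are unchanged.
#'
#' @param p_ref,p_alt prediction vectors (length `T`).
#' @param histone_mask logical mask over the `T` targets.
#' @return list with adjusted `p_ref` and `p_alt`.
#' @export
adjust_histone <- function(p_ref, p_alt, histone_mask) {
  if (!any(histone_mask)) return(list(p_ref = p_ref, p_alt = p_alt))
  s_r <- sum(p_ref[histone_mask])
  s_a <- sum(p_alt[histone_mask])
  if (s_r == 0 || s_a == 0)
    stop("histone prediction sum is zero for ",
         if (s_r == 0) "Ref" else "Alt",
         " allele; occupancy normalization undefined")
  tot <- s_r + s_a
  p_ref[histone_mask] <- p_ref[histone_mask] * tot / (2 * s_r)
  p_alt[histone_mask] <- p_alt[histone_mask] * tot / (2 * s_a)
  list(p_ref = p_ref, p_alt = p_alt)
}

#' Sequence-class-level variant effects
#'
#' For each variant: build the Ref and Alt window sequences centered on
#' the variant, predict chromatin profiles for both, apply the histone
#' occupancy normalization, project both onto the class vectors, and
#' report per-class `delta = score_Alt - score_Ref` (positive = increased
#' class activity).  For indels the Alt window is re-centered on the
#' midpoint of the substituted allele and trimmed/padded to `L`.
#'
#' @param model a trained `chrom_model`.
#' @param scm a `SequenceClassModel` (provides class vectors and the
#'   histone mask).
#' @param variants a [VariantTable].
#' @param genome a [GenomeSequence]; `ref` alleles must match it.
#' @param batch_size prediction batch size.
#' @param adjust apply [adjust_histone()] (default `TRUE`); if the
#'   normalization is undefined for a variant (zero histone sum) the
#'   unadjusted predictions are used and the variant is flagged.
#' @return data.frame of class `VariantEffectTable`: variant columns, one
#'   `delta_<class>` column per kept class, plus `score_ref_<class>` /
#'   `score_alt_<class>` matrices as attributes.
#' @export
variant_effect <- function(model, scm, variants, genome, batch_size = 64L,
                           adjust = TRUE) {
  cfg <- model$config
  L <- cfg$L; half <- L %/% 2L
  n <- nrow(variants)
  ref_seqs <- character(n); alt_seqs <- character(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    p0 <- v$pos - 1L  # 0-based position of first ref base
    ctg_len <- genome$lengths[[v$contig]]
    if (is.null(ctg_len)) stop("unknown contig: ", v$contig)
    ref_obs <- get_seq(genome, v$contig, p0, p0 + nchar(v$ref))
    if (ref_obs != v$ref)
      stop(sprintf("ref allele mismatch at %s:%d (genome %s, variant %s)",
                   v$contig, v$pos, ref_obs, v$ref))
    start <- p0 - half
    if (start < 0 || p0 + half > ctg_len)
      stop(sprintf("window out of bounds for variant at %s:%d",
                   v$contig, v$pos))
    ref_seqs[i] <- get_seq(genome, v$contig, start, start + L)
    if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
      s <- ref_seqs[i]
      substr(s, half + 1L, half + 1L) <- v$alt
      alt_seqs[i] <- s
    } else {
      # indel: substitute, then take L bp centered on the alt allele midpoint
      flank <- half + max(nchar(v$ref), nchar(v$alt)) + 1L
      a <- max(0L, p0 - flank)
      b <- min(ctg_len, p0 + nchar(v$ref) + flank)
      region <- get_seq(genome, v$contig, a, b)
      rel <- p0 - a  # 0-based offset of ref within region
      alt_region <- paste0(substr(region, 1L, rel), v$alt,
                           substr(region, rel + nchar(v$ref) + 1L,
                                  nchar(region)))
      mid <- rel + ceiling(nchar(v$alt) / 2)
      s0 <- mid - half
      if (s0 < 0 || s0 + L > nchar(alt_region))
        stop(sprintf("indel window out of bounds at %s:%d", v$contig, v$pos))
      alt_seqs[i] <- substr(alt_region, s0 + 1L, s0 + L)
    }
  }
  p_ref <- predict(model, ref_seqs, batch_size = batch_size)
  p_alt <- predict(model, alt_seqs, batch_size = batch_size)
  hmask <- scm$histone_mask
  if (adjust && any(hmask)) {
    for (i in seq_len(n)) {
      adjusted <- tryCatch(
        adjust_histone(p_ref[i, ], p_alt[i, ], hmask),
        error = function(e) NULL)
      if (!is.null(adjusted)) {
        p_ref[i, ] <- adjusted$p_ref
        p_alt[i, ] <- adjusted$p_alt
      }
    }
  }
  s_ref <- class_score(p_ref, scm)
  s_alt <- class_score(p_alt, scm)
  delta <- s_alt - s_ref
  out <- cbind(as.data.frame(variants),
               setNames(as.data.frame(delta),
                        paste0("delta_", scm$kept$class)))
  class(out) <- c("VariantEffectTable", "data.frame")
  attr(out, "score_ref") <- s_ref
  attr(out, "score_alt") <- s_alt
  attr(out, "classes") <- scm$kept$class
  out
}

#' Extract the per-class delta matrix from a `VariantEffectTable`
#'
#' @param effects a `VariantEffectTable`.
#' @return `n x n_classes` matrix with class names.
#' @export
effect_deltas <- function(effects) {
  cls <- attr(effects, "classes")
  m <- as.matrix(effects[, paste0("delta_", cls), drop = FALSE])
  colnames(m) <- cls
  m
}

#' Assign variants to sequence classes with effect-based reassignment
#'
#' A variant starts from the positional class given by the genome
#' annotation at its position.  It is reassigned to the class with the
#' largest absolute effect iff that class differs and BOTH
#' `|delta_best| - |delta_orig| > abs_gap` AND
#' `|delta_best| / |delta_orig| > fold_gap` hold (`|delta_orig| = 0` with
#' `|delta_best| > abs_gap` counts as satisfied: the limit of the rule).
#' Excluded (low-interpretability) classes are never reassignment
#' candidates.  Positions outside the annotation that do not qualify for
#' reassignment stay `"unassigned"`.
#'
#' @param effects a `VariantEffectTable`.
#' @param annotation a `GenomeAnnotation`.
#' @param abs_gap absolute-difference threshold (default 1).
#' @param fold_gap fold-ratio threshold (default 2.5).
#' @param exclude_classes class ids excluded from candidacy (e.g. low
#'   signal classes).
#' @return the `VariantEffectTable` with `assigned_class` and `provenance`
#'   (`"positional"` / `"reassigned"`) columns.
#' @export
assign_mutation_class <- function(effects, annotation, abs_gap = 1,
                                  fold_gap = 2.5,
                                  exclude_classes = character()) {
  delta <- effect_deltas(effects)
  cand <- setdiff(colnames(delta), exclude_classes)
  if (!length(cand)) stop("no candidate classes remain after exclusion")
  ann_ir <- .iranges_by_contig(annotation)
  ann_by_contig <- split(seq_len(nrow(annotation)), annotation$contig)
  assigned <- character(nrow(effects))
  prov <- character(nrow(effects))
  for (i in seq_len(nrow(effects))) {
    p0 <- effects$pos[i] - 1L
    cn <- effects$contig[i]
    pos_class <- "unassigned"
    rows <- ann_by_contig[[cn]]
    if (!is.null(rows)) {
      hit <- rows[annotation$start[rows] <= p0 & p0 < annotation$end[rows]]
      if (length(hit)) pos_class <- annotation$class[hit[1L]]
    }
    d <- abs(delta[i, cand])
    best <- cand[which.max(d)]
    d_best <- max(d)
    d_orig <- if (pos_class %in% colnames(delta)) abs(delta[i, pos_class])
              else 0
    reassign <- best != pos_class &&
      (d_best - d_orig > abs_gap) &&
      (d_orig == 0 || d_best / d_orig > fold_gap)
    if (reassign) {
      assigned[i] <- best; prov[i] <- "reassigned"
    } else {
      assigned[i] <- pos_class
      prov[i] <- "positional"
    }
  }
  effects$assigned_class <- assigned
  effects$provenance <- prov
  effects
}

#' Write a variant-effect table to TSV
#'
#' @param effects a `VariantEffectTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  write.table(as.data.frame(effects), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
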