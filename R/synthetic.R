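# Synthetic cohort generators.
#
# Every downstream stage of the package (training, clustering, scoring,
# population-genetics statistics) is exercised on data from these
# generators: a small multi-contig genome with planted, motif-driven
# cell-type-specific regulatory elements; peak profiles over those
# elements; variants whose allele frequencies are coupled to regulatory
# effect magnitude; tissue expression with enhancer-proximity structure;
# and planted-cluster prediction matrices.

#' Define a regulatory grammar
#'
#' One element kind per cell type: kind `i` carries motif `i` and is active
#' only in cell type `i`, so cell-type specificity is encoded in sequence
#' (the only information a sequence model can use).  Motifs are
#' column-stochastic position weight matrices with a dominant base per
#' column.
#'
#' @param cell_types character vector of cell-type names.
#' @param motif_width motif width in bp.
#' @param dominance probability of the dominant base at each motif
#'   position: a scalar for uniform-information motifs, or a length-2
#'   range `c(lo, hi)` from which each column's dominance is drawn
#'   (realistic motifs mix high- and low-information positions, which
#'   also grades variant effect magnitudes).
#' @param tf_half_width half-width of TF/accessibility peaks (bp); such
#'   peaks are narrow (hundreds of bp) as in real assays.
#' @param histone_half_width half-width of histone-mark peaks (bp); broad
#'   (1-2 kb), which the nucleosome-occupancy normalization logic assumes.
#' @param seed RNG seed for motif generation.
#' @return an object of class `RegulatoryGrammar`.
#' @export
regulatory_grammar <- function(cell_types = c("liver", "brain", "blood", "stem"),
                               motif_width = 10L, dominance = 0.88,
                               tf_half_width = 150L,
                               histone_half_width = 750L, seed = 1L) {
  stopifnot(length(cell_types) >= 1, motif_width >= 4)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  motifs <- lapply(seq_along(cell_types), function(i) {
    d <- if (length(dominance) == 2L)
      runif(motif_width, dominance[1], dominance[2])
    else rep_len(dominance, motif_width)
    pwm <- matrix(rep((1 - d) / 3, each = 4), nrow = 4,
                  dimnames = list(bases, NULL))
    dom <- sample.int(4, motif_width, replace = TRUE)
    pwm[cbind(dom, seq_len(motif_width))] <- d
    pwm
  })
  elements <- lapply(seq_along(cell_types), function(i)
    list(kind = paste0("enh_", cell_types[i]), motif = i,
         cell_types = cell_types[i], half_width = as.integer(tf_half_width)))
  structure(list(motifs = motifs, cell_types = cell_types,
                 elements = elements,
                 tf_half_width = as.integer(tf_half_width),
                 histone_half_width = as.integer(histone_half_width)),
            class = "RegulatoryGrammar")
}

# sample a sequence from a PWM
.sample_motif <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(ncol(pwm)),
               function(j) sample(bases, 1L, prob = pwm[, j]),
               character(1)), collapse = "")
}

# log-odds score of base b at motif column j vs uniform background
.pwm_logodds <- function(pwm, j, base) {
  log(pwm[base, j] / 0.25)
}

#' Generate a synthetic genome with planted regulatory elements
#'
#' Background bases are i.i.d. with the requested GC content; motif
#' instances are planted at element centers.
#'
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig (bp).
#' @param gc GC fraction in `(0, 1)`.
#' @param seed RNG seed; runs are bit-reproducible.
#' @param grammar a [regulatory_grammar()]; `NULL` for no planted elements.
#' @param elements_per_contig planted elements per contig.
#' @param margin minimum distance of an element center from contig ends.
#' @return a list of class `SyntheticGenome` with `genome`
#'   ([GenomeSequence]), `truth` (data.frame: contig, center, kind,
#'   cell_type, motif, motif_start, motif_end) and `grammar`.
#' @export
gen_genome <- function(n_contigs = 3L, contig_len = 50000L, gc = 0.5,
                       seed = 1L, grammar = regulatory_grammar(),
                       elements_per_contig = 30L, margin = 2000L) {
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0,1)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contigs <- setNames(vapply(seq_len(n_contigs), function(i)
    paste(sample(bases, contig_len, replace = TRUE, prob = p), collapse = ""),
    character(1)), paste0("ctg", seq_len(n_contigs)))
  truth <- NULL
  if (!is.null(grammar) && elements_per_contig > 0) {
    rows <- list()
    for (cn in names(contigs)) {
      # spaced element centers: sample until pairwise distance > 2*spacing
      lo <- margin; hi <- contig_len - margin
      centers <- sort(sample(seq.int(lo, hi), elements_per_contig))
      # enforce a minimal 800-bp separation by jittered regular placement
      # when the random draw collides
      if (any(diff(centers) < 800)) {
        grid <- seq.int(lo, hi, length.out = elements_per_contig)
        centers <- as.integer(round(grid + runif(elements_per_contig, -200, 200)))
      }
      kinds <- sample(seq_along(grammar$elements), elements_per_contig,
                      replace = TRUE)
      for (j in seq_along(centers)) {
        el <- grammar$elements[[kinds[j]]]
        pwm <- grammar$motifs[[el$motif]]
        inst <- .sample_motif(pwm)
        w <- nchar(inst)
        m_start <- centers[j] - w %/% 2L          # 0-based
        substr(contigs[[cn]], m_start + 1L, m_start + w) <- inst
        ib <- strsplit(inst, "")[[1]]
        score <- sum(log(pwm[cbind(match(ib, rownames(pwm)),
                                   seq_len(w))] / 0.25))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, center = centers[j], kind = el$kind,
          cell_type = el$cell_types[[1]], motif = el$motif,
          motif_start = m_start, motif_end = m_start + w,
          inst_score = score, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
  }
  if (is.null(truth))
    truth <- data.frame(contig = character(), center = integer(),
                        kind = character(), cell_type = character(),
                        motif = integer(), motif_start = integer(),
                        motif_end = integer(), inst_score = numeric(),
                        stringsAsFactors = FALSE)
  structure(list(genome = GenomeSequence(contigs), truth = truth,
                 grammar = grammar),
            class = "SyntheticGenome")
}

#' Generate a chromatin-profile compendium over a synthetic genome
#'
#' For each cell type, emits TF profiles (one per motif targeting that cell
#' type, with `n_tf_rep` replicates), one accessibility profile and
#' `n_histone` histone-mark profiles.  True peaks are centered on planted
#' elements active in the profile's cell type; histone peaks are broad,
#' TF/accessibility peaks narrow.  False peaks are added at a Poisson rate.
#'
#' @param sg a `SyntheticGenome` from [gen_genome()].
#' @param n_tf_rep TF replicate profiles per cell type.
#' @param n_histone histone-mark profiles per cell type.
#' @param n_accessibility accessibility profiles per cell type.
#' @param noise expected number of false peaks per profile per contig.
#' @param graded if `TRUE`, an element's peak enters each profile
#'   independently with probability [element_inclusion_prob()] of its
#'   planted instance's motif score, emulating compendia where weak
#'   binding sites are detected in fewer experiments; if `FALSE`
#'   (default) every active element peaks in every matching profile.
#' @param seed RNG seed.
#' @return an object of class `ProfileCompendium`: list with `peaks` (named
#'   list of [IntervalSet]) and `meta` (data.frame: profile_id, target,
#'   assay_class, cell_type).
#' @export
gen_profiles <- function(sg, n_tf_rep = 2L, n_histone = 2L,
                         n_accessibility = 1L, noise = 0, graded = FALSE,
                         seed = 1L) {
  stopifnot(inherits(sg, "SyntheticGenome"))
  set.seed(seed)
  gr <- sg$grammar
  genome <- sg$genome
  truth <- sg$truth
  peaks <- list(); meta <- list()
  add_profile <- function(id, target, assay, cell, centers, contigs, half,
                          scores = NULL) {
    if (graded && length(centers) && !is.null(scores)) {
      keep <- runif(length(centers)) < element_inclusion_prob(scores)
      centers <- centers[keep]; contigs <- contigs[keep]
    }
    if (length(centers)) {
      start <- pmax(0, centers - half)
      end <- pmin(genome$lengths[contigs], centers + half)
      iv <- IntervalSet(contigs, start, end)
    } else iv <- IntervalSet()
    if (noise > 0) {
      for (cn in names(genome$contigs)) {
        nf <- rpois(1L, noise)
        if (nf > 0) {
          c0 <- sample.int(genome$lengths[[cn]] - 2L * half - 2L, nf) + half
          iv <- rbind(iv, IntervalSet(rep(cn, nf), c0 - half, c0 + half))
        }
      }
    }
    class(iv) <- c("IntervalSet", "data.frame")
    peaks[[id]] <<- iv
    meta[[length(meta) + 1L]] <<- data.frame(
      profile_id = id, target = target, assay_class = assay,
      cell_type = cell, stringsAsFactors = FALSE)
  }
  for (ct in gr$cell_types) {
    act <- truth[truth$cell_type == ct, , drop = FALSE]
    mot <- unique(vapply(gr$elements[vapply(gr$elements, function(e)
      ct %in% e$cell_types, logical(1))], function(e) e$motif, integer(1)))
    for (m in mot) {
      sel <- act[act$motif == m, , drop = FALSE]
      for (r in seq_len(n_tf_rep))
        add_profile(sprintf("TF_m%d_%s_r%d", m, ct, r),
                    target = paste0("motif", m), assay = "TF", cell = ct,
                    centers = sel$center, contigs = sel$contig,
                    half = gr$tf_half_width, scores = sel$inst_score)
    }
    for (r in seq_len(n_accessibility))
      add_profile(sprintf("ACC_%s_r%d", ct, r), target = "accessibility",
                  assay = "accessibility", cell = ct,
                  centers = act$center, contigs = act$contig,
                  half = gr$tf_half_width, scores = act$inst_score)
    for (r in seq_len(n_histone))
      add_profile(sprintf("HM_%s_r%d", ct, r),
                  target = paste0("H3Kmark", r), assay = "histone",
                  cell = ct, centers = act$center, contigs = act$contig,
                  half = gr$histone_half_width, scores = act$inst_score)
  }
  structure(list(peaks = peaks, meta = do.call(rbind, meta)),
            class = "ProfileCompendium")
}

#' @export
print.ProfileCompendium <- function(x, ...) {
  cat("ProfileCompendium:", length(x$peaks), "profiles\n")
  print(table(x$meta$assay_class))
  invisible(x)
}

#' Drop profiles with too few peaks
#'
#' Mirrors the training-compendium rule that profiles with fewer than 1,000
#' peaks are excluded; the threshold is configurable for desk-scale data.
#'
#' @param comp a `ProfileCompendium`.
#' @param min_peaks minimum peak count to keep a profile.
#' @return filtered `ProfileCompendium`.
#' @export
filter_compendium <- function(comp, min_peaks = 1000L) {
  keep <- vapply(comp$peaks, nrow, integer(1)) >= min_peaks
  structure(list(peaks = comp$peaks[keep],
                 meta = comp$meta[comp$meta$profile_id %in%
                                    names(comp$peaks)[keep], , drop = FALSE]),
            class = "ProfileCompendium")
}

#' Peak-inclusion probability of a planted element
#'
#' Maps a motif-instance log-odds score to the probability that the
#' element's peak is called in any one profile:
#' `plogis(slope * (score - center))`.  Defaults put a consensus match of
#' a sharp 10-bp motif (score ~13) near certainty and a 2-3-mismatch
#' instance near 0.5, so peak compendia grade smoothly with binding
#' strength.
#'
#' @param score motif log-odds score(s) of the planted instance.
#' @param center score at which inclusion is 50% (default 9).
#' @param slope logistic steepness per score unit (default 0.8).
#' @return probabilities in `(0, 1)`.
#' @export
element_inclusion_prob <- function(score, center = 9, slope = 0.8) {
  plogis(slope * (score - center))
}

#' Simulate allele frequencies coupled to effect magnitude
#'
#' The probability that a variant is common (AF > 0.01) follows a logistic
#' model `P(common) = plogis(a - b * |effect|)`; `b = 0` is the null (AF
#' independent of effect).  Common variants draw AF uniformly from
#' (0.011, 0.5), rare ones from (1e-4, 0.009).
#'
#' @param effects numeric vector of (signed) regulatory effects.
#' @param a intercept on the logit scale; default gives a ~30% common
#'   fraction at zero effect.
#' @param b depletion strength per unit `|effect|`.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return numeric vector of allele frequencies in `[0, 1]`.
#' @export
sim_variant_af <- function(effects, a = -0.85, b = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_common <- plogis(a - b * abs(effects))
  is_common <- rbinom(length(effects), 1L, p_common) == 1L
  af <- numeric(length(effects))
  af[is_common] <- runif(sum(is_common), 0.011, 0.5)
  af[!is_common] <- runif(sum(!is_common), 1e-4, 0.009)
  af
}

#' Generate variants with effect-coupled allele frequencies
#'
#' SNVs are placed uniformly over the genome.  A variant falling inside a
#' planted motif gets a signed true effect equal to the log-odds change of
#' the motif match (alt minus ref); elsewhere the true effect is 0.  Allele
#' frequencies are then drawn via [sim_variant_af()].
#'
#' @param sg a `SyntheticGenome`.
#' @param n number of variants.
#' @param af_model list with logistic parameters `a` and `b` (see
#'   [sim_variant_af()]).
#' @param seed RNG seed.
#' @return a [VariantTable] with an extra `true_effect` column.
#' @export
gen_variants <- function(sg, n, af_model = list(a = -0.85, b = 1.5),
                         seed = 1L) {
  stopifnot(inherits(sg, "SyntheticGenome"))
  set.seed(seed)
  if (n == 0)
    return(VariantTable(character(), integer(), character(), character()))
  genome <- sg$genome
  bases <- c("A", "C", "G", "T")
  lens <- genome$lengths
  cum <- cumsum(as.numeric(lens))
  u <- sample.int(sum(lens), n, replace = TRUE)
  ci <- findInterval(u - 1, c(0, cum[-length(cum)])) # contig index
  pos0 <- u - c(0, cum)[ci] - 1L                     # 0-based position
  contig <- names(lens)[ci]
  ref <- character(length(pos0))
  for (cn in unique(contig)) {
    i <- contig == cn
    ref[i] <- substring(genome$contigs[[cn]], pos0[i] + 1L, pos0[i] + 1L)
  }
  # avoid N positions
  okN <- ref %in% bases
  contig <- contig[okN]; pos0 <- pos0[okN]; ref <- ref[okN]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  effect <- numeric(length(pos0))
  tr <- sg$truth
  if (nrow(tr)) {
    for (i in seq_along(pos0)) {
      hit <- which(tr$contig == contig[i] & tr$motif_start <= pos0[i] &
                     pos0[i] < tr$motif_end)
      if (length(hit)) {
        h <- hit[1L]
        pwm <- sg$grammar$motifs[[tr$motif[h]]]
        j <- pos0[i] - tr$motif_start[h] + 1L
        effect[i] <- .pwm_logodds(pwm, j, alt[i]) -
                     .pwm_logodds(pwm, j, ref[i])
      }
    }
  }
  af <- sim_variant_af(effect, a = af_model$a, b = af_model$b, seed = NULL)
  v <- VariantTable(contig, pos0 + 1L, ref, alt, af = af,
                    id = sprintf("var%06d", seq_along(pos0)))
  v$true_effect <- effect
  v
}

#' Generate tissue expression with enhancer-proximity structure
#'
#' Each synthetic gene gets a TSS placed uniformly on the genome; its
#' (RPKM-like, nonnegative) expression in tissue `t` is
#' `exp(baseline + effect_size * n_enh(t) + noise)` where `n_enh(t)` counts
#' that tissue's planted enhancers within `window` bp of the TSS.
#'
#' @param sg a `SyntheticGenome`.
#' @param n_genes number of genes.
#' @param effect_size log-scale expression boost per nearby enhancer; 0 is
#'   the null.
#' @param noise_sd log-scale noise s.d.
#' @param window proximity window in bp (default 10 kb each side).
#' @param seed RNG seed.
#' @return list with `expr` (gene x tissue matrix) and `tss` (data.frame:
#'   gene, contig, pos).
#' @export
gen_expression <- function(sg, n_genes = 200L, effect_size = 1,
                           noise_sd = 0.2, window = 10000L, seed = 1L) {
  stopifnot(inherits(sg, "SyntheticGenome"))
  set.seed(seed)
  genome <- sg$genome
  tissues <- sg$grammar$cell_types
  if (n_genes == 0)
    return(list(expr = matrix(numeric(), 0, length(tissues),
                              dimnames = list(NULL, tissues)),
                tss = data.frame(gene = character(), contig = character(),
                                 pos = integer())))
  lens <- genome$lengths
  contig <- sample(names(lens), n_genes, replace = TRUE,
                   prob = as.numeric(lens) / sum(lens))
  pos <- vapply(contig, function(cn) sample.int(lens[[cn]], 1L) - 1L,
                integer(1))
  tss <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                    contig = contig, pos = pos, stringsAsFactors = FALSE)
  baseline <- rnorm(n_genes, mean = 1, sd = 0.5)
  tr <- sg$truth
  expr <- matrix(0, n_genes, length(tissues),
                 dimnames = list(tss$gene, tissues))
  for (t in seq_along(tissues)) {
    cnt <- vapply(seq_len(n_genes), function(g) {
      as.numeric(sum(tr$cell_type == tissues[t] & tr$contig == contig[g] &
                       abs(tr$center - pos[g]) <= window))
    }, numeric(1))
    expr[, t] <- exp(baseline + effect_size * cnt +
                       rnorm(n_genes, sd = noise_sd))
  }
  list(expr = expr, tss = tss)
}

#' Generate a prediction matrix with planted cluster structure
#'
#' Rows are cluster-specific mean probability vectors plus Gaussian noise,
#' clipped into `[0, 1]`.  Cluster means sit at
#' `0.5 +/- separation * noise_sd / 2` per coordinate (random signs), so
#' `separation` measures the between-center distance in noise-s.d. units;
#' `separation = 0` collapses all clusters onto one center.
#'
#' @param n_points number of rows.
#' @param n_profiles number of columns (targets).
#' @param n_clusters number of planted clusters.
#' @param separation center separation in units of `noise_sd`.
#' @param noise_sd per-coordinate noise s.d.
#' @param seed RNG seed.
#' @return list with `X` (matrix in `[0,1]`) and `labels` (integer truth).
#' @export
gen_prediction_matrix <- function(n_points, n_profiles, n_clusters,
                                  separation, noise_sd = 0.1, seed = 1L) {
  stopifnot(separation >= 0, n_clusters >= 1)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_clusters * n_profiles, replace = TRUE),
                  n_clusters, n_profiles)
  centers <- 0.5 + separation * noise_sd / 2 * signs
  labels <- sort(rep_len(seq_len(n_clusters), n_points))
  X <- centers[labels, , drop = FALSE] +
    matrix(rnorm(n_points * n_profiles, sd = noise_sd), n_points, n_profiles)
  X <- pmin(pmax(X, 0), 1)
  list(X = X, labels = labels)
}

#' Write a synthetic cohort to disk
#'
#' Emits the standard plain-text formats consumed by the pipeline: genome
#' FASTA, one BED file per profile plus a metadata TSV, a VCF of variants,
#' an expression TSV and a TSS TSV.
#'
#' @param dir output directory (created if needed).
#' @param preset `"small"` (3 x 50 kb contigs, 4 cell types) or `"tiny"`
#'   (3 x 15 kb, 2 cell types; for smoke tests).
#' @param seed master RNG seed; each generator derives its own stream.
#' @param noise false-peak rate passed to [gen_profiles()].
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
synthesize_cohort <- function(dir, preset = c("small", "tiny"), seed = 7L,
                              noise = 0.5) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  par <- switch(preset,
    small = list(n_contigs = 3L, contig_len = 50000L, epc = 30L,
                 cts = c("liver", "brain", "blood", "stem"),
                 n_var = 2000L, n_genes = 200L),
    tiny = list(n_contigs = 3L, contig_len = 15000L, epc = 8L,
                cts = c("liver", "brain"), n_var = 300L, n_genes = 50L))
  gr <- regulatory_grammar(cell_types = par$cts, seed = seed)
  sg <- gen_genome(n_contigs = par$n_contigs, contig_len = par$contig_len,
                   seed = seed + 1L, grammar = gr,
                   elements_per_contig = par$epc)
  comp <- gen_profiles(sg, noise = noise, seed = seed + 2L)
  vars <- gen_variants(sg, n = par$n_var, seed = seed + 3L)
  ex <- gen_expression(sg, n_genes = par$n_genes, seed = seed + 4L)

  paths <- list(genome = file.path(dir, "genome.fa"),
                meta = file.path(dir, "profiles.tsv"),
                vcf = file.path(dir, "variants.vcf"),
                expr = file.path(dir, "expression.tsv"),
                tss = file.path(dir, "tss.tsv"),
                truth = file.path(dir, "truth.tsv"),
                peaks_dir = file.path(dir, "peaks"))
  write_fasta(sg$genome, paths$genome)
  dir.create(paths$peaks_dir, showWarnings = FALSE)
  for (id in names(comp$peaks))
    write_bed(comp$peaks[[id]], file.path(paths$peaks_dir,
                                          paste0(id, ".bed")))
  write.table(comp$meta, paths$meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_vcf(vars, paths$vcf, genome = sg$genome)
  write.table(data.frame(gene = rownames(ex$expr), ex$expr,
                         check.names = FALSE),
              paths$expr, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ex$tss, paths$tss, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sg$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(sg = sg, compendium = comp, variants = vars,
                 expression = ex, paths = paths))
}
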