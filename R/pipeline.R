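# End-to-end miniature pipeline and run configuration.

#' Default run configuration
#'
#' Bundles every tunable threshold of the pipeline with its standard
#' default: 100-bp tiling step, 180 PCA components, k = 14 neighbors,
#' 40 retained classes, the >1 absolute / >2.5-fold reassignment rule,
#' AF > 0.01 common-variant threshold and top-15,000 eQTL selection.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param preset synthetic-cohort preset (`"small"` or `"tiny"`).
#' @param steps training steps.
#' @param ... overrides for any listed field.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 7L, preset = "small", steps = 300L, ...) {
  cfg <- list(seed = as.integer(seed), preset = preset,
              steps = as.integer(steps),
              step_bp = 100L, n_components = 180L, k = 14L, keep = 40L,
              abs_gap = 1, fold_gap = 2.5, af_common = 0.01,
              eqtl_top_n = 15000L, min_peaks = 10L,
              batch_size = 32L, lr = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$seed >= 2^31 - 10L) stop("seed too large")
  structure(cfg, class = "run_config")
}

#' Run the miniature end-to-end pipeline on a synthetic cohort
#'
#' Stages: synthesize cohort -> filter compendium -> train the miniature
#' sequence model (last contig held out for testing, second-to-last for
#' validation) -> tile + predict -> fit sequence classes -> annotate ->
#' variant effects -> constraint scan and eQTL correlation against the
#' cohort's planted truth.  Artifacts and a JSON manifest are written to
#' `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir) || !nzchar(out_dir))
    stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  seed <- config$seed
  cohort <- stage("synth",
                  synthesize_cohort(file.path(out_dir, "cohort"),
                                    preset = config$preset, seed = seed))
  comp <- filter_compendium(cohort$compendium,
                            min_peaks = config$min_peaks)
  genome <- cohort$sg$genome
  ctgs <- names(genome$contigs)
  holdout <- list(test = ctgs[length(ctgs)],
                  validation = ctgs[max(1L, length(ctgs) - 1L)])
  mcfg <- chrom_config_miniature(n_targets = length(comp$peaks),
                                 init_seed = seed)
  model <- stage("train", {
    m <- build_model(mcfg, profile_meta = comp$meta)
    train_chromnet(m, genome, comp, holdout = holdout,
                   steps = config$steps, batch_size = config$batch_size,
                   lr = config$lr, seed = seed + 10L, verbose = verbose)
  })
  tiles <- stage("tile", tile_genome(genome, mcfg$L,
                                     step = config$step_bp))
  preds <- stage("predict", {
    seqs <- vapply(seq_len(nrow(tiles)), function(i)
      get_seq(genome, tiles$contig[i], tiles$start[i], tiles$end[i]),
      character(1))
    predict(model, seqs)
  })
  scm <- stage("fit", fit_sequence_classes(
    preds, n_components = config$n_components, k = config$k,
    keep = config$keep, profile_meta = comp$meta, seed = seed + 20L))
  ann <- stage("annotate",
               annotate_genome(tiles, scm$labels, scm$kept,
                               bin = config$step_bp))
  write_bed(IntervalSet(ann$contig, ann$start, ann$end, name = ann$class),
            file.path(out_dir, "annotation.bed"))
  vars <- cohort$variants
  half <- mcfg$L %/% 2L
  fits <- vars$pos - 1L >= half &
    vars$pos - 1L + half <= genome$lengths[vars$contig]
  vars <- vars[fits, , drop = FALSE]
  eff <- stage("veffect", {
    e <- variant_effect(model, scm, vars, genome)
    assign_mutation_class(e, ann, abs_gap = config$abs_gap,
                          fold_gap = config$fold_gap)
  })
  write_effects(eff, file.path(out_dir, "variant_effects.tsv"))
  gen <- stage("genetics", {
    delta <- effect_deltas(eff)
    cs <- constraint_scan(delta, eff$af,
                          common_threshold = config$af_common)
    eq <- NULL
    if (any(vars$true_effect != 0)) {
      eq_tab <- data.frame(id = vars$id, slope = vars$true_effect)
      eq <- tryCatch(eqtl_correlation(eff, eq_tab,
                                      top_n = config$eqtl_top_n),
                     error = function(e) NULL)
    }
    list(constraint = cs, eqtl = eq)
  })
  write.table(gen$constraint, file.path(out_dir, "constraint.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("seqclass")),
    seed = seed, preset = config$preset, steps = config$steps,
    n_profiles = length(comp$peaks), n_tiles = nrow(tiles),
    n_classes = nrow(scm$kept), n_variants = nrow(vars),
    config = unclass(config),
    input_sha = vapply(unlist(cohort$paths[c("genome", "vcf", "meta")]),
                       function(p) as.character(tools::md5sum(p)),
                       character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, compendium = comp, model = model,
                 tiles = tiles, predictions = preds, scm = scm,
                 annotation = ann, effects = eff, genetics = gen,
                 manifest = manifest))
}
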