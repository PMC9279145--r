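# Shared fixtures.  The trained-model fixture is expensive (~8 min) and
# memoized so the training-recovery and directional-effect criteria share
# one run.
#
# The training cohort is the single-motif world: one regulatory element
# kind (a liver enhancer with one sharp 10-bp motif, per-column dominant
# base probability drawn from (0.92, 0.995)) planted 50 times per 50-kb
# contig, and 20 profiles over it (8 TF replicates, 4 accessibility,
# 8 histone).  The motif is sharp because even an exact position-aware
# PWM scanner tops out at AUROC ~0.90 on this geometry when the
# dominant-base probability is 0.88; with the (0.92, 0.995) columns the
# oracle ceiling is ~0.99, leaving the learner honest headroom, and the
# mixed column information grades true variant effects (needed for the
# directional eQTL criterion; see the methods vignette).  Peak inclusion
# is graded: weak instances appear in fewer profiles, so the world's
# true class-level effects are continuous rather than binary.  The last
# contig is held out for testing.

.fixture_env <- new.env(parent = emptyenv())

motif_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  gr <- regulatory_grammar(cell_types = "liver",
                           dominance = c(0.92, 0.995), seed = 7)
  sg <- gen_genome(n_contigs = 3, contig_len = 50000, seed = 8,
                   grammar = gr, elements_per_contig = 50)
  comp <- gen_profiles(sg, n_tf_rep = 8, n_histone = 8,
                       n_accessibility = 4, noise = 0.5, graded = TRUE,
                       seed = 9)
  .fixture_env$cohort <- list(sg = sg, comp = comp)
  .fixture_env$cohort
}

# miniature model trained on the cohort; ctg3 held out.  Strong weight
# decay counters memorization of the tiny genome.
trained_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  co <- motif_cohort()
  m <- build_model(chrom_config_miniature(length(co$comp$peaks),
                                          init_seed = 1),
                   profile_meta = co$comp$meta)
  m <- train_chromnet(m, co$sg$genome, co$comp,
                      holdout = list(test = "ctg3",
                                     validation = character()),
                      steps = 2000, batch_size = 32, lr = 0.003,
                      weight_decay = 1, seed = 2)
  .fixture_env$model <- m
  m
}

# held-out tiles, sequences, predictions and labels
heldout_eval <- function() {
  if (!is.null(.fixture_env$eval)) return(.fixture_env$eval)
  co <- motif_cohort()
  m <- trained_model()
  tiles <- tile_genome(co$sg$genome, m$config$L, step = 100)
  tiles <- tiles[tiles$contig == "ctg3", ]
  seqs <- vapply(seq_len(nrow(tiles)), function(i)
    get_seq(co$sg$genome, "ctg3", tiles$start[i], tiles$end[i]),
    character(1))
  P <- predict(m, seqs)
  Y <- make_labels(tiles, co$comp)
  .fixture_env$eval <- list(tiles = tiles, seqs = seqs, P = P, Y = Y)
  .fixture_env$eval
}

# sequence-class model fitted on tile predictions over the whole cohort
# genome (training + held-out contigs)
tile_scm <- function() {
  if (!is.null(.fixture_env$scm)) return(.fixture_env$scm)
  co <- motif_cohort()
  m <- trained_model()
  tiles <- tile_genome(co$sg$genome, m$config$L, step = 100)
  seqs <- vapply(seq_len(nrow(tiles)), function(i)
    get_seq(co$sg$genome, tiles$contig[i], tiles$start[i], tiles$end[i]),
    character(1))
  P <- predict(m, seqs)
  scm <- suppressWarnings(
    fit_sequence_classes(P, n_components = 10, k = 14, keep = 4,
                         profile_meta = co$comp$meta, seed = 3))
  .fixture_env$scm <- list(scm = scm, tiles = tiles)
  .fixture_env$scm
}

# build a VariantEffectTable by hand (for rule tests that need no model)
fake_effects <- function(delta, contig = "c1", pos = NULL, af = NULL,
                         id = NULL) {
  n <- nrow(delta)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  df <- data.frame(contig = rep(contig, n), pos = pos,
                   ref = rep("A", n), alt = rep("G", n),
                   af = if (is.null(af)) rep(NA_real_, n) else af,
                   id = if (is.null(id)) sprintf("v%d", seq_len(n)) else id,
                   stringsAsFactors = FALSE)
  out <- cbind(df, setNames(as.data.frame(delta),
                            paste0("delta_", colnames(delta))))
  class(out) <- c("VariantEffectTable", "data.frame")
  attr(out, "classes") <- colnames(delta)
  out
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
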