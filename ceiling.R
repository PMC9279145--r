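library(seqclass)
gr <- regulatory_grammar(cell_types = "liver", seed = 7, dominance = as.numeric(Sys.getenv("DOM","0.88")))
sg <- gen_genome(n_contigs = 3, contig_len = 50000, seed = 8, grammar = gr,
                 elements_per_contig = 50)
comp <- gen_profiles(sg, n_tf_rep = 8, n_histone = 8, n_accessibility = 4,
                     noise = 0.5, seed = 9)
tiles <- tile_genome(sg$genome, 512, step = 100)
tiles <- tiles[tiles$contig == "ctg3", ]
Y <- make_labels(tiles, comp)
pwm <- log(gr$motifs[[1]] / 0.25); w <- ncol(pwm)
seqs <- vapply(seq_len(nrow(tiles)), function(i)
  get_seq(sg$genome, "ctg3", tiles$start[i], tiles$end[i]), character(1))
half <- 256
sc <- vapply(seqs, function(s) {
  idx <- match(strsplit(s, "")[[1]], c("A","C","G","T"))
  best <- -Inf
  for (p in 1:(nchar(s)-w+1)) {
    mcen <- p + w %/% 2 - 1
    if (abs(mcen - half) <= 150) {
      v <- sum(pwm[cbind(idx[p:(p+w-1)], 1:w)])
      if (!is.na(v) && v > best) best <- v
    }
  }
  best
}, numeric(1))
cat("oracle AUROC TF profile:", auroc(sc, Y[,"TF_m1_liver_r1"]), "\n")
# also oracle for truth-only labels (ignoring noise peaks)
comp0 <- gen_profiles(sg, n_tf_rep = 1, n_histone = 0, n_accessibility = 0,
                      noise = 0, seed = 9)
Y0 <- make_labels(tiles, comp0)
cat("oracle AUROC noise-free:", auroc(sc, Y0[,1]), "\n")
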