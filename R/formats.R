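#' @importFrom stats rnorm runif rbinom rpois quantile sd var cor fisher.test
#'   p.adjust glm binomial coef pnorm setNames predict cor.test
#' @importFrom utils head tail write.table read.table
NULL

# ---- GenomeSequence ---------------------------------------------------------

#' Construct a genome sequence object
#'
#' A `GenomeSequence` is an ordered set of named contigs, each a nucleotide
#' string over the alphabet `A/C/G/T/N`.  All internal coordinates in this
#' package are 0-based half-open; 1-based conventions (VCF) are converted at
#' the boundary.
#'
#' @param contigs named character vector of nucleotide strings.
#' @return an object of class `GenomeSequence`.
#' @export
GenomeSequence <- function(contigs) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be uniquely named")
  contigs <- toupper(unlist(contigs))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) ", paste(names(contigs)[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N}")
  structure(list(contigs = contigs, lengths = nchar(contigs)),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x$contigs), "contig(s):\n")
  for (nm in names(x$contigs))
    cat(sprintf("  %s: %d bp\n", nm, x$lengths[[nm]]))
  invisible(x)
}

#' @export
length.GenomeSequence <- function(x) length(x$contigs)

#' Read a (multi-)FASTA file
#'
#' Sequences are uppercased on read; `N` bases are preserved.
#'
#' @param path path to a FASTA file.
#' @return a [GenomeSequence].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e)))
  contigs <- toupper(as.character(ss))
  # keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  GenomeSequence(contigs)
}

#' Write a genome to FASTA
#'
#' @param genome a [GenomeSequence].
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Extract a subsequence (0-based half-open)
#'
#' @param genome a [GenomeSequence].
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @return character scalar.
#' @export
get_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome$contigs)) stop("unknown contig: ", contig)
  L <- genome$lengths[[contig]]
  if (start < 0 || end > L || start >= end)
    stop(sprintf("invalid range [%d,%d) on %s (length %d)", start, end, contig, L))
  substr(genome$contigs[[contig]], start + 1L, end)
}

# ---- IntervalSet ------------------------------------------------------------

#' Construct an interval set
#'
#' BED-convention intervals: 0-based half-open `[start, end)` on named
#' contigs, with optional `name` and `score` columns.
#'
#' @param contig,start,end vectors of equal length.
#' @param name,score optional per-interval annotations.
#' @return an object of class `IntervalSet` (a data.frame subclass).
#' @export
IntervalSet <- function(contig = character(), start = integer(),
                        end = integer(), name = NULL, score = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) && any(start >= end))
    stop("interval start must be < end (record ",
         which(start >= end)[1L], ")")
  df <- data.frame(contig = as.character(contig), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Read a BED3+ file
#'
#' Tab-delimited, 0-based half-open.  Columns beyond the third are kept as
#' `name` and `score` when present.
#'
#' @param path path to a BED file.
#' @return an [IntervalSet].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(IntervalSet())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  bad <- which(dt[[2]] >= dt[[3]])
  if (length(bad))
    stop(sprintf("BED record with start >= end at line %d of %s", bad[1L], path))
  IntervalSet(dt[[1]], dt[[2]], dt[[3]],
              name = if (ncol(dt) >= 4) dt[[4]] else NULL,
              score = if (ncol(dt) >= 5) dt[[5]] else NULL)
}

#' Write an interval set to BED
#'
#' Coordinates round-trip bit-exactly through [read_bed()].
#'
#' @param x an [IntervalSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("contig", "start", "end",
            intersect(c("name", "score"), colnames(x)))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: IRanges representation of one contig's intervals, for fast overlap
.iranges_by_contig <- function(x) {
  if (nrow(x) == 0) return(list())
  sp <- split(seq_len(nrow(x)), x$contig)
  lapply(sp, function(i)
    IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
}

# internal: does 0-based position pos fall in any interval of x on contig?
.pos_in_intervals <- function(ir_list, contig, pos) {
  ir <- ir_list[[contig]]
  if (is.null(ir)) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  IRanges::overlapsAny(q, ir)
}

# ---- Variant ----------------------------------------------------------------

#' Construct variants
#'
#' Positions follow the VCF convention (1-based).  Alleles are nonempty
#' strings over `A/C/G/T`.
#'
#' @param contig,pos,ref,alt equal-length vectors.
#' @param af optional allele frequencies in `[0, 1]`.
#' @param id optional variant identifiers.
#' @return a data.frame of class `VariantTable`.
#' @export
VariantTable <- function(contig, pos, ref, alt, af = NA_real_,
                         id = NA_character_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("REF/ALT alleles must be nonempty")
  if (any(grepl("[^ACGT]", c(ref, alt))))
    stop("alleles restricted to {A,C,G,T}")
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("AF must lie in [0,1]")
  af <- rep_len(as.numeric(af), length(contig))
  id <- rep_len(as.character(id), length(contig))
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = ref, alt = alt, af = as.numeric(af),
                   id = as.character(id), stringsAsFactors = FALSE)
  class(df) <- c("VariantTable", "data.frame")
  df
}

#' Read variants from a VCF file
#'
#' One record is emitted per ALT allele (multi-allelic rows are split).  The
#' INFO key holding the allele frequency is configurable.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @param af_key INFO key carrying the allele frequency (default `"AF"`).
#' @return a [VariantTable].
#' @export
read_vcf <- function(path, af_key = "AF") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(VariantTable(character(), integer(), character(), character()))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(f) < 5) stop("VCF rows need >= 5 fields: ", path)
  info <- if (length(f) >= 8) f[[8]] else rep(".", length(body))
  patt <- paste0("(?:^|;)", af_key, "=([^;]+)")
  has <- grepl(patt, info, perl = TRUE)
  af_str <- rep(NA_character_, length(body))
  af_str[has] <- sub(patt, "\\1",
                     regmatches(info, regexpr(patt, info, perl = TRUE)),
                     perl = TRUE)
  alt_list <- strsplit(f[[5]], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  # AF is per-ALT (Number=A): align the comma list with the split alleles
  af_list <- lapply(seq_along(body), function(i) {
    if (is.na(af_str[i])) return(rep(NA_real_, n_alt[i]))
    vals <- suppressWarnings(as.numeric(strsplit(af_str[i], ",",
                                                 fixed = TRUE)[[1]]))
    rep_len(vals, n_alt[i])
  })
  idx <- rep(seq_along(body), n_alt)
  if (any(f[[4]] == ".") || any(unlist(alt_list) == "."))
    stop("missing REF or ALT allele in ", path)
  VariantTable(contig = f[[1]][idx], pos = as.integer(f[[2]][idx]),
               ref = f[[4]][idx], alt = unlist(alt_list),
               af = unlist(af_list),
               id = ifelse(f[[3]][idx] == ".", NA_character_, f[[3]][idx]))
}

#' Write variants to a minimal VCF 4.2 file
#'
#' @param variants a [VariantTable].
#' @param path output path.
#' @param genome optional [GenomeSequence] used to emit contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$contigs), genome$lengths))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(variants$af), ".",
                 sprintf("AF=%s", format(variants$af, scientific = FALSE,
                                         trim = TRUE)))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  variants$contig, variants$pos,
                  ifelse(is.na(variants$id), ".", variants$id),
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- Windows and tiling -----------------------------------------------------

#' Tile a genome into fixed-length centered windows
#'
#' Window centers are placed every `step` bp on each contig such that the
#' full window `[center - L/2, center + L/2)` lies inside the contig.
#' Windows overlapping `exclude` (e.g. a blacklist) or containing more than
#' `max_n_frac` fraction of `N` bases are dropped.
#'
#' @param genome a [GenomeSequence].
#' @param window_len window length `L` in bp (even).
#' @param step center spacing in bp.
#' @param exclude optional [IntervalSet] of regions to avoid; any overlap of
#'   the window span drops the window.
#' @param max_n_frac maximum tolerated fraction of `N` bases (default 0:
#'   windows with any `N` are dropped).
#' @return a data.frame of class `WindowSet` with columns `contig`, `center`,
#'   `start`, `end`, sorted by (contig order, center).
#' @export
tile_genome <- function(genome, window_len, step = 100L, exclude = NULL,
                        max_n_frac = 0) {
  if (window_len %% 2L != 0L) stop("window_len must be even")
  if (step < 1L) stop("step must be >= 1")
  half <- window_len %/% 2L
  ex_ir <- if (!is.null(exclude) && nrow(exclude)) .iranges_by_contig(exclude)
           else list()
  out <- lapply(names(genome$contigs), function(cn) {
    L <- genome$lengths[[cn]]
    if (L < window_len) return(NULL)
    # feasible centers: center - half >= 0 and center + half <= L
    centers <- seq.int(from = half, to = L - half, by = step)
    if (!length(centers)) return(NULL)
    keep <- rep(TRUE, length(centers))
    ir <- ex_ir[[cn]]
    if (!is.null(ir)) {
      q <- IRanges::IRanges(start = centers - half + 1L,
                            end = centers + half)
      keep <- keep & !IRanges::overlapsAny(q, ir)
    }
    # N masking: build N runs once per contig
    nr <- .n_runs(genome$contigs[[cn]])
    if (length(nr)) {
      q <- IRanges::IRanges(start = centers - half + 1L, end = centers + half)
      if (max_n_frac <= 0) {
        keep <- keep & !IRanges::overlapsAny(q, nr)
      } else {
        ov <- .overlap_bp(q, nr)
        keep <- keep & (ov / window_len <= max_n_frac)
      }
    }
    centers <- centers[keep]
    if (!length(centers)) return(NULL)
    data.frame(contig = cn, center = centers,
               start = centers - half, end = centers + half,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(contig = character(), center = integer(),
                      start = integer(), end = integer())
  class(res) <- c("WindowSet", "data.frame")
  attr(res, "window_len") <- as.integer(window_len)
  attr(res, "step") <- as.integer(step)
  res
}

# IRanges of N runs in a sequence (1-based)
.n_runs <- function(seqstr) {
  m <- gregexpr("N+", seqstr)[[1]]
  if (m[1] == -1) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(m),
                   width = attr(m, "match.length"))
}

# total overlap bp of each query range with subject ranges
.overlap_bp <- function(q, s) {
  out <- rep(0L, length(q))
  hits <- IRanges::findOverlaps(q, s)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  w <- pmin(IRanges::end(q)[qi], IRanges::end(s)[si]) -
       pmax(IRanges::start(q)[qi], IRanges::start(s)[si]) + 1L
  agg <- rowsum(w, qi)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Center base of an even-length window
#'
#' For a window `[start, start + L)` the designated center base is the one at
#' 0-based index `start + L/2`, i.e. the left base of the right half.
#'
#' @param window one row of a `WindowSet` (or any list with `start`, `end`).
#' @return 0-based position of the center base.
#' @export
window_center <- function(window) {
  as.integer(window$start + (window$end - window$start) %/% 2L)
}

#' Does the window's center base overlap a peak?
#'
#' @param window a single-row window (list/data.frame with `contig`, `start`,
#'   `end`).
#' @param peaks an [IntervalSet].
#' @return logical scalar.
#' @export
center_overlaps <- function(window, peaks) {
  ctr <- window_center(window)
  ir <- .iranges_by_contig(peaks)
  as.logical(.pos_in_intervals(ir, window$contig[[1]], ctr))
}

#' One-hot encode DNA sequences
#'
#' Rows are positions, columns the channels `A`, `C`, `G`, `T`.  `N` (or any
#' non-ACGT base) is encoded as 0.25 in each channel.
#'
#' @param seqs character vector of equal-length sequences.
#' @return numeric matrix of dim `(length(seqs) * L, 4)` with sequences
#'   stacked row-wise; attribute `n` and `L` record the layout.
#' @export
one_hot <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  idx <- match(chars, c("A", "C", "G", "T"))
  n <- length(seqs)
  X <- matrix(0, nrow = n * L, ncol = 4L)
  known <- !is.na(idx)
  X[cbind(which(known), idx[known])] <- 1
  if (any(!known)) X[!known, ] <- 0.25
  attr(X, "n") <- n; attr(X, "L") <- L
  X
}
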