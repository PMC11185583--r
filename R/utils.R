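# Internal helpers: seeded RNG streams, coordinate conversion, alignment
# column parsing shared by the detector, the gene mapper and the transcript
# screen.

.datatable.aware <- TRUE

.SDPOLY_STAGES <- c("reference", "events", "plant", "depth", "transcripts",
                    "detect", "permutation", "misc")

#' Derive a per-stage random seed from one global seed
#'
#' One global seed drives the whole pipeline; each stage draws from its own
#' derived stream so stages can be rerun independently without disturbing the
#' others.
#'
#' @param seed integer global seed.
#' @param stage one of `"reference"`, `"events"`, `"plant"`, `"depth"`,
#'   `"transcripts"`, `"detect"`, `"permutation"`, `"misc"`.
#' @param offset optional extra integer offset (e.g. a replicate index).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = "misc", offset = 0L) {
  i <- match(stage, .SDPOLY_STAGES)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + i * 1000003 + offset * 7919) %% 2147483647)
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# BED-style data.frame (0-based half-open) <-> GRanges (1-based closed)
bed_to_gr <- function(df, seqlengths = NULL) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges(seqlengths = seqlengths))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

gr_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

# Parse a pairwise alignment into per-column counts. Accepts a Biostrings
# PairwiseAlignmentsSingleSubject or a character vector of two equal-length
# gapped strings. Gap runs with width >= intron_min are classified as introns
# and reported separately (used by the transcript screen).
alignment_columns <- function(alignment, intron_min = Inf) {
  if (methods::is(alignment, "PairwiseAlignmentsSingleSubject")) {
    p <- as.character(Biostrings::alignedPattern(alignment))
    s <- as.character(Biostrings::alignedSubject(alignment))
  } else if (is.character(alignment) && length(alignment) == 2L) {
    p <- alignment[1]; s <- alignment[2]
  } else {
    stop("alignment must be a PairwiseAlignmentsSingleSubject or two gapped strings")
  }
  if (nchar(p) != nchar(s)) stop("aligned strings differ in length")
  if (nchar(p) == 0L) stop("empty alignment")
  pc <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
  sc <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  gap <- pc == "-" | sc == "-"
  if (all(gap)) stop("alignment has no aligned columns")
  matches <- sum(!gap & pc == sc)
  mismatches <- sum(!gap & pc != sc)
  runs <- rle(gap)
  gap_widths <- runs$lengths[runs$values]
  # an intron is a long gap in the pattern (the read skipping subject
  # sequence); long subject-side gaps are ordinary deletions
  ends <- cumsum(runs$lengths)[runs$values]
  pattern_side <- vapply(seq_along(gap_widths), function(i)
    all(pc[(ends[i] - gap_widths[i] + 1):ends[i]] == "-"), TRUE)
  intron <- gap_widths >= intron_min & pattern_side
  list(
    matches = matches,
    mismatches = mismatches,
    gap_columns = sum(gap_widths[!intron]),
    gap_openings = sum(!intron),
    intron_columns = sum(gap_widths[intron]),
    n_introns = sum(intron)
  )
}

# Standard empirical p-value with the +1 correction.
perm_pvalue <- function(observed, perms, alternative = c("le", "ge")) {
  alternative <- match.arg(alternative)
  hits <- if (alternative == "le") sum(perms <= observed) else sum(perms >= observed)
  (1 + hits) / (length(perms) + 1)
}

# Nucleotide scoring matrix used by all extension/verification alignments.
nuc_mat <- function(match = 1L, mismatch = -3L) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
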