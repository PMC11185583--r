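# Segmental duplication detection within a haplotype assembly:
# masked k-mer seeding -> collinear chaining (forward and reverse-complement
# strand separately) -> local dynamic-programming extension -> identity and
# length filters.

#' Parameters for segmental duplication detection
#'
#' Defaults implement the operational SD definition: aligned blocks of at
#' least 1 kbp at a minimum of 90% sequence identity.
#'
#' @param min_length_bp minimum aligned length (alignment columns) of a pair.
#' @param min_identity minimum per-column identity,
#'   matches / (matches + mismatches + gap columns).
#' @param kmer_size seed k-mer size (>= 11).
#' @param max_chain_gap_bp maximum positional gap between consecutive seeds in
#'   a chain.
#' @param diag_band_bp diagonal tolerance when grouping seeds into chains.
#' @param max_kmer_occ seeds from k-mers occurring more often than this are
#'   ignored (repeat guard).
#' @param flank_bp extra sequence taken around a chain before extension.
#' @return a list of class `sd_detect_params`.
#' @export
sd_detect_params <- function(min_length_bp = 1000L, min_identity = 0.90,
                             kmer_size = 15L, max_chain_gap_bp = 2000L,
                             diag_band_bp = 100L, max_kmer_occ = 50L,
                             flank_bp = 200L) {
  stopifnot(min_identity > 0, min_identity <= 1, kmer_size >= 11,
            min_length_bp > 0, max_chain_gap_bp > 0)
  structure(list(min_length_bp = as.integer(min_length_bp),
                 min_identity = min_identity,
                 kmer_size = as.integer(kmer_size),
                 max_chain_gap_bp = as.integer(max_chain_gap_bp),
                 diag_band_bp = as.integer(diag_band_bp),
                 max_kmer_occ = as.integer(max_kmer_occ),
                 flank_bp = as.integer(flank_bp)),
            class = "sd_detect_params")
}

# coerce sequences to a named character vector
.as_seq_chr <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences) || length(sequences) == 0)
    stop("sequences must be a non-empty DNAStringSet or character vector")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  sequences
}

# mask GRanges/BED df -> list of 0-based half-open IntegerMatrix per sequence
.mask_list <- function(mask, seq_names) {
  out <- vector("list", length(seq_names))
  if (is.null(mask)) return(out)
  df <- if (methods::is(mask, "GRanges")) gr_to_bed(mask) else mask
  for (i in seq_along(seq_names)) {
    rows <- df[df$chrom == seq_names[i], , drop = FALSE]
    if (nrow(rows))
      out[[i]] <- cbind(as.integer(rows$start), as.integer(rows$end))
  }
  out
}

# Group seed matches into collinear chains. Seeds carry 0-based positions.
# Direct chains share a diagonal (tpos - qpos); inverted chains share an
# antidiagonal (tpos + qpos).
chain_seeds <- function(seeds, k, band, max_gap) {
  if (nrow(seeds) == 0) return(data.table::data.table())
  dt <- data.table::as.data.table(seeds)
  dt[, diag := ifelse(strand == 1L, tpos - qpos, tpos + qpos)]
  dt[, dbin := as.integer(floor(diag / band))]
  data.table::setorder(dt, qseq, tseq, strand, dbin, qpos)
  brk <- c(TRUE,
           dt$qseq[-1] != dt$qseq[-nrow(dt)] |
           dt$tseq[-1] != dt$tseq[-nrow(dt)] |
           dt$strand[-1] != dt$strand[-nrow(dt)] |
           dt$dbin[-1] != dt$dbin[-nrow(dt)] |
           (dt$qpos[-1] - dt$qpos[-nrow(dt)]) > max_gap)
  dt[, chain := cumsum(brk)]
  chains <- dt[, .(qseq = qseq[1], tseq = tseq[1], strand = strand[1],
                   q_start = min(qpos), q_end = max(qpos) + k,
                   t_start = min(tpos), t_end = max(tpos) + k,
                   diag0 = as.integer(round(mean(diag))),
                   n_seeds = .N), by = chain]
  chains
}

# extract [start, end) 0-based half-open from a sequence string
.subseq0 <- function(s, start, end) substr(s, start + 1L, end)

#' Identity of a pairwise alignment
#'
#' Per-column identity: matches / (matches + mismatches + gap columns), each
#' gap column counted individually.  Accepts a
#' [Biostrings::PairwiseAlignments] object, a character vector of two
#' equal-length gapped strings, or a list with elements `matches`,
#' `mismatches` and `gap_columns`.
#'
#' @param alignment the alignment (see Details).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' alignment_identity(c("ACGT-TT", "ACGAATT"))
#' @export
alignment_identity <- function(alignment) {
  if (is.list(alignment) && !methods::is(alignment, "PairwiseAlignmentsSingleSubject") &&
      all(c("matches", "mismatches", "gap_columns") %in% names(alignment))) {
    cols <- alignment
  } else {
    cols <- alignment_columns(alignment)
  }
  denom <- cols$matches + cols$mismatches + cols$gap_columns
  if (denom == 0) stop("empty alignment")
  cols$matches / denom
}

# Align two candidate loci (already oriented) with a banded Smith-Waterman
# around the chain diagonal; coordinates relative to the supplied windows.
.extend_candidate <- function(a_seq, b_seq, d0 = 0L, band = 150L) {
  r <- .banded_local_align(a_seq, b_seq, as.integer(d0), as.integer(band),
                           1, -3, -5)
  if (r$score <= 0) return(NULL)
  list(
    a_start = r$a_start, a_end = r$a_end,
    b_start = r$b_start, b_end = r$b_end,
    matches = r$matches, mismatches = r$mismatches,
    gap_columns = r$gap_columns,
    score = r$score
  )
}

#' Find segmental duplication pairs in an assembly
#'
#' Detects all pairs of non-identical loci, within and between the supplied
#' sequences, that align at `min_identity` or better over at least
#' `min_length_bp` alignment columns.  Seeding skips tandem-repeat-masked
#' positions and pairs wholly inside masked tracts are dropped.
#'
#' @param sequences a [Biostrings::DNAStringSet] or named character vector
#'   (one haplotype assembly; contigs/chromosomes as elements).
#' @param params an [sd_detect_params()] object.
#' @param mask optional tandem-repeat mask: GRanges or BED-style data.frame
#'   (`chrom`, `start`, `end`, 0-based half-open).
#' @return a data.frame of class `sd_pairs` with columns `seq_a`, `start_a`,
#'   `end_a`, `seq_b`, `start_b`, `end_b` (0-based half-open), `orientation`
#'   (`"direct"`/`"inverted"`), `aligned_length` (alignment columns) and
#'   `identity`.  Pair intervals are ordered so that locus A is
#'   lexicographically before locus B.
#' @export
find_sd_pairs <- function(sequences, params = sd_detect_params(), mask = NULL) {
  sequences <- .as_seq_chr(sequences)
  k <- params$kmer_size
  seeds <- .self_seed_pairs(sequences, k, .mask_list(mask, names(sequences)),
                            k, params$max_kmer_occ, 2e7)
  chains <- chain_seeds(seeds, k, params$diag_band_bp, params$max_chain_gap_bp)
  empty <- data.frame(seq_a = character(), start_a = integer(), end_a = integer(),
                      seq_b = character(), start_b = integer(), end_b = integer(),
                      orientation = character(), aligned_length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("sd_pairs", "data.frame")
  if (nrow(chains) == 0) return(empty)
  chains <- chains[(q_end - q_start) >= 0.6 * params$min_length_bp &
                   (t_end - t_start) >= 0.6 * params$min_length_bp &
                   n_seeds >= 5L &
                   n_seeds >= 0.02 * pmin(q_end - q_start, t_end - t_start)]
  if (nrow(chains) == 0) return(empty)

  nm <- names(sequences)
  lens <- nchar(sequences)
  res <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i]
    fl <- params$flank_bp
    qs <- max(0L, ch$q_start - fl); qe <- min(lens[ch$qseq], ch$q_end + fl)
    ts <- max(0L, ch$t_start - fl); te <- min(lens[ch$tseq], ch$t_end + fl)
    # skip chains that are just one locus overlapping itself on a shifted
    # diagonal within the same window
    if (ch$qseq == ch$tseq && ch$strand == 1L && ts < qe && qs < te &&
        (min(qe, te) - max(qs, ts)) > 0.9 * (qe - qs)) next
    a_seq <- .subseq0(sequences[[ch$qseq]], qs, qe)
    b_raw <- .subseq0(sequences[[ch$tseq]], ts, te)
    b_seq <- if (ch$strand == 1L) b_raw else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(b_raw)))
    # expected band diagonal within the extracted windows (rc coords for '-')
    d0 <- if (ch$strand == 1L) ch$diag0 + qs - ts else
      te - params$kmer_size + qs - ch$diag0
    ext <- .extend_candidate(a_seq, b_seq, d0,
                             band = params$diag_band_bp + 100L)
    if (is.null(ext)) next
    aligned_length <- ext$matches + ext$mismatches + ext$gap_columns
    identity <- ext$matches / aligned_length
    if (aligned_length < params$min_length_bp || identity < params$min_identity) next
    a0 <- qs + ext$a_start; a1 <- qs + ext$a_end
    if (ch$strand == 1L) {
      b0 <- ts + ext$b_start; b1 <- ts + ext$b_end
    } else {
      L <- te - ts
      b0 <- ts + L - ext$b_end; b1 <- ts + L - ext$b_start
    }
    res[[i]] <- data.frame(
      seq_a = nm[ch$qseq], start_a = a0, end_a = a1,
      seq_b = nm[ch$tseq], start_b = b0, end_b = b1,
      orientation = if (ch$strand == 1L) "direct" else "inverted",
      aligned_length = as.integer(aligned_length), identity = identity,
      score = ext$score, stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)

  # drop coincident / self intervals
  keep <- !(pairs$seq_a == pairs$seq_b & pairs$start_a == pairs$start_b &
              pairs$end_a == pairs$end_b)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)

  # canonical order: interval A lexicographically <= interval B
  flip <- pairs$seq_b < pairs$seq_a |
    (pairs$seq_b == pairs$seq_a & (pairs$start_b < pairs$start_a |
       (pairs$start_b == pairs$start_a & pairs$end_b < pairs$end_a)))
  if (any(flip)) {
    tmp <- pairs[flip, c("seq_a", "start_a", "end_a")]
    pairs[flip, c("seq_a", "start_a", "end_a")] <-
      pairs[flip, c("seq_b", "start_b", "end_b")]
    pairs[flip, c("seq_b", "start_b", "end_b")] <- tmp
  }

  pairs <- .dedupe_pairs(pairs)

  # pairs wholly inside masked tandem-repeat tracts are dropped
  if (!is.null(mask)) {
    mgr <- if (methods::is(mask, "GRanges")) mask else bed_to_gr(mask)
    gra <- bed_to_gr(data.frame(chrom = pairs$seq_a, start = pairs$start_a,
                                end = pairs$end_a))
    grb <- bed_to_gr(data.frame(chrom = pairs$seq_b, start = pairs$start_b,
                                end = pairs$end_b))
    ina <- IRanges::overlapsAny(gra, mgr, type = "within")
    inb <- IRanges::overlapsAny(grb, mgr, type = "within")
    pairs <- pairs[!(ina & inb), , drop = FALSE]
  }
  pairs$score <- NULL
  pairs <- pairs[order(pairs$seq_a, pairs$start_a, pairs$seq_b, pairs$start_b), ]
  rownames(pairs) <- NULL
  class(pairs) <- c("sd_pairs", "data.frame")
  pairs
}

# Collapse redundant candidates arising from overlapping chains.
# Tie-break: higher identity, then longer, then leftmost.
.dedupe_pairs <- function(pairs) {
  o <- order(-pairs$identity, -pairs$aligned_length, pairs$seq_a, pairs$start_a)
  pairs <- pairs[o, , drop = FALSE]
  n <- nrow(pairs)
  keep <- rep(TRUE, n)
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (pairs$orientation[i] != pairs$orientation[j]) next
      if (pairs$seq_a[i] != pairs$seq_a[j] || pairs$seq_b[i] != pairs$seq_b[j]) next
      wa <- min(pairs$end_a[i] - pairs$start_a[i], pairs$end_a[j] - pairs$start_a[j])
      wb <- min(pairs$end_b[i] - pairs$start_b[i], pairs$end_b[j] - pairs$start_b[j])
      oa <- ov(pairs$start_a[i], pairs$end_a[i], pairs$start_a[j], pairs$end_a[j])
      ob <- ov(pairs$start_b[i], pairs$end_b[i], pairs$start_b[j], pairs$end_b[j])
      if (oa > 0.5 * wa && ob > 0.5 * wb) { keep[i] <- FALSE; break }
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Merge SD pair intervals into a nonoverlapping footprint
#'
#' Takes the union of all pair intervals (both sides of every pair), merging
#' overlapping or book-ended intervals.  Idempotent.
#'
#' @param pairs an `sd_pairs` data.frame (or any data.frame with `seq_a`,
#'   `start_a`, `end_a`, `seq_b`, `start_b`, `end_b`).
#' @return a BED-style data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) sorted by position, with attribute `total_bp`.
#' @export
merge_pair_intervals <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "total_bp") <- 0L
    return(out)
  }
  df <- data.frame(
    chrom = c(pairs$seq_a, pairs$seq_b),
    start = c(pairs$start_a, pairs$start_b),
    end = c(pairs$end_a, pairs$end_b), stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::reduce(bed_to_gr(df))
  out <- gr_to_bed(GenomicRanges::sort(gr))
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}
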