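# Screen transcripts for reads that align better to a non-reference
# haplotype than to the reference: per-column identity >= 99.9% on the
# haplotype side, gap-compressed identity < 99.7% on the reference side.

#' Gap-compressed identity of a pairwise alignment
#'
#' matches / (matches + mismatches + gap openings): each contiguous gap run
#' counts once regardless of its length.  Gap runs at least `intron_min`
#' columns wide are treated as introns and excluded from the denominator
#' entirely (set `intron_min = Inf` to count every gap).
#'
#' @param alignment a [Biostrings::PairwiseAlignments] object, two
#'   equal-length gapped strings, or a counts list with `matches`,
#'   `mismatches`, `gap_openings`.
#' @param intron_min minimum gap width treated as an intron.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' gap_compressed_identity(c("AAAA--AAAA", "AAAAGGAAAA"))   # one opening
#' @export
gap_compressed_identity <- function(alignment, intron_min = Inf) {
  if (is.list(alignment) && !methods::is(alignment, "PairwiseAlignmentsSingleSubject") &&
      all(c("matches", "mismatches", "gap_openings") %in% names(alignment))) {
    cols <- alignment
  } else {
    cols <- alignment_columns(alignment, intron_min = intron_min)
  }
  denom <- cols$matches + cols$mismatches + cols$gap_openings
  if (denom == 0) stop("empty alignment")
  cols$matches / denom
}

#' Screening thresholds
#'
#' @param hap_min_identity minimum per-column identity to the best haplotype
#'   locus (paper threshold: at least 99.9%).
#' @param ref_max_gci reference gap-compressed identity at or above which a
#'   read is dropped (paper threshold: below 99.7%).
#' @param intron_min_bp alignment deletions at least this long are treated as
#'   introns (spliced reads against genomic loci) and excluded from both
#'   identity denominators.
#' @param kmer_size,max_kmer_occ,locus_gap_bp,flank_bp candidate-locus
#'   seeding controls.
#' @return list of class `screen_params`.
#' @export
screen_params <- function(hap_min_identity = 0.999, ref_max_gci = 0.997,
                          intron_min_bp = 30L, kmer_size = 15L,
                          max_kmer_occ = 100L, locus_gap_bp = 20000L,
                          flank_bp = 100L) {
  structure(list(hap_min_identity = hap_min_identity,
                 ref_max_gci = ref_max_gci,
                 intron_min_bp = as.integer(intron_min_bp),
                 kmer_size = as.integer(kmer_size),
                 max_kmer_occ = as.integer(max_kmer_occ),
                 locus_gap_bp = as.integer(locus_gap_bp),
                 flank_bp = as.integer(flank_bp)),
            class = "screen_params")
}

# candidate loci of a read on an indexed genome: seed positions grouped per
# (target, strand) and split at gaps > locus_gap_bp; best few by seed count
.candidate_loci <- function(read, index, params, max_candidates = 4L) {
  seeds <- .kmer_index_query(index$xp, setNames(read, "r"), FALSE, 0L,
                             params$max_kmer_occ, 2e6)
  if (nrow(seeds) == 0) return(NULL)
  dt <- data.table::as.data.table(seeds)
  data.table::setorder(dt, tseq, strand, tpos)
  brk <- c(TRUE, dt$tseq[-1] != dt$tseq[-nrow(dt)] |
             dt$strand[-1] != dt$strand[-nrow(dt)] |
             (dt$tpos[-1] - dt$tpos[-nrow(dt)]) > params$locus_gap_bp)
  dt[, grp := cumsum(brk)]
  loci <- dt[, .(tseq = tseq[1], strand = strand[1], t_start = min(tpos),
                 t_end = max(tpos) + index$k, n_seeds = .N), by = grp]
  data.table::setorder(loci, -n_seeds)
  head(loci, max_candidates)
}

# best alignment of a read to an indexed genome; identities computed
# intron-aware
.best_alignment <- function(read, index, params) {
  loci <- .candidate_loci(read, index, params)
  if (is.null(loci) || nrow(loci) == 0) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i]
    fl <- params$flank_bp
    ts <- max(0L, lc$t_start - fl)
    te <- min(index$lens[lc$tseq], lc$t_end + fl)
    twin <- .subseq0(index$sequences[[lc$tseq]], ts, te)
    subj <- if (lc$strand == 1L) twin else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(twin)))
    aln <- Biostrings::pairwiseAlignment(
      pattern = read, subject = subj, type = "global-local",
      substitutionMatrix = nuc_mat(1L, -2L), gapOpening = 8, gapExtension = 0.2)
    cols <- alignment_columns(aln, intron_min = params$intron_min_bp)
    identity <- cols$matches / (cols$matches + cols$mismatches + cols$gap_columns)
    gci <- cols$matches / (cols$matches + cols$mismatches + cols$gap_openings)
    s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
    s1 <- Biostrings::end(Biostrings::subject(aln))
    if (lc$strand == 1L) { t0 <- ts + s0; t1 <- ts + s1 } else {
      L <- te - ts
      t0 <- ts + L - s1; t1 <- ts + L - s0
    }
    # require most of the read to be aligned (not swallowed by end gaps)
    if ((cols$matches + cols$mismatches) < 0.5 * nchar(read)) next
    cand <- list(target = index$names[lc$tseq], start = t0, end = t1,
                 strand = if (lc$strand == 1L) "+" else "-",
                 identity = identity, gci = gci,
                 score = Biostrings::score(aln))
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$identity > best$identity))
      best <- cand
  }
  best
}

#' Screen transcript reads against haplotypes and the reference
#'
#' Each read is aligned to its best reference locus and to its best locus in
#' every haplotype.  A read is retained when its best haplotype per-column
#' identity is at least `hap_min_identity` and its reference gap-compressed
#' identity is below `ref_max_gci`; reads at or above the reference ceiling
#' are dropped regardless of the haplotype side.
#'
#' @param transcripts DNAStringSet (named) or character vector of reads.
#' @param haplotypes named list of haplotype assemblies (DNAStringSet each)
#'   or of prebuilt [build_assembly_index()] objects.
#' @param reference DNAStringSet / `sd_reference` or a prebuilt index.
#' @param params a [screen_params()] object.
#' @return data.frame of class `transcript_hits`: read, best haplotype and
#'   locus, haplotype identity, reference identity and gap-compressed
#'   identity, `aligned` and `retained` flags, and `orf_aa` (longest forward
#'   open reading frame of the read).
#' @export
screen_reads <- function(transcripts, haplotypes, reference,
                         params = screen_params()) {
  reads <- .as_seq_chr(transcripts)
  if (inherits(reference, "sd_reference")) reference <- reference$sequences
  ref_idx <- if (inherits(reference, "assembly_index")) reference else
    build_assembly_index(reference, params$kmer_size)
  ref_bests <- lapply(reads, .best_alignment, index = ref_idx, params = params)
  # one haplotype index alive at a time: cohort assemblies are large and the
  # index memory lives outside R's heap
  hap_bests <- vector("list", length(reads))
  hap_names <- rep(NA_character_, length(reads))
  for (hn in names(haplotypes)) {
    h <- haplotypes[[hn]]
    idx <- if (inherits(h, "assembly_index")) h else
      build_assembly_index(h, params$kmer_size)
    for (r in seq_along(reads)) {
      b <- .best_alignment(reads[[r]], idx, params)
      cur <- hap_bests[[r]]
      if (!is.null(b) && (is.null(cur) || b$identity > cur$identity ||
                          (b$identity == cur$identity && b$score > cur$score))) {
        hap_bests[[r]] <- b; hap_names[r] <- hn
      }
    }
    rm(idx); gc(FALSE)
  }
  out <- vector("list", length(reads))
  for (r in seq_along(reads)) {
    rd <- reads[[r]]
    ref_best <- ref_bests[[r]]
    hap_best <- hap_bests[[r]]; hap_name <- hap_names[r]
    aligned <- !is.null(ref_best) || !is.null(hap_best)
    ref_gci <- if (!is.null(ref_best)) ref_best$gci else NA_real_
    hap_id <- if (!is.null(hap_best)) hap_best$identity else NA_real_
    retained <- aligned &&
      (!is.null(hap_best) && hap_id >= params$hap_min_identity) &&
      (is.null(ref_best) || ref_gci < params$ref_max_gci)
    orf <- find_orf(rd)
    out[[r]] <- data.frame(
      read_id = names(reads)[r],
      haplotype = hap_name,
      hap_chrom = if (!is.null(hap_best)) hap_best$target else NA_character_,
      hap_start = if (!is.null(hap_best)) hap_best$start else NA_integer_,
      hap_end = if (!is.null(hap_best)) hap_best$end else NA_integer_,
      hap_identity = hap_id,
      ref_identity = if (!is.null(ref_best)) ref_best$identity else NA_real_,
      ref_gci = ref_gci,
      aligned = aligned, retained = retained,
      orf_aa = if (orf$found) orf$aa_length else 0L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("transcript_hits", "data.frame")
  res
}

#' Longest forward-strand open reading frame
#'
#' Longest ATG-to-stop frame on the forward strand; no ORF when there is no
#' ATG or no in-frame stop.
#'
#' @param sequence character or DNAString.
#' @return list: `found`, `start` (0-based nt offset), `end` (0-based
#'   half-open, including the stop codon), `aa_length` (amino acids,
#'   excluding the stop).
#' @export
find_orf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  none <- list(found = FALSE, start = NA_integer_, end = NA_integer_,
               aa_length = 0L)
  if (n < 3) return(none)
  codons_at <- function(off) {
    m <- substring(s, seq(off + 1L, n - 2L, by = 3L),
                   seq(off + 3L, n, by = 3L))
    m
  }
  best <- none
  for (off in 0:2) {
    if (n - off < 3) next
    cods <- codons_at(off)
    starts <- which(cods == "ATG")
    stops <- which(cods %in% c("TAA", "TAG", "TGA"))
    for (st in starts) {
      sp <- stops[stops > st]
      if (!length(sp)) next
      aa <- sp[1] - st
      if (aa > best$aa_length) {
        best <- list(found = TRUE, start = off + (st - 1L) * 3L,
                     end = off + sp[1] * 3L, aa_length = aa)
      }
    }
  }
  best
}

#' Summarize novel putative protein-coding genes
#'
#' Clusters retained hits into loci per haplotype (hits within
#' `cluster_gap_bp` on one haplotype chromosome merge), filters to putative
#' protein-coding loci (longest read ORF at least `min_orf_aa`), and counts
#' per haplotype.  Family totals count only the haplotype with the greatest
#' number of that family's novel paralogs.
#'
#' @param hits `transcript_hits` from [screen_reads()].
#' @param family_map optional data.frame (`read_id`, `family`); reads without
#'   a family fall into family `"unassigned"`.
#' @param cluster_gap_bp locus merge distance.
#' @param min_orf_aa minimum ORF length (amino acids) for the
#'   protein-coding filter.
#' @return list: `per_haplotype` (haplotype, n_loci), `families` (family,
#'   total, haplotype), `total` novel genes.
#' @export
summarize_novel_genes <- function(hits, family_map = NULL,
                                  cluster_gap_bp = 10000L, min_orf_aa = 100L) {
  x <- hits[hits$retained & hits$orf_aa >= min_orf_aa, , drop = FALSE]
  if (nrow(x) == 0) {
    return(list(per_haplotype = data.frame(haplotype = character(),
                                           n_loci = integer()),
                families = data.frame(family = character(), total = integer(),
                                      haplotype = character()),
                total = 0L))
  }
  fam <- if (!is.null(family_map))
    family_map$family[match(x$read_id, family_map$read_id)] else
      rep(NA_character_, nrow(x))
  fam[is.na(fam)] <- "unassigned"
  x$family <- fam
  # cluster into loci per haplotype chromosome
  x <- x[order(x$haplotype, x$hap_chrom, x$hap_start), , drop = FALSE]
  n <- nrow(x)
  new_locus <- c(TRUE, x$haplotype[-1] != x$haplotype[-n] |
                   x$hap_chrom[-1] != x$hap_chrom[-n] |
                   (x$hap_start[-1] - x$hap_end[-n]) > cluster_gap_bp)
  x$locus <- cumsum(new_locus)
  per_hap <- stats::aggregate(locus ~ haplotype, data = x,
                              FUN = function(v) length(unique(v)))
  names(per_hap)[2] <- "n_loci"
  # family totals: haplotype with the most loci of that family
  fl <- unique(x[, c("family", "haplotype", "locus")])
  cnt <- stats::aggregate(locus ~ family + haplotype, data = fl,
                          FUN = function(v) length(unique(v)))
  names(cnt)[3] <- "n"
  fams <- do.call(rbind, lapply(split(cnt, cnt$family), function(d) {
    i <- which.max(d$n)
    data.frame(family = d$family[i], total = d$n[i], haplotype = d$haplotype[i],
               stringsAsFactors = FALSE)
  }))
  rownames(fams) <- NULL
  list(per_haplotype = per_hap, families = fams, total = sum(fams$total))
}
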