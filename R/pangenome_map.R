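# Project per-haplotype SD footprints onto the reference, build
# nonoverlapping frequency-classified regions, compute the accumulation
# curve, and test novel-SD proximity to the known footprint.

#' Frequency classification parameters
#'
#' Rare = observed in up to `rare_max_carriers` haplotypes (< 3% allele
#' frequency in a 170-haplotype cohort); common = observed
#' `common_min`..`common_max` times; `polymorphic_af_ceiling` is the allele
#' frequency below which a non-fixed region is flagged `polymorphic_90`.
#'
#' @param rare_max_carriers,common_min,common_max,polymorphic_af_ceiling see
#'   Description.
#' @return list of class `frequency_params`.
#' @export
frequency_params <- function(rare_max_carriers = 5L, common_min = 6L,
                             common_max = 20L, polymorphic_af_ceiling = 0.90) {
  stopifnot(rare_max_carriers < common_min, common_min <= common_max)
  structure(list(rare_max_carriers = as.integer(rare_max_carriers),
                 common_min = as.integer(common_min),
                 common_max = as.integer(common_max),
                 polymorphic_af_ceiling = polymorphic_af_ceiling),
            class = "frequency_params")
}

#' Identity alignment for a reference-collinear haplotype
#'
#' Convenience "collinear declaration": every chromosome maps to itself
#' unchanged.
#'
#' @param reference an `sd_reference` or DNAStringSet.
#' @return an alignment block table usable by [project_to_reference()].
#' @export
identity_alignment <- function(reference) {
  seqs <- if (inherits(reference, "sd_reference")) reference$sequences else reference
  data.frame(hap_chrom = names(seqs), hap_start = 0L,
             hap_end = Biostrings::width(seqs),
             ref_chrom = names(seqs), ref_start = 0L,
             ref_end = Biostrings::width(seqs),
             type = "block", event_id = NA_character_, stringsAsFactors = FALSE)
}

#' Lift a reference-coordinate mask into haplotype coordinates
#'
#' Shifts mask intervals by the insertions recorded in the alignment block
#' table (masks never overlap planted insertion points in the synthetic
#' cohort).
#'
#' @param mask BED-style data.frame in reference coordinates.
#' @param alignment block table as in [project_to_reference()].
#' @return BED-style data.frame in haplotype coordinates.
#' @export
mask_to_haplotype <- function(mask, alignment) {
  blks <- alignment[alignment$type == "block", , drop = FALSE]
  out <- mask
  for (i in seq_len(nrow(mask))) {
    b <- blks[blks$ref_chrom == mask$chrom[i] & blks$ref_start <= mask$start[i] &
                blks$ref_end >= mask$end[i], , drop = FALSE]
    if (!nrow(b)) next
    shift <- b$hap_start[1] - b$ref_start[1]
    out$start[i] <- mask$start[i] + shift
    out$end[i] <- mask$end[i] + shift
  }
  out
}

#' Project a haplotype SD footprint onto the reference
#'
#' Maps each footprint interval through the haplotype-to-reference alignment
#' blocks.  Portions inside haplotype-only insertions map to the insertion's
#' anchoring reference point as a zero-width interval flagged
#' `novel_sequence`.  Intervals on contigs absent from the alignment are
#' returned separately as unplaced.
#'
#' @param footprint BED-style data.frame (`chrom`, `start`, `end`) in
#'   haplotype coordinates, e.g. from [merge_pair_intervals()].
#' @param alignment block table with columns `hap_chrom`, `hap_start`,
#'   `hap_end`, `ref_chrom`, `ref_start`, `ref_end`, `type`
#'   (`"block"`/`"insertion"`); collinear blocks must be length-preserving.
#' @return list: `projected` (BED-style reference intervals with
#'   `novel_sequence` flag) and `unplaced`.
#' @export
project_to_reference <- function(footprint, alignment) {
  proj <- list(); unplaced <- list()
  if (nrow(footprint) == 0) {
    return(list(projected = data.frame(chrom = character(), start = integer(),
                                       end = integer(),
                                       novel_sequence = logical()),
                unplaced = footprint))
  }
  for (i in seq_len(nrow(footprint))) {
    fc <- footprint$chrom[i]; fs <- footprint$start[i]; fe <- footprint$end[i]
    blks <- alignment[alignment$hap_chrom == fc, , drop = FALSE]
    if (!nrow(blks)) {
      unplaced[[length(unplaced) + 1L]] <- footprint[i, , drop = FALSE]
      next
    }
    hit <- blks[blks$hap_end > fs & blks$hap_start < fe, , drop = FALSE]
    if (!nrow(hit)) {
      unplaced[[length(unplaced) + 1L]] <- footprint[i, , drop = FALSE]
      next
    }
    for (b in seq_len(nrow(hit))) {
      os <- max(fs, hit$hap_start[b]); oe <- min(fe, hit$hap_end[b])
      if (hit$type[b] == "block") {
        shift <- hit$ref_start[b] - hit$hap_start[b]
        proj[[length(proj) + 1L]] <- data.frame(
          chrom = hit$ref_chrom[b], start = os + shift, end = oe + shift,
          novel_sequence = FALSE, stringsAsFactors = FALSE)
      } else {
        proj[[length(proj) + 1L]] <- data.frame(
          chrom = hit$ref_chrom[b], start = hit$ref_start[b],
          end = hit$ref_start[b], novel_sequence = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    projected = if (length(proj)) unique(do.call(rbind, proj)) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 novel_sequence = logical()),
    unplaced = if (length(unplaced)) do.call(rbind, unplaced) else
      footprint[0, , drop = FALSE]
  )
}

#' Build nonoverlapping, frequency-classified reference SD regions
#'
#' Pools the projected footprints of all haplotypes, splits the union at
#' every breakpoint, assigns each piece its carrier set (haplotypes whose
#' footprint overlaps by at least 1 bp), and merges adjacent pieces with
#' identical carrier sets.  This keeps a polymorphic extension distinct from
#' an abutting fixed region instead of absorbing it into one merged interval.
#' Zero-width novel-sequence anchors are ignored here.
#'
#' Frequency classes: `fixed` (all haplotypes), `private` (one), otherwise
#' `polymorphic_known`/`polymorphic_novel` by overlap with the reference's
#' own SD footprint.  `polymorphic_90` additionally flags non-fixed regions
#' with allele frequency below the ceiling; `freq_bin` bins carriers into
#' rare (<= `rare_max_carriers`) and common (`common_min`..`common_max`).
#'
#' @param projections named list (one element per haplotype) of projected
#'   BED-style data.frames from [project_to_reference()].
#' @param n_haplotypes cohort size.
#' @param ref_sd_footprint BED-style data.frame: the reference's own SD
#'   footprint (e.g. [find_sd_pairs()] + [merge_pair_intervals()] on the
#'   reference, or [reference_sd_footprint()]).
#' @param params a [frequency_params()] object.
#' @return data.frame of regions with carrier counts, allele frequency and
#'   classes; attribute `total_bp` gives the merged footprint size.
#' @export
build_regions <- function(projections, n_haplotypes,
                          ref_sd_footprint = NULL,
                          params = frequency_params()) {
  if (n_haplotypes < 1) stop("n_haplotypes must be >= 1")
  if (length(projections) < 1) stop("at least one haplotype projection required")
  clean <- lapply(projections, function(df) {
    df <- df[df$end > df$start, c("chrom", "start", "end"), drop = FALSE]
    df
  })
  pooled <- do.call(rbind, clean)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      carrier_count = integer(), n_haplotypes = integer(),
                      allele_frequency = numeric(), known_in_reference = logical(),
                      freq_class = character(), polymorphic_90 = logical(),
                      freq_bin = character())
  if (is.null(pooled) || nrow(pooled) == 0) {
    attr(empty, "total_bp") <- 0L
    return(empty)
  }
  pieces <- GenomicRanges::disjoin(bed_to_gr(pooled))
  hap_grs <- lapply(clean, bed_to_gr)
  carrier_mat <- vapply(hap_grs, function(g) IRanges::overlapsAny(pieces, g),
                        logical(length(pieces)))
  if (length(pieces) == 1L) carrier_mat <- matrix(carrier_mat, nrow = 1L)
  key <- apply(carrier_mat, 1L, function(x) paste(which(x), collapse = ","))
  df <- gr_to_bed(pieces)
  # merge book-ended pieces with identical carrier sets
  o <- order(df$chrom, df$start)
  df <- df[o, ]; key <- key[o]; carrier_mat <- carrier_mat[o, , drop = FALSE]
  n <- nrow(df)
  new_grp <- c(TRUE, df$chrom[-1] != df$chrom[-n] |
                 df$start[-1] != df$end[-n] | key[-1] != key[-n])
  grp <- cumsum(new_grp)
  first <- !duplicated(grp)
  out <- data.frame(
    chrom = df$chrom[first],
    start = tapply(df$start, grp, min)[as.character(unique(grp))],
    end = tapply(df$end, grp, max)[as.character(unique(grp))],
    stringsAsFactors = FALSE)
  out$carrier_count <- rowSums(carrier_mat[first, , drop = FALSE])
  out$n_haplotypes <- n_haplotypes
  out$allele_frequency <- out$carrier_count / n_haplotypes
  known_gr <- if (!is.null(ref_sd_footprint) && nrow(ref_sd_footprint))
    bed_to_gr(ref_sd_footprint[, c("chrom", "start", "end")]) else
      GenomicRanges::GRanges()
  out$known_in_reference <- IRanges::overlapsAny(bed_to_gr(out), known_gr)
  out$freq_class <- ifelse(
    out$carrier_count == n_haplotypes, "fixed",
    ifelse(out$carrier_count == 1L, "private",
           ifelse(out$known_in_reference, "polymorphic_known",
                  "polymorphic_novel")))
  out$polymorphic_90 <- out$carrier_count < n_haplotypes &
    out$allele_frequency < params$polymorphic_af_ceiling
  out$freq_bin <- ifelse(out$carrier_count <= params$rare_max_carriers, "rare",
                         ifelse(out$carrier_count >= params$common_min &
                                  out$carrier_count <= params$common_max,
                                "common", "other"))
  rownames(out) <- NULL
  attr(out, "total_bp") <- sum(out$end - out$start)
  attr(out, "carrier_sets") <- lapply(which(first), function(i)
    which(carrier_mat[i, ]))
  out
}

#' Classify regions as intra-, inter-chromosomal or both
#'
#' A region is `intra` when every supporting SD pair has its partner locus on
#' the same chromosome, `inter` when every partner is on a different
#' chromosome, `both` otherwise.
#'
#' @param regions region table from [build_regions()].
#' @param pairs_ref SD pairs in reference coordinates (BED-style columns
#'   `seq_a`, `start_a`, `end_a`, `seq_b`, `start_b`, `end_b`), pooled over
#'   haplotypes.
#' @return character vector of `{intra, inter, both}` per region.
#' @export
classify_chrom_type <- function(regions, pairs_ref) {
  if (nrow(regions) == 0) return(character())
  sides <- data.frame(
    chrom = c(pairs_ref$seq_a, pairs_ref$seq_b),
    start = c(pairs_ref$start_a, pairs_ref$start_b),
    end = c(pairs_ref$end_a, pairs_ref$end_b),
    partner = c(pairs_ref$seq_b, pairs_ref$seq_a), stringsAsFactors = FALSE)
  sides$end <- pmax(sides$end, sides$start + 1L)  # widen anchors
  sgr <- bed_to_gr(sides)
  rgr <- bed_to_gr(regions[, c("chrom", "start", "end")])
  # regions and pair sides may legitimately live on disjoint chromosome sets
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rgr, sgr))
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (!length(js)) stop("region ", i, " has no supporting SD pair")
    same <- sides$partner[js] == regions$chrom[i]
    out[i] <- if (all(same)) "intra" else if (!any(same)) "inter" else "both"
  }
  out
}

#' SD accumulation curve over added genomes
#'
#' For each genome (haplotype assembly) in order, the bp of its projected SD
#' footprint not present in the reference footprint or any previously added
#' genome; the per-genome rate is the mean increment.
#'
#' @param footprints named list of projected BED-style footprints, one per
#'   genome, in the order genomes are added.
#' @param ref_sd_footprint the reference's own SD footprint (counted as
#'   already known), or NULL.
#' @return data.frame (`genome`, `novel_bp`, `cumulative_novel_bp`) with
#'   attribute `rate_bp_per_genome`.
#' @export
accumulation_curve <- function(footprints, ref_sd_footprint = NULL) {
  if (length(footprints) < 2) stop("need at least two genomes")
  seen <- if (!is.null(ref_sd_footprint) && nrow(ref_sd_footprint))
    GenomicRanges::reduce(bed_to_gr(ref_sd_footprint[, c("chrom", "start", "end")])) else
      GenomicRanges::GRanges()
  novel <- numeric(length(footprints))
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    fp <- fp[fp$end > fp$start, c("chrom", "start", "end"), drop = FALSE]
    gr <- GenomicRanges::reduce(bed_to_gr(fp))
    new_gr <- GenomicRanges::setdiff(gr, seen)
    novel[i] <- sum(IRanges::width(new_gr))
    seen <- GenomicRanges::reduce(GenomicRanges::union(seen, gr))
  }
  out <- data.frame(genome = names(footprints) %||% seq_along(footprints),
                    novel_bp = novel, cumulative_novel_bp = cumsum(novel),
                    stringsAsFactors = FALSE)
  attr(out, "rate_bp_per_genome") <- mean(novel)
  out
}

# the merged known footprint as per-chromosome sorted interval tables
.known_by_chrom <- function(known_df) {
  kg <- gr_to_bed(GenomicRanges::reduce(bed_to_gr(known_df)))
  lapply(split(kg, kg$chrom), function(d) d[order(d$start), , drop = FALSE])
}

# distance (gap width, 0 when overlapping or book-ended) from each query
# region to the nearest known interval on the same chromosome; queries on
# chromosomes without any known interval are dropped.  Plain vector math:
# this runs inside the permutation loop.
.nearest_distances <- function(chrom, start, end, known_by_chrom) {
  out <- rep(NA_real_, length(start))
  for (ch in unique(chrom)) {
    k <- known_by_chrom[[ch]]
    if (is.null(k)) next
    i <- which(chrom == ch)
    n <- nrow(k)
    j <- findInterval(end[i], k$start)
    d_next <- ifelse(j < n, k$start[pmin(j + 1L, n)] - end[i], Inf)
    d_prev <- ifelse(j >= 1, start[i] - k$end[pmax(j, 1L)], Inf)
    out[i] <- pmax(0, pmin(d_next, d_prev))
  }
  out[!is.na(out)]
}

#' Permutation test for proximity of novel SDs to the known footprint
#'
#' Statistic: median distance from each novel region to the nearest known SD
#' interval.  Null: each novel region is re-placed uniformly within its
#' chromosome arm, preserving its length.  Empirical p-value with the +1
#' correction, one-sided towards small distances.
#'
#' @param novel BED-style data.frame of novel regions.
#' @param known BED-style data.frame of the known SD footprint.
#' @param arms data.frame (`chrom`, `start`, `end`, `arm`) of chromosome arm
#'   bounds.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list: `p_value`, `observed` median distance, `perm` the null
#'   statistics.
#' @export
proximity_permutation_test <- function(novel, known, arms, n_perm = 999L,
                                       seed = 1L) {
  if (is.null(novel) || nrow(novel) == 0) stop("no novel regions to test")
  if (is.null(known) || nrow(known) == 0) stop("known footprint is empty")
  if (n_perm < 99) stop("n_perm must be >= 99")
  kbc <- .known_by_chrom(known[, c("chrom", "start", "end")])
  # assign arms by region start
  arm_of <- integer(nrow(novel))
  for (i in seq_len(nrow(novel))) {
    j <- which(arms$chrom == novel$chrom[i] & arms$start <= novel$start[i] &
                 arms$end > novel$start[i])
    if (!length(j)) stop("novel region outside the supplied arm bounds")
    arm_of[i] <- j[1]
  }
  observed <- median(.nearest_distances(novel$chrom, novel$start, novel$end,
                                        kbc))
  lens <- novel$end - novel$start
  lo <- arms$start[arm_of]
  hi <- pmax(arms$end[arm_of] - lens, lo + 1)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    st <- as.integer(floor(lo + runif(nrow(novel)) * (hi - lo)))
    median(.nearest_distances(novel$chrom, st, st + lens, kbc))
  }, 1.0))
  list(p_value = perm_pvalue(observed, perm, "le"), observed = observed,
       perm = perm)
}
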