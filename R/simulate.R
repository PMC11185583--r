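# Read-depth and transcript simulators for the synthetic cohort.

#' Default GC bias curve used by the depth simulator
#'
#' A monotone multiplicative coverage bias over the GC range the iid
#' background actually occupies (roughly target +/- 0.05), emulating the
#' GC-dependent coverage trend of short-read libraries.
#'
#' @param center GC fraction at which the factor is 1.
#' @param slope change in factor per unit GC.
#' @return a function mapping GC fractions to positive depth factors.
#' @export
default_gc_bias <- function(center = 0.41, slope = 4) {
  function(gc) pmax(0.2, 1 + slope * (gc - center))
}

.as_gc_fun <- function(gc_bias_curve) {
  if (is.null(gc_bias_curve)) return(function(gc) rep(1, length(gc)))
  if (is.function(gc_bias_curve)) return(gc_bias_curve)
  if (is.data.frame(gc_bias_curve)) {
    stopifnot(all(c("gc", "factor") %in% names(gc_bias_curve)),
              all(gc_bias_curve$factor > 0))
    f <- approxfun(gc_bias_curve$gc, gc_bias_curve$factor, rule = 2)
    return(function(gc) f(gc))
  }
  stop("gc_bias_curve must be NULL, a function, or a data.frame(gc, factor)")
}

# tile chromosomes into fixed windows; gc per window from the reference
.tile_windows <- function(sequences, window_size) {
  if (window_size <= 0) stop("window_size must be positive")
  out <- lapply(names(sequences), function(chrom) {
    L <- Biostrings::width(sequences[chrom])
    if (window_size > L)
      warning("window larger than chromosome ", chrom, "; single truncated window")
    starts <- seq(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    v <- Biostrings::Views(sequences[[chrom]], start = starts + 1L, end = ends)
    gc <- rowSums(Biostrings::letterFrequency(v, c("G", "C"))) / (ends - starts)
    data.frame(chrom = chrom, start = starts, end = ends, gc = gc,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# fraction of each window covered by a set of intervals
.window_cov_frac <- function(windows, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(numeric(nrow(windows)))
  wgr <- bed_to_gr(windows[, c("chrom", "start", "end")])
  igr <- GenomicRanges::reduce(bed_to_gr(intervals[, c("chrom", "start", "end")]))
  hits <- GenomicRanges::findOverlaps(wgr, igr)
  frac <- numeric(nrow(windows))
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                                             igr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    frac[as.integer(names(agg))] <- as.numeric(agg)
  }
  frac / (windows$end - windows$start)
}

#' Simulate per-window read depth for every sample
#'
#' Expected depth in a window is
#' `base_depth * (true copy number / 2) * gc_bias_curve(window GC)`; realized
#' depth is Poisson.  True copy number accounts for the diploid baseline, the
#' reference's own SD pairs (each retained copy adds one to every homologous
#' window), and planted insertion events (each carrier haplotype adds one to
#' the source windows).
#'
#' @param cohort an `sd_cohort` from [plant_duplications()].
#' @param gc_bias_curve NULL (flat), a function of GC, or a
#'   `data.frame(gc, factor)`; see [default_gc_bias()].
#' @param window_size window width in bp (default from the config).
#' @param base_depth expected depth of a copy-number-2 window (default from
#'   the config).
#' @param seed defaults to the cohort seed's depth stream.
#' @return a list of class `sd_depth`: `windows` (chrom, start, end, gc),
#'   `depth` (windows x samples matrix), `true_cn` (same shape), and the
#'   parameters used.
#' @export
simulate_depth <- function(cohort, gc_bias_curve = default_gc_bias(),
                           window_size = NULL, base_depth = NULL, seed = NULL) {
  cfg <- cohort$config
  window_size <- window_size %||% cfg$window_size
  base_depth <- base_depth %||% cfg$base_depth
  if (window_size <= 0) stop("window_size must be positive")
  gcf <- .as_gc_fun(gc_bias_curve)
  reference <- cohort$reference
  windows <- .tile_windows(reference$sequences, window_size)
  nw <- nrow(windows)
  samples <- unique(cohort$manifest$sample)
  events <- cohort$truth$events
  nh_by_sample <- 2L

  # per-window coverage fractions of every reference SD pair (S union C) and
  # of every insertion-event source
  refsd <- reference$ref_sd
  pair_frac <- lapply(seq_len(nrow(refsd)), function(i) .window_cov_frac(
    windows, data.frame(chrom = c(refsd$chrom_a[i], refsd$chrom_b[i]),
                        start = c(refsd$start_a[i], refsd$start_b[i]),
                        end = c(refsd$end_a[i], refsd$end_b[i]))))
  ins <- which(nrow(events) > 0 & events$mode == "insertion")
  ins_frac <- lapply(ins, function(i) .window_cov_frac(
    windows, events[i, c("chrom", "start", "end")]))

  # retained copies of each reference pair per haplotype (default: all)
  loss <- which(nrow(events) > 0 & events$mode == "ref_copy_loss")
  cn <- matrix(2, nrow = nw, ncol = length(samples),
               dimnames = list(NULL, samples))
  for (si in seq_along(samples)) {
    haps <- cohort$manifest$hap_index[cohort$manifest$sample == samples[si]]
    for (pi in seq_len(nrow(refsd))) {
      lev <- loss[!is.na(events$ref_pair_id[loss]) &
                    events$ref_pair_id[loss] == refsd$pair_id[pi]]
      retained <- if (length(lev)) sum(haps %in% events$carriers[[lev[1]]]) else
        length(haps)
      if (retained > 0)
        cn[, si] <- cn[, si] + pair_frac[[pi]] * retained
    }
    for (k in seq_along(ins)) {
      carriers <- sum(haps %in% events$carriers[[ins[k]]])
      if (carriers > 0)
        cn[, si] <- cn[, si] + ins_frac[[k]] * carriers
    }
  }

  seed <- seed %||% derive_seed(cfg$seed, "depth")
  depth <- with_seed(seed, {
    lam <- base_depth * (cn / 2) * gcf(windows$gc)
    matrix(rpois(length(lam), lam), nrow = nw,
           dimnames = list(NULL, samples))
  })
  structure(list(windows = windows, depth = depth, true_cn = cn,
                 window_size = window_size, base_depth = base_depth),
            class = "sd_depth")
}

#' Spliced reference transcript of an annotated gene
#'
#' @param reference an `sd_reference`.
#' @param gene_id gene identifier.
#' @return character mRNA (concatenated exons).
#' @export
gene_mrna <- function(reference, gene_id) {
  ex <- reference$exons[reference$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown gene: ", gene_id)
  paste(vapply(seq_len(nrow(ex)), function(i) as.character(
    Biostrings::subseq(reference$sequences[[ex$chrom[i]]],
                       ex$start[i] + 1L, ex$end[i])), ""), collapse = "")
}

# spliced transcript of the paralog copy planted by an event (exon offsets
# taken relative to the event source)
.paralog_mrna <- function(cohort, gene_id, event_id) {
  ev <- cohort$truth$events
  i <- match(event_id, ev$event_id)
  if (is.na(i)) stop("unknown event: ", event_id)
  ref <- cohort$reference
  ex <- ref$exons[ref$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex) || any(ex$start < ev$start[i]) || any(ex$end > ev$end[i]))
    stop("gene ", gene_id, " is not contained in event ", event_id)
  cp <- cohort$event_seqs[[event_id]]
  if (ev$orientation[i] == "inverted")
    cp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cp)))
  # cp now equals the mutated source in source orientation
  paste(vapply(seq_len(nrow(ex)), function(e) substr(
    cp, ex$start[e] - ev$start[i] + 1L, ex$end[e] - ev$start[i]), ""),
    collapse = "")
}

#' Simulate long-read transcript sequences from the cohort
#'
#' Emits spliced (exon-concatenated) transcripts copied from the requested
#' haplotype allele: the reference allele of a gene, or the paralog copy
#' planted by an insertion event that contains the gene.  Optionally applies
#' iid substitution errors.
#'
#' @param cohort an `sd_cohort`.
#' @param requests data.frame with columns `gene_id`, `haplotype` and
#'   `event_id` (`NA` for the reference allele).  Default: one read from
#'   every planted gene paralog in every carrier haplotype plus one
#'   reference-allele read per involved gene.
#' @param error_rate iid substitution error rate applied to reads.
#' @param seed defaults to the cohort seed's transcript stream.
#' @return list: `reads` (DNAStringSet, possibly empty) and `truth`
#'   (read_id, gene_id, event_id, haplotype).
#' @export
simulate_transcripts <- function(cohort, requests = NULL, error_rate = 0,
                                 seed = NULL) {
  ev <- cohort$truth$events
  if (is.null(requests)) {
    gene_ev <- which(ev$mode == "insertion" & !is.na(ev$overlaps_gene))
    reqs <- list()
    for (i in gene_ev) {
      for (h in ev$carriers[[i]]) {
        reqs[[length(reqs) + 1L]] <- data.frame(
          gene_id = ev$overlaps_gene[i],
          haplotype = cohort$manifest$haplotype[h],
          event_id = ev$event_id[i], stringsAsFactors = FALSE)
      }
      reqs[[length(reqs) + 1L]] <- data.frame(
        gene_id = ev$overlaps_gene[i],
        haplotype = cohort$manifest$haplotype[1],
        event_id = NA_character_, stringsAsFactors = FALSE)
    }
    requests <- if (length(reqs)) do.call(rbind, reqs) else
      data.frame(gene_id = character(), haplotype = character(),
                 event_id = character(), stringsAsFactors = FALSE)
  }
  if (nrow(requests) == 0) {
    return(list(reads = Biostrings::DNAStringSet(),
                truth = data.frame(read_id = character(), gene_id = character(),
                                   event_id = character(),
                                   haplotype = character())))
  }
  # validate: paralog must exist in the named haplotype
  hap_idx <- match(requests$haplotype, cohort$manifest$haplotype)
  if (anyNA(hap_idx)) stop("unknown haplotype in requests")
  for (r in seq_len(nrow(requests))) {
    eid <- requests$event_id[r]
    if (!is.na(eid)) {
      i <- match(eid, ev$event_id)
      if (is.na(i)) stop("unknown event: ", eid)
      if (!(hap_idx[r] %in% ev$carriers[[i]]))
        stop("paralog ", eid, " absent from haplotype ", requests$haplotype[r])
    }
  }
  seed <- seed %||% derive_seed(cohort$config$seed, "transcripts")
  with_seed(seed, {
    seqs <- character(nrow(requests))
    for (r in seq_len(nrow(requests))) {
      s <- if (is.na(requests$event_id[r]))
        gene_mrna(cohort$reference, requests$gene_id[r])
      else .paralog_mrna(cohort, requests$gene_id[r], requests$event_id[r])
      if (error_rate > 0)
        s <- paste(.mutate_chars(strsplit(s, "")[[1]], error_rate), collapse = "")
      seqs[r] <- s
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("tx%04d", seq_len(nrow(requests)))
    list(reads = reads,
         truth = data.frame(read_id = names(reads),
                            gene_id = requests$gene_id,
                            event_id = requests$event_id,
                            haplotype = requests$haplotype,
                            stringsAsFactors = FALSE))
  })
}
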