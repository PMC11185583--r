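# Read-depth copy number: windowed depth with repeat masking, GC-bias
# recalibration anchored on a k-mer self-decomposition of the reference,
# per-gene medians, and per-gene adjustment factors against assembly CN.

#' Windowed read depth with repeat masking
#'
#' Attaches the tandem-repeat/low-complexity mask: a window is masked when
#' the mask covers more than `max_mask_frac` of it.
#'
#' @param reference an `sd_reference` or DNAStringSet (for window GC).
#' @param depth either an `sd_depth` object from [simulate_depth()] (the
#'   per-sample matrix is carried along) or a data.frame
#'   (`chrom`, `start`, `end`, `depth`) on the same window grid.
#' @param mask BED-style data.frame or GRanges; NULL for no mask.
#' @param window_size window width; inferred from `depth` when omitted.
#' @param max_mask_frac masking threshold (strictly greater than).
#' @return data.frame of windows: `chrom`, `start`, `end`, `gc`,
#'   `raw_depth` (or one `depth_<sample>` column per sample), `masked`.
#' @export
window_depth <- function(reference, depth, mask = NULL, window_size = NULL,
                         max_mask_frac = 0.10) {
  seqs <- if (inherits(reference, "sd_reference")) reference$sequences else reference
  if (inherits(depth, "sd_depth")) {
    windows <- depth$windows
    dmat <- depth$depth
  } else {
    windows <- depth[, c("chrom", "start", "end")]
    if (!"gc" %in% names(depth)) {
      ws <- unique(depth$end - depth$start)
      windows <- .tile_windows(seqs, window_size %||% max(ws))
      stopifnot(nrow(windows) == nrow(depth))
    } else windows$gc <- depth$gc
    dmat <- matrix(depth$depth, ncol = 1, dimnames = list(NULL, "raw_depth"))
  }
  if (!"gc" %in% names(windows)) {
    tl <- .tile_windows(seqs, unique(windows$end - windows$start)[1])
    windows$gc <- tl$gc[match(paste(windows$chrom, windows$start),
                              paste(tl$chrom, tl$start))]
  }
  frac <- if (is.null(mask)) numeric(nrow(windows)) else
    .window_cov_frac(windows, if (methods::is(mask, "GRanges")) gr_to_bed(mask)
                     else mask)
  out <- cbind(windows, as.data.frame(dmat))
  if (ncol(dmat) == 1L && colnames(dmat)[1] != "raw_depth")
    names(out)[ncol(out)] <- "raw_depth"
  out$masked <- frac > max_mask_frac
  out
}

#' Recalibrate the GC correction curve
#'
#' Decomposes the reference into overlapping `kmer`-mers as artificial
#' unbiased reads to obtain each window's expected multiplicity for a
#' perfectly matched sample (duplicated windows legitimately exceed 1).  The
#' GC curve is then estimated from observed depth of unmasked,
#' multiplicity-1 windows: per GC bin, factor = global mean depth / bin mean
#' depth.  Without observed depth the artificial reads themselves are used,
#' which yields a flat curve (factors 1) — the self-consistency baseline.
#' Bins with fewer than `min_bin_windows` windows are filled by linear
#' interpolation from occupied neighbours and flagged.
#'
#' @param reference an `sd_reference` or DNAStringSet.
#' @param windows optional window table from [window_depth()] with a
#'   `raw_depth` (or single sample) column.
#' @param window_size window width used to summarize multiplicity.
#' @param kmer decomposition k-mer size.
#' @param bin_width GC bin width.
#' @param min_bin_windows occupancy needed for a bin to be estimated
#'   directly.
#' @param depth_col which depth column of `windows` to use.
#' @return data.frame of class `gc_curve` (`gc_bin`, `factor`, `n_windows`,
#'   `interpolated`) with attribute `multiplicity` (per-window mean k-mer
#'   multiplicity on the reference grid).
#' @export
recalibrate_gc <- function(reference, windows = NULL, window_size = 1000L,
                           kmer = 36L, bin_width = 0.01, min_bin_windows = 50L,
                           depth_col = "raw_depth") {
  seqs <- if (inherits(reference, "sd_reference")) reference$sequences else reference
  seq_chr <- .as_seq_chr(seqs)
  mult <- .kmer_multiplicity(seq_chr, as.integer(kmer))
  grid <- .tile_windows(if (methods::is(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(seq_chr), window_size)
  wmult <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- mult[[grid$chrom[i]]]
    lo <- grid$start[i] + 1L
    hi <- min(grid$end[i], length(v))
    if (hi >= lo) {
      vv <- v[lo:hi]
      vv <- vv[vv > 0]
      wmult[i] <- if (length(vv)) mean(vv) else NA_real_
    } else wmult[i] <- NA_real_
  }
  if (is.null(windows)) {
    tab <- grid
    tab$raw_depth <- wmult  # artificial unbiased reads
    tab$masked <- FALSE
    tab$mult <- wmult
    depth_col <- "raw_depth"
  } else {
    tab <- windows
    tab$mult <- wmult[match(paste(tab$chrom, tab$start),
                            paste(grid$chrom, grid$start))]
  }
  use <- !tab$masked & !is.na(tab$mult) & tab$mult < 1.05 & tab$mult > 0.95 &
    !is.na(tab[[depth_col]])
  if (!any(use)) stop("no unique unmasked windows available for GC estimation")
  gcb <- floor(tab$gc[use] / bin_width) * bin_width
  dep <- tab[[depth_col]][use]
  gmean <- mean(dep)
  bins <- sort(unique(gcb))
  bmean <- tapply(dep, gcb, mean)[as.character(bins)]
  bn <- as.integer(table(gcb)[as.character(bins)])
  occupied <- bn >= min_bin_windows & bmean > 0
  if (!any(occupied)) stop("no GC bin reaches the occupancy threshold")
  fac <- rep(NA_real_, length(bins))
  fac[occupied] <- gmean / bmean[occupied]
  if (any(!occupied)) {
    fac[!occupied] <- approx(bins[occupied], fac[occupied], xout = bins[!occupied],
                             rule = 2)$y
  }
  out <- data.frame(gc_bin = bins, factor = fac, n_windows = bn,
                    interpolated = !occupied)
  class(out) <- c("gc_curve", "data.frame")
  attr(out, "multiplicity") <- wmult
  attr(out, "bin_width") <- bin_width
  out
}

#' Apply a GC curve to window depths
#'
#' @param windows window table from [window_depth()].
#' @param curve a `gc_curve` (NULL = no correction).
#' @param depth_col depth column to correct.
#' @return numeric vector of corrected depths.
#' @export
apply_gc_curve <- function(windows, curve, depth_col = "raw_depth") {
  d <- windows[[depth_col]]
  if (is.null(curve)) return(d)
  bw <- attr(curve, "bin_width") %||% 0.01
  b <- floor(windows$gc / bw) * bw
  i <- findInterval(b, curve$gc_bin)
  i[i < 1] <- 1L
  d * curve$factor[i]
}

#' Per-window copy-number estimates
#'
#' Corrects depth by the GC curve and scales so the modal unmasked
#' unique-sequence window sits at copy number 2.  Masked windows carry `NA`.
#'
#' @param windows window table from [window_depth()].
#' @param curve optional `gc_curve` from [recalibrate_gc()].
#' @param depth_col depth column to convert.
#' @return `windows` with added `cn_estimate` column (and attribute
#'   `mode_depth`).
#' @export
window_cn <- function(windows, curve = NULL, depth_col = "raw_depth") {
  corrected <- apply_gc_curve(windows, curve, depth_col)
  sel <- !windows$masked
  if (!is.null(curve) && !is.null(attr(curve, "multiplicity"))) {
    m <- attr(curve, "multiplicity")
    if (length(m) == nrow(windows)) sel <- sel & !is.na(m) & abs(m - 1) < 0.05
  }
  x <- corrected[sel]
  if (!length(x)) stop("no unmasked windows to anchor the scale")
  dens <- density(x, na.rm = TRUE)
  mode_depth <- dens$x[which.max(dens$y)]
  cn <- 2 * corrected / mode_depth
  cn[windows$masked] <- NA_real_
  windows$cn_estimate <- cn
  attr(windows, "mode_depth") <- mode_depth
  windows
}

#' Per-gene read-depth copy number
#'
#' Median `cn_estimate` over unmasked windows fully contained within each
#' gene's bounds; genes without an eligible window get `NA` with a reason.
#'
#' @param windows window table carrying `cn_estimate` (see [window_cn()]).
#' @param genes data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @return data.frame (`gene_id`, `cn`, `n_windows`, `reason`).
#' @export
gene_cn <- function(windows, genes) {
  stopifnot("cn_estimate" %in% names(windows))
  wgr <- bed_to_gr(windows[, c("chrom", "start", "end")])
  out <- data.frame(gene_id = genes$gene_id, cn = NA_real_, n_windows = 0L,
                    reason = NA_character_, stringsAsFactors = FALSE)
  ggr <- bed_to_gr(genes[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(wgr, ggr, type = "within")
  for (i in seq_len(nrow(genes))) {
    wi <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    wi <- wi[!windows$masked[wi]]
    if (!length(wi)) {
      out$reason[i] <- "no_unmasked_window_contained"
      next
    }
    out$cn[i] <- median(windows$cn_estimate[wi])
    out$n_windows[i] <- length(wi)
  }
  out
}

#' Per-gene adjustment factors against assembly copy number
#'
#' factor = assembly CN / depth CN, taking the assembly calls on the
#' reference sample as ground truth; genes needing more than a 50% adjustment
#' (`|factor - 1| > max_adjust`, or `|log2 factor| > log2(1 + max_adjust)`
#' with `log_scale = TRUE`) are excluded.
#'
#' @param depth_cn named numeric vector (or `gene_cn()` table) of depth CN on
#'   the reference sample.
#' @param assembly_cn named numeric vector of assembly CN ground truth.
#' @param max_adjust exclusion threshold (0.5 = "50% adjustment").
#' @param log_scale use the symmetric log2 criterion instead.
#' @return data.frame (`gene_id`, `depth_cn`, `assembly_cn`, `factor`,
#'   `excluded`, `reason`).
#' @export
calibrate_adjustments <- function(depth_cn, assembly_cn, max_adjust = 0.5,
                                  log_scale = FALSE) {
  if (is.data.frame(depth_cn)) depth_cn <- setNames(depth_cn$cn, depth_cn$gene_id)
  genes <- intersect(names(depth_cn), names(assembly_cn))
  out <- data.frame(gene_id = genes, depth_cn = depth_cn[genes],
                    assembly_cn = assembly_cn[genes], factor = NA_real_,
                    excluded = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    d <- out$depth_cn[i]; a <- out$assembly_cn[i]
    if (is.na(d) || is.na(a)) {
      out$excluded[i] <- TRUE; out$reason[i] <- "missing"
    } else if (d == 0 && a > 0) {
      out$excluded[i] <- TRUE; out$reason[i] <- "unalignable"
    } else if (d == 0) {
      out$excluded[i] <- TRUE; out$reason[i] <- "undefined"
    } else {
      f <- a / d
      out$factor[i] <- f
      too_big <- if (log_scale) abs(log2(f)) > log2(1 + max_adjust) else
        abs(f - 1) > max_adjust
      if (too_big) {
        out$excluded[i] <- TRUE
        out$reason[i] <- "adjustment_over_threshold"
      }
    }
  }
  rownames(out) <- NULL
  out
}
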