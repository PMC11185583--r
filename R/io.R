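# On-disk interchange: FASTA via Biostrings, BED/GFF3 via rtracklayer,
# TSV via data.table.  All tables keep 0-based half-open coordinates; BED and
# GFF3 conversions go through GRanges.

#' Write SD pairs as a SEDEF-like TSV
#'
#' Columns: seqA, startA, endA, seqB, startB, endB, strand (+/-),
#' aligned_length, identity.
#'
#' @param pairs `sd_pairs` data.frame.
#' @param path output file.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- data.frame(
    seqA = pairs$seq_a, startA = pairs$start_a, endA = pairs$end_a,
    seqB = pairs$seq_b, startB = pairs$start_b, endB = pairs$end_b,
    strand = ifelse(pairs$orientation == "direct", "+", "-"),
    aligned_length = pairs$aligned_length, identity = pairs$identity)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read SD pairs from a SEDEF-like TSV
#' @param path file written by [write_pairs_tsv()].
#' @return `sd_pairs` data.frame.
#' @export
read_pairs_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  out <- data.frame(
    seq_a = x$seqA, start_a = x$startA, end_a = x$endA,
    seq_b = x$seqB, start_b = x$startB, end_b = x$endB,
    orientation = ifelse(x$strand == "+", "direct", "inverted"),
    aligned_length = x$aligned_length, identity = x$identity,
    stringsAsFactors = FALSE)
  class(out) <- c("sd_pairs", "data.frame")
  out
}

.need_rtracklayer <- function() {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED/GFF3 IO")
}

#' Write a BED-style data.frame to a BED file
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  .need_rtracklayer()
  gr <- bed_to_gr(df[, c("chrom", "start", "end")])
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a BED-style data.frame
#' @param path BED file.
#' @export
read_bed <- function(path) {
  .need_rtracklayer()
  gr_to_bed(rtracklayer::import(path, format = "BED"))[, c("chrom", "start", "end")]
}

#' Write a synthetic cohort to disk
#'
#' reference.fa, one FASTA per haplotype, genes.gff3, trf_mask.bed,
#' manifest.tsv, truth tables (events, copies, gene CN) as TSV.
#'
#' @param cohort an `sd_cohort`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  .need_rtracklayer()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- cohort$reference
  Biostrings::writeXStringSet(ref$sequences, file.path(outdir, "reference.fa"))
  for (h in names(cohort$haplotypes))
    Biostrings::writeXStringSet(cohort$haplotypes[[h]],
                                file.path(outdir, paste0(h, ".fa")))
  # gene models as GFF3 (gene + exon features)
  g <- ref$genes; e <- ref$exons
  ggr <- bed_to_gr(data.frame(chrom = g$chrom, start = g$start, end = g$end))
  S4Vectors::mcols(ggr) <- S4Vectors::DataFrame(type = "gene", ID = g$gene_id)
  egr <- bed_to_gr(data.frame(chrom = e$chrom, start = e$start, end = e$end))
  S4Vectors::mcols(egr) <- S4Vectors::DataFrame(
    type = "exon", ID = paste0(e$gene_id, ".e", e$exon), Parent = e$gene_id)
  GenomicRanges::strand(ggr) <- g$strand
  rtracklayer::export(c(ggr, egr), file.path(outdir, "genes.gff3"), format = "GFF3")
  write_bed(ref$trf, file.path(outdir, "trf_mask.bed"))
  data.table::fwrite(cohort$manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  ev <- cohort$truth$events
  ev$carriers <- vapply(ev$carriers, paste, "", collapse = ",")
  data.table::fwrite(ev, file.path(outdir, "truth_events.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$copies, file.path(outdir, "truth_copies.tsv"),
                     sep = "\t")
  cn <- as.data.frame(cohort$truth$gene_truth_cn)
  cn <- cbind(gene_id = rownames(cn), cn)
  data.table::fwrite(cn, file.path(outdir, "truth_gene_cn.tsv"), sep = "\t")
  invisible(outdir)
}

#' Write a depth simulation as long-format TSV
#' @param depth `sd_depth` object.
#' @param path output file.
#' @export
write_depth_tsv <- function(depth, path) {
  w <- depth$windows
  long <- do.call(rbind, lapply(colnames(depth$depth), function(s)
    data.frame(sample = s, chrom = w$chrom, start = w$start, end = w$end,
               gc = w$gc, depth = depth$depth[, s], stringsAsFactors = FALSE)))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}
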