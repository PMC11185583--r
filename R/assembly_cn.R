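# Assembly-based gene copy number: map reference gene sequences to each
# haplotype assembly, count non-redundant qualifying alignments, aggregate
# to gene families, rank variability by dispersion index, and test for
# population-differentiated copy number.

#' Parameters for assembly-based copy-number mapping
#'
#' @param min_coverage minimum fraction of the gene covered by an alignment.
#' @param min_identity minimum per-column alignment identity.
#' @param min_cds_bp genes with shorter coding sequence are excluded.
#' @param break_buffer_bp copies within this distance of a contig end are
#'   flagged unreliable (assembly-break guard).
#' @param exclude_single_haplotype_duplicates flag genes whose duplication is
#'   observed in exactly one haplotype cohort-wide.
#' @param max_mutual_overlap redundancy threshold: two alignments are
#'   redundant when they mutually overlap more than this fraction of the
#'   shorter one.
#' @param kmer_size,max_chain_gap_bp,diag_band_bp,max_kmer_occ seeding and
#'   chaining controls (see [sd_detect_params()]).
#' @return list of class `cn_map_params`.
#' @export
cn_map_params <- function(min_coverage = 0.60, min_identity = 0.90,
                          min_cds_bp = 200L, break_buffer_bp = 30000L,
                          exclude_single_haplotype_duplicates = TRUE,
                          max_mutual_overlap = 0.5, kmer_size = 15L,
                          max_chain_gap_bp = 2000L, diag_band_bp = 100L,
                          max_kmer_occ = 100L) {
  stopifnot(min_coverage > 0, min_coverage <= 1, min_identity > 0,
            min_identity <= 1, min_cds_bp > 0, break_buffer_bp > 0)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 min_cds_bp = as.integer(min_cds_bp),
                 break_buffer_bp = as.integer(break_buffer_bp),
                 exclude_single_haplotype_duplicates =
                   exclude_single_haplotype_duplicates,
                 max_mutual_overlap = max_mutual_overlap,
                 kmer_size = as.integer(kmer_size),
                 max_chain_gap_bp = as.integer(max_chain_gap_bp),
                 diag_band_bp = as.integer(diag_band_bp),
                 max_kmer_occ = as.integer(max_kmer_occ)),
            class = "cn_map_params")
}

#' Build a reusable k-mer index of an assembly
#'
#' @param sequences DNAStringSet or named character vector.
#' @param k seed k-mer size.
#' @return list of class `assembly_index` (external-pointer based; rebuild
#'   rather than serialize).
#' @export
build_assembly_index <- function(sequences, k = 15L) {
  sequences <- .as_seq_chr(sequences)
  structure(list(xp = .kmer_index_build(sequences, k, list()),
                 names = names(sequences), lens = nchar(sequences),
                 k = as.integer(k), sequences = sequences),
            class = "assembly_index")
}

# map a query sequence against an indexed assembly; returns qualifying,
# non-redundant local alignments
.map_query <- function(query, index, params) {
  k <- index$k
  seeds <- .kmer_index_query(index$xp, setNames(query, "q"), FALSE, 0L,
                             params$max_kmer_occ, 5e6)
  if (nrow(seeds) == 0) return(NULL)
  chains <- chain_seeds(seeds, k, params$diag_band_bp, params$max_chain_gap_bp)
  qlen <- nchar(query)
  chains <- chains[(q_end - q_start) >= 0.4 * params$min_coverage * qlen &
                     n_seeds >= 5L]
  if (nrow(chains) == 0) return(NULL)
  res <- list()
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i]
    fl <- 200L
    ts <- max(0L, ch$t_start - fl)
    te <- min(index$lens[ch$tseq], ch$t_end + fl)
    twin <- .subseq0(index$sequences[[ch$tseq]], ts, te)
    subj <- if (ch$strand == 1L) twin else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(twin)))
    d0 <- if (ch$strand == 1L) ch$diag0 - ts else te - k - ch$diag0
    r <- .banded_local_align(query, subj, as.integer(d0),
                             params$diag_band_bp + 100L, 1, -3, -5)
    if (r$score <= 0) next
    identity <- r$matches / (r$matches + r$mismatches + r$gap_columns)
    coverage <- (r$a_end - r$a_start) / qlen
    if (ch$strand == 1L) { t0 <- ts + r$b_start; t1 <- ts + r$b_end } else {
      L <- te - ts
      t0 <- ts + L - r$b_end; t1 <- ts + L - r$b_start
    }
    res[[length(res) + 1L]] <- data.frame(
      target = index$names[ch$tseq], start = t0, end = t1,
      strand = if (ch$strand == 1L) "+" else "-",
      coverage = coverage, identity = identity,
      score = r$score, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(NULL)
  hits <- do.call(rbind, res)
  # greedy non-redundant selection by score
  hits <- hits[order(-hits$score, hits$target, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || hits$target[i] != hits$target[j]) next
      ov <- max(0, min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]))
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov > params$max_mutual_overlap * shorter) { keep[i] <- FALSE; break }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count copies of a gene in one haplotype assembly
#'
#' Non-redundant local alignments of the gene sequence passing the coverage
#' and identity thresholds.  Alignments completely contained in the repeat
#' mask are removed; copies within `break_buffer_bp` of a contig end are
#' flagged unreliable.
#'
#' @param gene_seq gene genomic sequence (character or DNAString).
#' @param haplotype DNAStringSet / named character vector, or a prebuilt
#'   [build_assembly_index()].
#' @param params a [cn_map_params()] object.
#' @param repeat_mask optional BED-style data.frame or GRanges in haplotype
#'   coordinates.
#' @return list: `count` (reliable qualifying copies), `hits` (alignment
#'   table with `qualifies` and `reliable` flags).
#' @export
map_gene_copies <- function(gene_seq, haplotype, params = cn_map_params(),
                            repeat_mask = NULL) {
  index <- if (inherits(haplotype, "assembly_index")) haplotype else
    build_assembly_index(haplotype, params$kmer_size)
  gene_seq <- as.character(gene_seq)
  hits <- .map_query(gene_seq, index, params)
  if (is.null(hits)) {
    return(list(count = 0L,
                hits = data.frame(target = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  coverage = numeric(), identity = numeric(),
                                  score = numeric(), qualifies = logical(),
                                  reliable = logical())))
  }
  hits$qualifies <- hits$coverage >= params$min_coverage &
    hits$identity >= params$min_identity
  if (!is.null(repeat_mask)) {
    mgr <- if (methods::is(repeat_mask, "GRanges")) repeat_mask else
      bed_to_gr(repeat_mask)
    hgr <- bed_to_gr(data.frame(chrom = hits$target, start = hits$start,
                                end = hits$end))
    inside <- IRanges::overlapsAny(hgr, mgr, type = "within")
    hits$qualifies <- hits$qualifies & !inside
  }
  tlen <- index$lens[match(hits$target, index$names)]
  hits$reliable <- hits$start >= params$break_buffer_bp &
    (tlen - hits$end) >= params$break_buffer_bp
  # contigs shorter than twice the buffer would flag everything; only apply
  # the guard when the contig is long enough to satisfy it
  short <- tlen < 2 * params$break_buffer_bp + (hits$end - hits$start)
  hits$reliable[short] <- TRUE
  list(count = sum(hits$qualifies & hits$reliable), hits = hits)
}

#' Assembly copy-number matrix over a cohort
#'
#' Maps every eligible gene against every haplotype and returns per-haplotype
#' counts and the diploid gene x sample matrix.  Genes failing the CDS-length
#' or single-exon filters are skipped with a reason.  When
#' `exclude_single_haplotype_duplicates` is set, genes whose duplication
#' (count > 1) is seen in exactly one haplotype cohort-wide are flagged.
#'
#' @param genes data.frame with `gene_id`, `cds_bp`, `n_exons` and a
#'   `sequence` column (or pass `gene_seqs` separately).
#' @param haplotypes named list of assemblies (DNAStringSet each), e.g.
#'   `cohort$haplotypes`.
#' @param manifest data.frame (`sample`, `haplotype`) pairing haplotypes to
#'   samples.
#' @param params a [cn_map_params()] object.
#' @param gene_seqs optional named character vector of gene sequences.
#' @param repeat_masks optional named list of per-haplotype repeat masks.
#' @return list of class `cn_matrix`: `cn` (gene x sample diploid counts),
#'   `per_haplotype`, `filtered` (gene, reason), `flagged_single_hap`.
#' @export
assembly_cn_matrix <- function(genes, haplotypes, manifest,
                               params = cn_map_params(), gene_seqs = NULL,
                               repeat_masks = NULL) {
  if (is.null(gene_seqs)) {
    stopifnot("sequence" %in% names(genes))
    gene_seqs <- setNames(genes$sequence, genes$gene_id)
  }
  ok <- genes$cds_bp >= params$min_cds_bp & genes$n_exons > 1L
  filtered <- data.frame(
    gene = genes$gene_id[!ok],
    reason = ifelse(genes$cds_bp[!ok] < params$min_cds_bp,
                    "cds_too_short", "single_exon"),
    stringsAsFactors = FALSE)
  use <- genes$gene_id[ok]
  samples <- unique(manifest$sample)
  per_hap <- matrix(NA_integer_, nrow = length(use), ncol = nrow(manifest),
                    dimnames = list(use, manifest$haplotype))
  for (h in manifest$haplotype) {
    idx <- build_assembly_index(haplotypes[[h]], params$kmer_size)
    mask <- if (!is.null(repeat_masks)) repeat_masks[[h]] else NULL
    for (g in use) {
      per_hap[g, h] <- map_gene_copies(gene_seqs[[g]], idx, params, mask)$count
    }
    # index memory lives outside R's heap; release it before the next build
    rm(idx); gc(FALSE)
  }
  cn <- vapply(samples, function(s) {
    hs <- manifest$haplotype[manifest$sample == s]
    rowSums(per_hap[, hs, drop = FALSE])
  }, numeric(length(use)))
  if (length(use) == 1L) cn <- matrix(cn, nrow = 1L,
                                      dimnames = list(use, samples))
  flagged <- character()
  if (params$exclude_single_haplotype_duplicates && length(use)) {
    dup_haps <- rowSums(per_hap > 1L, na.rm = TRUE)
    flagged <- use[dup_haps == 1L]
  }
  structure(list(cn = cn, per_haplotype = per_hap, filtered = filtered,
                 flagged_single_hap = flagged, source = "assembly"),
            class = "cn_matrix")
}

#' Aggregate a gene-level CN matrix to gene families
#'
#' @param cn gene x sample matrix (or `cn_matrix` list).
#' @param family_map data.frame (`gene_id`, `family`).
#' @return family x sample matrix (sum of member genes).
#' @export
family_cn_matrix <- function(cn, family_map) {
  if (inherits(cn, "cn_matrix")) cn <- cn$cn
  fam <- family_map$family[match(rownames(cn), family_map$gene_id)]
  if (anyNA(fam)) stop("family_map does not cover all genes")
  rowsum(cn, group = fam)
}

#' Dispersion index of copy number across samples
#'
#' Sample variance (n - 1 denominator) divided by the mean.
#'
#' @param mat family (or gene) x sample CN matrix.
#' @return named numeric vector.
#' @export
dispersion_index <- function(mat) {
  apply(mat, 1L, function(x) {
    m <- mean(x)
    if (m == 0) return(0)
    var(x) / m
  })
}

#' Rank gene families by copy-number dispersion
#'
#' Among families with mean diploid CN above `ranking_min_mean_cn`, ranks by
#' dispersion index (variance/mean) and returns the `top_k` most and least
#' variable.
#'
#' @param mat family x sample CN matrix.
#' @param params a [family_variability_params()] object.
#' @return list: `ranking` (family, mean_cn, dispersion, descending), `top`,
#'   `bottom`.
#' @export
dispersion_rank <- function(mat, params = family_variability_params()) {
  mean_cn <- rowMeans(mat)
  eligible <- mean_cn > params$ranking_min_mean_cn
  if (!any(eligible)) stop("no family with mean CN above ranking threshold")
  di <- dispersion_index(mat[eligible, , drop = FALSE])
  ranking <- data.frame(family = names(di), mean_cn = mean_cn[eligible],
                        dispersion = di, stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$dispersion, ranking$family), ]
  rownames(ranking) <- NULL
  k <- min(params$top_k, nrow(ranking))
  list(ranking = ranking, top = head(ranking$family, k),
       bottom = rev(tail(ranking$family, k)))
}

#' Family variability / testing parameters
#'
#' @param variable_dispersion_min dispersion index at or above which a family
#'   counts as copy-number variable.
#' @param min_mean_cn mean diploid CN (in either population) above which a
#'   family is tested.
#' @param ranking_min_mean_cn mean CN above which a family enters the
#'   variability ranking.
#' @param top_k families reported at each end of the ranking.
#' @return list of class `family_variability_params`.
#' @export
family_variability_params <- function(variable_dispersion_min = 0.1,
                                      min_mean_cn = 2, ranking_min_mean_cn = 3,
                                      top_k = 25L) {
  stopifnot(variable_dispersion_min > 0, min_mean_cn > 0,
            ranking_min_mean_cn > 0, top_k > 0)
  structure(list(variable_dispersion_min = variable_dispersion_min,
                 min_mean_cn = min_mean_cn,
                 ranking_min_mean_cn = ranking_min_mean_cn,
                 top_k = as.integer(top_k)),
            class = "family_variability_params")
}

#' One-sided exact binomial test of direction counts
#'
#' Probability of at least `k` successes in `n` trials at rate 0.5; used to
#' summarize how many significant gene families shift towards higher copy
#' number in one population.
#'
#' @param k number of families shifted in the focal direction.
#' @param n number of significant families with a direction.
#' @return the one-sided exact p-value.
#' @export
binomial_direction_test <- function(k, n) {
  stopifnot(k >= 0, n >= k)
  binom.test(k, n, p = 0.5, alternative = "greater")$p.value
}

#' Population-differentiated copy number tests
#'
#' Families with dispersion index at or above `variable_dispersion_min` and
#' mean CN above `min_mean_cn` in either population are tested with a
#' two-sided Mann-Whitney U test (AFR vs non-AFR), Benjamini-Hochberg
#' corrected.  Among significant families the direction is the sign of
#' (AFR mean - non-AFR mean) and the binomial summary is the one-sided exact
#' test of the number shifted higher in AFR against 0.5.
#'
#' @param mat family x sample CN matrix.
#' @param populations per-sample labels (`"AFR"`/`"nonAFR"`), aligned with
#'   the matrix columns.
#' @param params a [family_variability_params()] object.
#' @param alpha BH-adjusted significance threshold.
#' @return list: `table` (family, p, p_adj, direction, significant),
#'   `binomial` (k, n, p_value), `n_tested`.
#' @export
population_cn_tests <- function(mat, populations,
                                params = family_variability_params(),
                                alpha = 0.05) {
  stopifnot(length(populations) == ncol(mat))
  afr <- populations == "AFR"
  if (sum(afr) < 2 || sum(!afr) < 2)
    stop("each population needs at least two samples")
  di <- dispersion_index(mat)
  mean_afr <- rowMeans(mat[, afr, drop = FALSE])
  mean_non <- rowMeans(mat[, !afr, drop = FALSE])
  test_it <- di >= params$variable_dispersion_min &
    (mean_afr > params$min_mean_cn | mean_non > params$min_mean_cn)
  fams <- rownames(mat)[test_it]
  if (!length(fams)) {
    return(list(table = data.frame(family = character(), p = numeric(),
                                   p_adj = numeric(), direction = integer(),
                                   significant = logical()),
                binomial = list(k = 0L, n = 0L, p_value = NA_real_),
                n_tested = 0L))
  }
  p <- vapply(fams, function(f) {
    suppressWarnings(wilcox.test(mat[f, afr], mat[f, !afr],
                                 alternative = "two.sided")$p.value)
  }, 1.0)
  p_adj <- p.adjust(p, method = "BH")
  direction <- sign(mean_afr[fams] - mean_non[fams])
  significant <- p_adj <= alpha
  k <- sum(significant & direction > 0)
  n <- sum(significant & direction != 0)
  tab <- data.frame(family = fams, p = p, p_adj = p_adj,
                    direction = as.integer(direction),
                    significant = significant, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       binomial = list(k = k, n = n,
                       p_value = if (n > 0) binomial_direction_test(k, n)
                       else NA_real_),
       n_tested = length(fams))
}

#' Paralog presence matrix across haplotypes
#'
#' @param counts data.frame (`paralog`, `haplotype`, `count`) with optional
#'   logical `missing` column (e.g. contig break within the buffer of the
#'   locus); missing cells become `NA`, not 0.
#' @return list: `matrix` (paralog x haplotype, NA = missing) and `labels`
#'   per paralog: `fixed_single_copy` (all observed counts are 1),
#'   `variable_never_deleted` (min >= 1, max > 1), `deletable` (min is 0).
#' @export
paralog_presence_matrix <- function(counts) {
  paralogs <- unique(counts$paralog)
  haps <- unique(counts$haplotype)
  m <- matrix(NA_integer_, length(paralogs), length(haps),
              dimnames = list(paralogs, haps))
  for (i in seq_len(nrow(counts))) {
    miss <- if ("missing" %in% names(counts)) isTRUE(counts$missing[i]) else FALSE
    m[counts$paralog[i], counts$haplotype[i]] <-
      if (miss) NA_integer_ else as.integer(counts$count[i])
  }
  labels <- vapply(paralogs, function(p) {
    v <- m[p, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    if (min(v) == 0) "deletable"
    else if (max(v) > 1) "variable_never_deleted"
    else "fixed_single_copy"
  }, "")
  list(matrix = m, labels = labels)
}

#' Concordance between assembly and read-depth copy number
#'
#' R-squared of the least-squares fit of depth CN on assembly CN over shared
#' gene x sample cells.
#'
#' @param assembly_cn,depth_cn matrices with shared row/column names (or
#'   equal shapes).
#' @return R-squared.
#' @export
assembly_vs_depth_concordance <- function(assembly_cn, depth_cn) {
  if (inherits(assembly_cn, "cn_matrix")) assembly_cn <- assembly_cn$cn
  genes <- intersect(rownames(assembly_cn), rownames(depth_cn))
  samples <- intersect(colnames(assembly_cn), colnames(depth_cn))
  a <- as.vector(assembly_cn[genes, samples])
  d <- as.vector(depth_cn[genes, samples])
  keep <- complete.cases(a, d)
  a <- a[keep]; d <- d[keep]
  if (length(a) < 2) stop("fewer than two shared gene x sample cells")
  if (var(a) == 0) stop("assembly CN is constant; fit undefined")
  summary(lm(d ~ a))$r.squared
}
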