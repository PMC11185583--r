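# Structural characterization of SD pairs: dispersion and orientation
# configuration, rare-vs-common permutation comparisons, the
# inverted x interspersed association, and the singleton profile.

#' Classify the dispersion configuration of SD pairs
#'
#' Separation is the gap between the nearer ends of the two intervals
#' (0 when they overlap or are book-ended).  Intrachromosomal pairs are
#' `clustered` (separation <= 1 Mbp) or `interspersed` (> 1 Mbp); pairs more
#' than 50 Mbp apart are additionally flagged `distant` (a subset of
#' interspersed).  Pairs on different chromosomes are `interchromosomal`.
#'
#' @param pairs an `sd_pairs` data.frame.
#' @param interspersed_min_bp separation above which a pair is interspersed.
#' @param distant_min_bp separation above which a pair is flagged distant.
#' @return `pairs` with added `separation_bp`, `dispersion_class` and
#'   `distant` columns.
#' @export
classify_configuration <- function(pairs, interspersed_min_bp = 1e6,
                                   distant_min_bp = 5e7) {
  if (nrow(pairs) == 0) {
    pairs$separation_bp <- integer()
    pairs$dispersion_class <- character()
    pairs$distant <- logical()
    return(pairs)
  }
  same <- pairs$seq_a == pairs$seq_b
  sep <- ifelse(same,
                pmax(0, pmax(pairs$start_a, pairs$start_b) -
                       pmin(pairs$end_a, pairs$end_b)),
                NA_real_)
  pairs$separation_bp <- sep
  pairs$dispersion_class <- ifelse(!same, "interchromosomal",
                                   ifelse(sep > interspersed_min_bp,
                                          "interspersed", "clustered"))
  pairs$distant <- same & sep > distant_min_bp
  pairs
}

#' Permutation comparison of rare versus common SD properties
#'
#' Statistic: difference in medians (rare minus common) of `aligned_length`
#' and of `identity`.  Null: permutation of the rare/common labels.
#' One-sided empirical p-values (rare larger) with the +1 correction.
#'
#' @param pairs data.frame with `aligned_length`, `identity` and a `freq_bin`
#'   column containing `"rare"`/`"common"` labels (e.g. pairs annotated with
#'   the frequency bin of their region).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `p_length`, `p_identity`, the observed median
#'   differences, and the group sizes.
#' @export
rare_common_compare <- function(pairs, n_perm = 999L, seed = 1L) {
  rare <- pairs$freq_bin == "rare"
  common <- pairs$freq_bin == "common"
  if (!any(rare)) stop("no pairs in class: rare")
  if (!any(common)) stop("no pairs in class: common")
  x <- pairs[rare | common, , drop = FALSE]
  lab <- x$freq_bin == "rare"
  stat <- function(lab, v) median(v[lab]) - median(v[!lab])
  obs_len <- stat(lab, x$aligned_length)
  obs_id <- stat(lab, x$identity)
  perms <- with_seed(seed, replicate(n_perm, {
    pl <- sample(lab)
    c(stat(pl, x$aligned_length), stat(pl, x$identity))
  }))
  list(
    p_length = perm_pvalue(obs_len, perms[1, ], "ge"),
    p_identity = perm_pvalue(obs_id, perms[2, ], "ge"),
    observed_length_diff = obs_len, observed_identity_diff = obs_id,
    n_rare = sum(rare), n_common = sum(common)
  )
}

#' Association between interspersed placement and inverted orientation
#'
#' Builds the 2x2 table of dispersion (interspersed vs clustered) by
#' orientation (inverted vs direct) and reports the cross-product odds ratio
#' `(a*d)/(b*c)` with the two-sided Fisher exact p-value.
#'
#' @param configurations output of [classify_configuration()] (only
#'   intrachromosomal pairs enter the table), or a 2x2 matrix
#'   `rbind(interspersed = c(inverted, direct), clustered = c(inverted, direct))`.
#' @return list: `odds_ratio` (`Inf` flagged `unbounded` when a denominator
#'   cell is zero), `p_value`, and the `table`.
#' @export
inverted_interspersed_test <- function(configurations) {
  if (is.matrix(configurations)) {
    tab <- configurations
  } else {
    x <- configurations[configurations$dispersion_class %in%
                          c("interspersed", "clustered"), , drop = FALSE]
    tab <- matrix(c(
      sum(x$dispersion_class == "interspersed" & x$orientation == "inverted"),
      sum(x$dispersion_class == "interspersed" & x$orientation == "direct"),
      sum(x$dispersion_class == "clustered" & x$orientation == "inverted"),
      sum(x$dispersion_class == "clustered" & x$orientation == "direct")),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("interspersed", "clustered"), c("inverted", "direct")))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("2x2 table has a zero margin")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  unbounded <- (b * c_) == 0
  or <- if (unbounded) Inf else (a * d) / (b * c_)
  p <- fisher.test(tab)$p.value
  list(odds_ratio = or, unbounded = unbounded, p_value = p, table = tab)
}

#' Profile of singleton SD configurations
#'
#' Counts singleton pairs (single occurrence in one genome) by dispersion
#' class and orientation, per haplotype, plus the pooled fraction of
#' singletons that are clustered.  When read-depth validation columns are
#' supplied, a singleton is only counted if its locus copy-number estimate
#' exceeds the sample median by at least `min_cn_excess`.
#'
#' @param configurations data.frame from [classify_configuration()] with
#'   added `haplotype` and logical `singleton` columns; optional `locus_cn`
#'   and `sample_median_cn` columns enable the read-depth validation hook.
#' @param min_cn_excess copy-number excess required for validation.
#' @return list: `counts` (haplotype x dispersion x orientation table),
#'   `clustered_fraction`, `n_singletons`.
#' @export
singleton_profile <- function(configurations, min_cn_excess = 0.5) {
  x <- configurations[configurations$singleton, , drop = FALSE]
  if (nrow(x) && all(c("locus_cn", "sample_median_cn") %in% names(x))) {
    x <- x[x$locus_cn - x$sample_median_cn >= min_cn_excess, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    return(list(counts = table(haplotype = character(),
                               dispersion = character(),
                               orientation = character()),
                clustered_fraction = NA_real_, n_singletons = 0L))
  }
  counts <- table(haplotype = x$haplotype,
                  dispersion = x$dispersion_class,
                  orientation = x$orientation)
  list(counts = counts,
       clustered_fraction = mean(x$dispersion_class == "clustered"),
       n_singletons = nrow(x))
}
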