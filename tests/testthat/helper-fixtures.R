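# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

# small cohort with planted events, detection run on every haplotype
fixture_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  cfg <- cohort_config(n_chromosomes = 2, chrom_length_bp = 5e5,
                       n_samples = 5, seed = 7)
  ref <- generate_reference(cfg)
  ev <- sample_planted_events(ref, n_fixed = 1, n_high_af = 1, n_common = 2,
                              n_rare = 2, n_private = 2, n_known_poly = 2,
                              n_gene_events = 2)
  coh <- plant_duplications(ref, ev)
  params <- sd_detect_params()
  ref_pairs <- find_sd_pairs(ref$sequences, params, mask = ref$trf)
  ref_fp <- merge_pair_intervals(ref_pairs)
  hap_pairs <- list(); projs <- list()
  for (h in coh$manifest$haplotype) {
    hp <- find_sd_pairs(coh$haplotypes[[h]], params,
                        mask = mask_to_haplotype(ref$trf, coh$alignments[[h]]))
    hap_pairs[[h]] <- hp
    projs[[h]] <- project_to_reference(merge_pair_intervals(hp),
                                       coh$alignments[[h]])$projected
  }
  regions <- build_regions(projs, cfg$n_haplotypes, ref_fp)
  .fixture_env$cohort <- list(cfg = cfg, ref = ref, events = ev, coh = coh,
                              ref_pairs = ref_pairs, ref_fp = ref_fp,
                              hap_pairs = hap_pairs, projs = projs,
                              regions = regions)
  .fixture_env$cohort
}

# random DNA string
rand_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Full (unbanded) dynamic-programming oracle for a pair of loci, independent
# of the detector's seeding/banded-extension path.
dp_oracle_alignment <- function(a, b, inverted = FALSE) {
  if (inverted) b <- revcomp(b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  gap <- pc == "-" | sc == "-"
  m <- sum(!gap & pc == sc); mm <- sum(!gap & pc != sc); g <- sum(gap)
  list(identity = m / (m + mm + g), aligned_length = m + mm + g,
       a_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
       a_end = Biostrings::end(Biostrings::pattern(aln)))
}

# brute-force two-sided Fisher exact p over all tables with the observed
# margins (hypergeometric enumeration)
fisher_oracle_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# step-up Benjamini-Hochberg from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- rep(NA_real_, m)
  for (i in m:1) {
    v <- m * sorted[i] / i
    run[i] <- if (i == m) min(v, 1) else min(v, run[i + 1], 1)
  }
  adj[o] <- run
  adj
}

# exact two-sided Mann-Whitney p by complete enumeration of group assignments
mw_oracle_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n + m, n)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n * (n + 1) / 2
  }
  obs <- u_of(seq_len(n))
  us <- apply(idx, 2, u_of)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-09)
}
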