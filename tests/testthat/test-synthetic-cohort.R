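# Generator contracts: determinism, composition, planting semantics, depth
# and transcript simulation.

test_that("reference generation is deterministic and respects its contracts", {
  cfg <- cohort_config(n_chromosomes = 2, chrom_length_bp = 3e5,
                       n_samples = 2, seed = 1)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$trf, r2$trf)

  # realized GC close to target
  cfg5 <- cohort_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                        n_samples = 2, gc_target = 0.5, seed = 3)
  r5 <- generate_reference(cfg5)
  gc <- sum(Biostrings::letterFrequency(r5$sequences, c("G", "C"))) /
    sum(Biostrings::width(r5$sequences))
  expect_gte(gc, 0.48); expect_lte(gc, 0.52)

  # annotations: at least one multi-exon gene with CDS >= 200 and one tandem
  # tract per chromosome
  for (ch in names(r1$sequences)) {
    g <- r1$genes[r1$genes$chrom == ch, ]
    expect_gte(nrow(g), 1)
    expect_true(all(g$n_exons > 1))
    expect_true(all(g$cds_bp >= 200))
    expect_gte(nrow(r1$trf[r1$trf$chrom == ch, ]), 1)
  }

  expect_error(cohort_config(n_chromosomes = 0), "n_chromosomes")
  expect_error(cohort_config(chrom_length_bp = 50000), "too small")
  expect_error(cohort_config(gc_target = 1.2), "gc_target")
})

test_that("planting inserts carrier copies and leaves non-carriers untouched", {
  cfg <- cohort_config(n_chromosomes = 1, chrom_length_bp = 3e5,
                       n_samples = 2, seed = 2)
  ref <- generate_reference(cfg)

  # no events: every haplotype byte-identical to the reference
  empty <- plant_duplications(ref, data.frame())
  for (h in names(empty$haplotypes))
    expect_identical(as.character(empty$haplotypes[[h]]),
                     as.character(ref$sequences))

  ev <- data.frame(event_id = "e1", mode = "insertion", chrom = "chr1",
                   start = 100000L, end = 102000L, target_chrom = "chr1",
                   target_pos = 150000L, orientation = "inverted",
                   divergence = 0.05, stringsAsFactors = FALSE)
  ev$carriers <- list(c(1L, 3L))
  coh <- plant_duplications(ref, ev)
  # carrier haplotypes are 2 kbp longer, non-carriers identical
  w <- sapply(coh$haplotypes, function(x) Biostrings::width(x)[1])
  expect_equal(unname(w[c(1, 3)]), rep(302000L, 2))
  expect_equal(unname(w[c(2, 4)]), rep(300000L, 2))

  # the planted copy is the reverse complement of the mutated source, with a
  # realized substitution count within 3 SD of Binomial(2000, 0.05)
  src <- as.character(Biostrings::subseq(ref$sequences[["chr1"]], 100001, 102000))
  cp <- coh$event_seqs[["e1"]]
  mism <- sum(strsplit(revcomp(cp), "")[[1]] != strsplit(src, "")[[1]])
  expect_lt(abs(mism - 2000 * 0.05), 3 * sqrt(2000 * 0.05 * 0.95))

  # copy sequence appears verbatim at the target in carriers only
  hap1 <- as.character(coh$haplotypes[[1]][["chr1"]])
  expect_identical(substr(hap1, 150001, 152000), cp)
  hap2 <- as.character(coh$haplotypes[[2]][["chr1"]])
  expect_identical(hap2, as.character(ref$sequences[["chr1"]]))

  # errors: carrier out of range, overlapping targets, too-short event
  bad <- ev; bad$carriers <- list(99L)
  expect_error(plant_duplications(ref, bad), "carrier")
  two <- rbind(ev, ev); two$event_id <- c("a", "b")
  two$carriers <- list(1L, 1L)
  expect_error(plant_duplications(ref, two), "overlapping target")
  short <- ev; short$end <- ev$start + 500L
  expect_error(plant_duplications(ref, short), "1 kbp")
})

test_that("gene copy-number truth is consistent with planted events", {
  fx <- fixture_cohort()
  cn <- fx$coh$truth$gene_truth_cn
  ev <- fx$coh$truth$events
  n_genes <- nrow(fx$ref$genes)
  manifest <- fx$coh$manifest
  for (s in colnames(cn)) {
    haps <- manifest$hap_index[manifest$sample == s]
    planted <- 0L
    for (i in seq_len(nrow(ev))) {
      if (ev$mode[i] == "insertion" && !is.na(ev$overlaps_gene[i]))
        planted <- planted + sum(haps %in% ev$carriers[[i]])
    }
    expect_equal(sum(cn[, s]), 2L * n_genes + planted)
  }
})

test_that("depth follows the copy-number x GC model", {
  cfg <- cohort_config(n_chromosomes = 2, chrom_length_bp = 6e5,
                       n_samples = 1, ref_sds_per_chrom = 0, seed = 4)
  ref <- generate_reference(cfg)
  coh <- plant_duplications(ref, data.frame())
  # flat curve, CN 2 everywhere: mean depth within 2% of base over >= 1000 windows
  dep <- simulate_depth(coh, gc_bias_curve = NULL)
  expect_gte(nrow(dep$windows), 1000)
  expect_lt(abs(mean(dep$depth[, 1]) - cfg$base_depth), 0.02 * cfg$base_depth)
  # determinism
  dep2 <- simulate_depth(coh, gc_bias_curve = NULL)
  expect_identical(dep$depth, dep2$depth)
  expect_error(simulate_depth(coh, window_size = 0), "window_size")

  # a duplication carried on both haplotypes doubles expected depth
  ev <- data.frame(event_id = "e1", mode = "insertion", chrom = "chr1",
                   start = 200000L, end = 240000L, target_chrom = "chr2",
                   target_pos = 300000L, orientation = "direct",
                   divergence = 0, stringsAsFactors = FALSE)
  ev$carriers <- list(c(1L, 2L))
  coh2 <- plant_duplications(ref, ev)
  dep2 <- simulate_depth(coh2, gc_bias_curve = NULL)
  w <- dep2$windows
  inside <- w$chrom == "chr1" & w$start >= 200000 & w$end <= 240000
  flank <- w$chrom == "chr1" & (w$end <= 200000 | w$start >= 240000)
  expect_lt(abs(mean(dep2$depth[inside, 1]) / mean(dep2$depth[flank, 1]) - 2),
            0.15)

  # a curve doubling depth at high GC doubles high-GC windows on average
  curve <- function(gc) ifelse(gc >= 0.43, 2, 1)
  dep3 <- simulate_depth(coh, gc_bias_curve = curve)
  hi <- dep$windows$gc >= 0.43
  expect_gte(sum(hi), 30)
  ratio <- mean(dep3$depth[hi, 1]) / mean(dep$depth[hi, 1])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("transcript simulation copies spliced alleles with truth", {
  fx <- fixture_cohort()
  coh <- fx$coh
  # zero requests
  none <- simulate_transcripts(coh, requests = data.frame(
    gene_id = character(), haplotype = character(), event_id = character()))
  expect_equal(length(none$reads), 0)

  tx <- simulate_transcripts(coh)
  expect_gt(length(tx$reads), 0)
  # reference-allele reads equal the spliced reference transcript
  refr <- tx$truth$read_id[is.na(tx$truth$event_id)]
  for (r in refr) {
    g <- tx$truth$gene_id[tx$truth$read_id == r]
    expect_identical(as.character(tx$reads[[r]]), gene_mrna(fx$ref, g))
  }
  # paralog reads differ from the reference transcript iff divergence > 0
  ev <- coh$truth$events
  par <- tx$truth[!is.na(tx$truth$event_id), ]
  for (i in seq_len(nrow(par))) {
    d <- ev$divergence[ev$event_id == par$event_id[i]]
    same <- identical(as.character(tx$reads[[par$read_id[i]]]),
                      gene_mrna(fx$ref, par$gene_id[i]))
    expect_identical(same, d == 0)
  }
  # requesting a paralog from a non-carrier haplotype errors
  gene_evs <- ev[ev$mode == "insertion" & !is.na(ev$overlaps_gene), ]
  gene_ev <- gene_evs[vapply(gene_evs$carriers, length, 1L) <
                        fx$cfg$n_haplotypes, ][1, ]
  non_carrier <- setdiff(seq_len(fx$cfg$n_haplotypes), gene_ev$carriers[[1]])[1]
  bad <- data.frame(gene_id = gene_ev$overlaps_gene,
                    haplotype = coh$manifest$haplotype[non_carrier],
                    event_id = gene_ev$event_id)
  expect_error(simulate_transcripts(coh, bad), "absent")
})
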