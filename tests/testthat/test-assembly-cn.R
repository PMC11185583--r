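# Assembly-based copy number: mapping, filters, dispersion ranking, paralog
# presence, population tests and concordance.

test_that("gene copies are counted with coverage/identity/repeat filters", {
  withr::with_seed(21, {
    gene <- rand_dna(3000)
    bg <- function(n) rand_dna(n)
    hap1 <- c(ctg1 = paste0(bg(40000), gene, bg(40000),
                            mutate_dna(gene, 0.03), bg(40000)))
    hap2 <- c(ctg1 = paste0(bg(40000), gene, bg(80000 + 3000)))
    params <- cn_map_params()
    r1 <- map_gene_copies(gene, hap1, params)
    r2 <- map_gene_copies(gene, hap2, params)
    expect_equal(r1$count, 2L)   # original + 3%-divergent planted copy
    expect_equal(r2$count, 1L)
    # diploid CN 3 for the sample
    expect_equal(r1$count + r2$count, 3L)

    # an alignment completely inside the repeat mask is removed
    mask <- data.frame(chrom = "ctg1", start = 39000L, end = 44000L)
    rm1 <- map_gene_copies(gene, hap2, params, repeat_mask = mask)
    expect_equal(rm1$count, 0L)

    # a copy within 30 kbp of the contig end is unreliable
    hap3 <- c(ctg1 = paste0(bg(5000), gene, bg(100000)))
    r3 <- map_gene_copies(gene, hap3, params)
    expect_equal(sum(r3$hits$qualifies), 1L)
    expect_equal(r3$count, 0L)

    # a diverged pseudo-copy below 90% identity does not count
    hap4 <- c(ctg1 = paste0(bg(40000), gene, bg(40000),
                            mutate_dna(gene, 0.2), bg(40000)))
    r4 <- map_gene_copies(gene, hap4, params)
    expect_equal(r4$count, 1L)
  })
})

test_that("cohort CN matrix applies gene filters and matches planted truth", {
  fx <- fixture_cohort()
  ref <- fx$ref
  gseq <- vapply(seq_len(nrow(ref$genes)), function(i) as.character(
    Biostrings::subseq(ref$sequences[[ref$genes$chrom[i]]],
                       ref$genes$start[i] + 1L, ref$genes$end[i])), "")
  genes <- ref$genes
  genes$sequence <- gseq
  # add one too-short and one single-exon gene to exercise the filters
  genes <- rbind(genes,
                 data.frame(gene_id = c("tiny", "mono"), chrom = "chr1",
                            start = 0L, end = 150L, strand = "+",
                            cds_bp = c(150L, 900L), n_exons = c(3L, 1L),
                            sequence = c(substr(gseq[1], 1, 150),
                                         substr(gseq[1], 1, 900))))
  cnm <- assembly_cn_matrix(genes, fx$coh$haplotypes, fx$coh$manifest)
  expect_setequal(cnm$filtered$gene, c("tiny", "mono"))
  expect_setequal(cnm$filtered$reason, c("cds_too_short", "single_exon"))
  truth <- fx$coh$truth$gene_truth_cn
  expect_gte(mean(cnm$cn == truth[rownames(cnm$cn), colnames(cnm$cn)]), 0.98)
})

test_that("dispersion index and ranking behave as defined", {
  m <- rbind(a = c(2, 4, 6), b = c(4, 4, 4), c = c(1, 1, 1))
  di <- dispersion_index(m)
  expect_equal(unname(di["a"]), var(c(2, 4, 6)) / 4)   # = 1.0
  expect_equal(unname(di["a"]), 1.0)
  expect_equal(unname(di["b"]), 0.0)

  mat <- rbind(highvar = c(2, 10, 2, 10, 6), flat4 = rep(4, 5),
               flat6 = rep(6, 5), low = rep(1, 5))
  rk <- dispersion_rank(mat, family_variability_params(top_k = 2))
  expect_equal(rk$ranking$family[1], "highvar")
  expect_true("flat4" %in% rk$bottom || "flat6" %in% rk$bottom)
  expect_false("low" %in% rk$ranking$family)  # below mean-CN threshold
  expect_error(dispersion_rank(rbind(low = rep(1, 5))), "no family")
})

test_that("paralog presence matrix distinguishes missing from absent", {
  counts <- data.frame(
    paralog = rep(c("p1", "p2", "p3"), each = 4),
    haplotype = rep(paste0("h", 1:4), 3),
    count = c(1, 1, 1, 1,   1, 2, 1, 3,   0, 1, 0, 1),
    missing = c(rep(FALSE, 7), TRUE, rep(FALSE, 4)))
  pm <- paralog_presence_matrix(counts)
  expect_equal(unname(pm$labels[c("p1", "p2", "p3")]),
               c("fixed_single_copy", "variable_never_deleted", "deletable"))
  expect_true(is.na(pm$matrix["p2", "h4"]))
})

test_that("population tests recover planted shifts and printed binomials", {
  expect_equal(round(binomial_direction_test(13, 16), 2), 0.01)
  expect_equal(binomial_direction_test(13, 16), 697 / 65536)

  # identical CN distributions: nothing significant after BH
  withr::with_seed(31, {
    m0 <- matrix(rpois(50 * 60, 4), nrow = 50,
                 dimnames = list(paste0("f", 1:50), NULL))
    pops <- rep(c("AFR", "nonAFR"), each = 30)
    r0 <- population_cn_tests(m0, pops)
    # BH controls the FDR, so the global null yields at most the occasional
    # single rejection
    expect_lte(sum(r0$table$significant), 1)

    # +2-copy shift planted in AFR for 5 of 50 families, n = 30 per group
    m1 <- m0
    m1[1:5, pops == "AFR"] <- m1[1:5, pops == "AFR"] + 2L
    r1 <- population_cn_tests(m1, pops)
    sig <- r1$table$family[r1$table$significant]
    expect_gte(sum(sig %in% paste0("f", 1:5)), 4)
    expect_lte(sum(!(sig %in% paste0("f", 1:5))), 1)
    planted_sig <- intersect(sig, paste0("f", 1:5))
    expect_true(all(r1$table$direction[r1$table$family %in% planted_sig] == 1))
  })
  expect_error(population_cn_tests(matrix(2, 2, 3), rep("AFR", 3)),
               "two samples")
})

test_that("assembly/depth concordance equals the analytic R-squared", {
  a <- matrix(rep(2:11, 4), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  # identical matrices: lm warns about the perfect fit, R-squared is still 1
  expect_equal(suppressWarnings(assembly_vs_depth_concordance(a, a)), 1.0)
  withr::with_seed(41, {
    noise <- matrix(rnorm(length(a), sd = 0.3), nrow = nrow(a))
    d <- a + noise
    r2 <- assembly_vs_depth_concordance(a, d)
    analytic <- var(as.vector(a)) / (var(as.vector(a)) + 0.3^2)
    expect_lt(abs(r2 - analytic), 0.05)
  })
  const <- matrix(4, nrow = 10, ncol = 4, dimnames = dimnames(a))
  expect_error(assembly_vs_depth_concordance(const, a), "constant")
  expect_error(assembly_vs_depth_concordance(a[1, 1, drop = FALSE],
                                             a[1, 1, drop = FALSE]), "cells")
})

test_that("family aggregation is exactly additive", {
  fx <- fixture_cohort()
  cn <- fx$coh$truth$gene_truth_cn
  fam <- data.frame(gene_id = rownames(cn),
                    family = rep(c("A", "B"), length.out = nrow(cn)))
  fcn <- family_cn_matrix(cn, fam)
  for (f in c("A", "B")) {
    members <- fam$gene_id[fam$family == f]
    expect_equal(fcn[f, ], colSums(cn[members, , drop = FALSE]))
  }
})
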