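# Reference projection, region building / frequency classes, chromosome
# type, accumulation curve and the proximity permutation test.

test_that("projection maps through blocks, anchors insertions, reports unplaced", {
  aln <- data.frame(hap_chrom = "chr1", hap_start = 0L, hap_end = 50000L,
                    ref_chrom = "chr1", ref_start = 0L, ref_end = 50000L,
                    type = "block", event_id = NA)
  fp <- data.frame(chrom = "chr1", start = 5000L, end = 7000L)
  pr <- project_to_reference(fp, aln)
  expect_equal(pr$projected[, c("start", "end")],
               data.frame(start = 5000L, end = 7000L))

  # tandem duplicate inserted at reference position 10000 (copy 2 kbp): the
  # haplotype footprint covers source + copy; projection = source interval
  # plus a zero-width anchor at 10000
  aln2 <- data.frame(
    hap_chrom = "chr1", hap_start = c(0L, 10000L, 12000L),
    hap_end = c(10000L, 12000L, 52000L),
    ref_chrom = "chr1", ref_start = c(0L, 10000L, 10000L),
    ref_end = c(10000L, 10000L, 50000L),
    type = c("block", "insertion", "block"), event_id = c(NA, "e1", NA))
  fp2 <- data.frame(chrom = "chr1", start = 8000L, end = 12000L)
  pr2 <- project_to_reference(fp2, aln2)
  expect_equal(nrow(pr2$projected), 2)
  src <- pr2$projected[!pr2$projected$novel_sequence, ]
  anc <- pr2$projected[pr2$projected$novel_sequence, ]
  expect_equal(c(src$start, src$end), c(8000L, 10000L))
  expect_equal(c(anc$start, anc$end), c(10000L, 10000L))

  # unaligned contig -> unplaced
  fp3 <- data.frame(chrom = "contigX", start = 0L, end = 1500L)
  pr3 <- project_to_reference(fp3, aln)
  expect_equal(nrow(pr3$projected), 0)
  expect_equal(nrow(pr3$unplaced), 1)
})

test_that("regions carry exact carrier counts and frequency classes", {
  # fixed: planted in all 20 haplotypes
  all20 <- lapply(1:20, function(h) data.frame(chrom = "chr1", start = 100L,
                                               end = 2100L))
  r <- build_regions(all20, 20)
  expect_equal(r$freq_class, "fixed")
  expect_equal(r$carrier_count, 20)
  expect_false(r$polymorphic_90)

  # private: 1 of 20, AF 0.05
  one <- c(list(data.frame(chrom = "chr1", start = 100L, end = 2100L)),
           lapply(2:20, function(h) data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer())))
  r1 <- build_regions(one, 20)
  expect_equal(r1$freq_class, "private")
  expect_equal(r1$allele_frequency, 0.05)

  # 5 of 170 haplotypes: rare bin, AF below 3%
  five <- lapply(1:170, function(h) if (h <= 5)
    data.frame(chrom = "chr1", start = 100L, end = 2100L) else
      data.frame(chrom = character(), start = integer(), end = integer()))
  r5 <- build_regions(five, 170)
  expect_equal(r5$freq_bin, "rare")
  expect_lt(100 * r5$allele_frequency, 3)

  # known vs novel split by the reference footprint
  mix <- lapply(1:10, function(h) if (h <= 4)
    data.frame(chrom = "chr1", start = c(100L, 9000L), end = c(2100L, 11000L))
    else data.frame(chrom = character(), start = integer(), end = integer()))
  ref_fp <- data.frame(chrom = "chr1", start = 0L, end = 3000L)
  rm <- build_regions(mix, 10, ref_fp)
  expect_equal(rm$freq_class[rm$start == 100], "polymorphic_known")
  expect_equal(rm$freq_class[rm$start == 9000], "polymorphic_novel")
  expect_error(build_regions(mix, 0), "n_haplotypes")
})

test_that("adjacent pieces with different carrier sets stay distinct", {
  # haplotypes 1..6 carry [0,1000); only 1..3 carry the extension [1000,2000)
  projs <- lapply(1:6, function(h) {
    if (h <= 3) data.frame(chrom = "chr1", start = 0L, end = 2000L)
    else data.frame(chrom = "chr1", start = 0L, end = 1000L)
  })
  r <- build_regions(projs, 6)
  expect_equal(nrow(r), 2)
  expect_equal(r$carrier_count, c(6, 3))
  # conservation: region lengths sum to the merged footprint
  expect_equal(sum(r$end - r$start), 2000)
  expect_equal(attr(r, "total_bp"), 2000)
})

test_that("pipeline regions match planted carrier counts and classes", {
  fx <- fixture_cohort()
  ev <- fx$coh$truth$events
  reg <- fx$regions
  expect_equal(attr(reg, "total_bp"), sum(reg$end - reg$start))
  for (i in seq_len(nrow(ev))) {
    hit <- reg[reg$chrom == ev$chrom[i] & reg$start < ev$end[i] &
                 reg$end > ev$start[i], ]
    expect_gte(nrow(hit), 1)
    nc <- length(ev$carriers[[i]])
    expect_true(nc %in% hit$carrier_count)
    expected_class <- if (nc == fx$cfg$n_haplotypes) "fixed" else
      if (nc == 1) "private" else
        if (ev$mode[i] == "ref_copy_loss") "polymorphic_known" else
          "polymorphic_novel"
    expect_true(expected_class %in% hit$freq_class,
                label = paste(ev$event_id[i], expected_class, "in",
                              paste(hit$freq_class, collapse = ",")))
  }
})

test_that("chromosome type reflects partner locations", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                        start = c(0L, 5000L, 10000L),
                        end = c(1000L, 6000L, 11000L))
  pairs <- data.frame(
    seq_a = c("chr1", "chr1", "chr1", "chr1"),
    start_a = c(0L, 5000L, 10000L, 10000L),
    end_a = c(1000L, 6000L, 11000L, 11000L),
    seq_b = c("chr1", "chr2", "chr1", "chr3"),
    start_b = c(90000L, 0L, 90000L, 0L),
    end_b = c(91000L, 1000L, 91000L, 1000L))
  expect_equal(classify_chrom_type(regions, pairs),
               c("intra", "inter", "both"))
  orphan <- data.frame(chrom = "chr9", start = 0L, end = 100L)
  expect_error(classify_chrom_type(orphan, pairs), "no supporting")
})

test_that("accumulation curve counts novel bp per added genome", {
  fp <- function(start, end) data.frame(chrom = "chr1", start = start, end = end)
  # all genomes identical to the known footprint: increments all zero
  known <- fp(0L, 50000L)
  same <- list(g1 = known, g2 = known, g3 = known)
  ac0 <- accumulation_curve(same, known)
  expect_equal(ac0$novel_bp, c(0, 0, 0))

  # three disjoint 100 kbp footprints: increments all 1e5, rate 1e5
  disj <- list(g1 = fp(0L, 100000L), g2 = fp(200000L, 300000L),
               g3 = fp(400000L, 500000L))
  ac <- accumulation_curve(disj)
  expect_equal(ac$novel_bp, rep(1e5, 3))
  expect_equal(attr(ac, "rate_bp_per_genome"), 1e5)

  # the same genome twice: second increment zero
  rep2 <- list(g1 = fp(0L, 100000L), g1b = fp(0L, 100000L))
  expect_equal(accumulation_curve(rep2)$novel_bp, c(1e5, 0))
  expect_error(accumulation_curve(disj[1]), "two genomes")
})

test_that("interval distances match the GRanges oracle", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      ks <- sort(sample(1e6, 6))
      known <- data.frame(chrom = sample(c("c1", "c2"), 6, replace = TRUE),
                          start = ks, end = ks + sample(500:5000, 6))
      qs <- sort(sample(1e6, 20))
      q <- data.frame(chrom = sample(c("c1", "c2"), 20, replace = TRUE),
                      start = qs, end = qs + sample(100:2000, 20))
      mine <- sdpoly:::.nearest_distances(q$chrom, q$start, q$end,
                                          sdpoly:::.known_by_chrom(known))
      hits <- suppressWarnings(GenomicRanges::distanceToNearest(
        sdpoly:::bed_to_gr(q), GenomicRanges::reduce(sdpoly:::bed_to_gr(known))))
      expect_equal(sort(mine),
                   sort(S4Vectors::mcols(hits)$distance))
    }
  })
})

test_that("proximity permutation test hits its extremes and errors", {
  arms <- data.frame(chrom = "chr1", start = c(0L, 5000000L),
                     end = c(5000000L, 10000000L), arm = c("p", "q"))
  known <- data.frame(chrom = "chr1", start = 250000L, end = 260000L)
  # novel regions book-ended to the known SD: observed distance 0, no
  # permutation can beat it on a mostly SD-free arm
  novel <- data.frame(chrom = "chr1", start = c(249000L, 260000L),
                      end = c(250000L, 261000L))
  res <- proximity_permutation_test(novel, known, arms, n_perm = 99, seed = 5)
  expect_equal(res$p_value, 0.01)
  expect_equal(res$observed, 0)

  # single novel region at the arm's only known SD
  single <- data.frame(chrom = "chr1", start = 260000L, end = 261000L)
  res1 <- proximity_permutation_test(single, known, arms, n_perm = 99, seed = 6)
  expect_equal(res1$p_value, 0.01)

  expect_error(proximity_permutation_test(novel[0, ], known, arms), "novel")
  expect_error(proximity_permutation_test(novel, known[0, ], arms), "known")
  expect_error(proximity_permutation_test(novel, known, arms, n_perm = 10),
               "n_perm")
})
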