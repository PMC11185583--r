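# Gap-compressed identity, ORF finding, screening thresholds and the
# novel-gene summary.

test_that("gap-compressed identity counts each gap run once", {
  expect_equal(gap_compressed_identity(c(strrep("A", 500), strrep("A", 500))),
               1.0)
  # 100 matches, 1 mismatch, one 5-bp gap -> 100/102
  a <- paste0(strrep("A", 50), "C", strrep("A", 50), "-----")
  b <- paste0(strrep("A", 50), "G", strrep("A", 50), "TTTTT")
  expect_equal(gap_compressed_identity(c(a, b)), 100 / 102)
  # two separate 1-bp gaps (two openings) vs one 2-bp gap (one opening)
  two <- c(paste0(strrep("A", 50), "-", strrep("A", 30), "-", strrep("A", 20)),
           paste0(strrep("A", 50), "T", strrep("A", 30), "T", strrep("A", 20)))
  one <- c(paste0(strrep("A", 50), "--", strrep("A", 50)),
           paste0(strrep("A", 50), "TT", strrep("A", 50)))
  expect_equal(gap_compressed_identity(two), 100 / 102)
  expect_equal(gap_compressed_identity(one), 100 / 101)
  expect_error(gap_compressed_identity(c("", "")), "empty|length")
})

test_that("gap-compressed identity dominates per-column identity", {
  withr::with_seed(61, {
    for (i in 1:25) {
      n <- sample(50:200, 1)
      a <- strsplit(rand_dna(n), "")[[1]]
      b <- a
      # random substitutions and gap runs
      sub <- sample(n, sample(0:5, 1))
      for (j in sub) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
      gstart <- sample(n - 10, sample(0:2, 1))
      glen <- 0L
      for (g in gstart) {
        w <- sample(1:4, 1)
        b[g:(g + w - 1)] <- "-"
        glen <- glen + w
      }
      aln <- c(paste(a, collapse = ""), paste(b, collapse = ""))
      gci <- gap_compressed_identity(aln)
      pci <- alignment_identity(aln)
      expect_gte(gci, pci)
      cols <- sdpoly:::alignment_columns(aln)
      if (cols$gap_columns == cols$gap_openings) expect_equal(gci, pci)
      else expect_gt(gci, pci)
    }
  })
})

test_that("longest forward ORF is found", {
  expect_false(find_orf("CCCCCCCCCCCC")$found)       # no ATG
  orf <- find_orf("ATGAAATAG")
  expect_true(orf$found)
  expect_equal(orf$aa_length, 2L)                    # M, K
  expect_false(find_orf("ATGAAAAAA")$found)          # no in-frame stop
  withr::with_seed(62, {
    codons <- sample(setdiff(sdpoly:::.SENSE_CODONS, "ATG"), 299,
                     replace = TRUE)
    seqc <- paste0(rand_dna(7), "ATG", paste(codons, collapse = ""), "TGA",
                   rand_dna(11))
    o <- find_orf(seqc)
    expect_equal(o$aa_length, 300L)
  })
})

test_that("screening applies both identity thresholds", {
  withr::with_seed(63, {
    gene <- rand_dna(1200)
    substitute_n <- function(s, n) {
      ch <- strsplit(s, "")[[1]]
      for (j in sample(nchar(s), n))
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      paste(ch, collapse = "")
    }
    mk_genome <- function(insert) Biostrings::DNAStringSet(
      c(chr1 = paste0(rand_dna(3000), insert, rand_dna(3000))))
    reference <- mk_genome(gene)
    # haplotype carries an exact copy of a paralog diverged 1% from the
    # reference gene (12 substitutions in 1200 bp)
    par1 <- substitute_n(gene, 12)
    hapA <- mk_genome(par1)
    # and another at only ~0.2% divergence (2 substitutions: 1198/1200 above
    # the 99.7% reference ceiling)
    par2 <- substitute_n(gene, 2)
    hapB <- mk_genome(par2)
    reads <- Biostrings::DNAStringSet(c(ref_read = gene, novel = par1,
                                        allelic = par2))
    hits <- screen_reads(reads, list(hapA = hapA, hapB = hapB), reference)
    # reference-identical read: identity 1 to the reference, dropped
    expect_false(hits$retained[hits$read_id == "ref_read"])
    expect_equal(hits$ref_gci[hits$read_id == "ref_read"], 1.0)
    # 1% paralog: perfect on the haplotype, < 99.7% on the reference
    expect_true(hits$retained[hits$read_id == "novel"])
    expect_equal(hits$hap_identity[hits$read_id == "novel"], 1.0)
    expect_lt(hits$ref_gci[hits$read_id == "novel"], 0.997)
    # 0.2% paralog: too close to the reference, dropped
    expect_false(hits$retained[hits$read_id == "allelic"])
    expect_gte(hits$ref_gci[hits$read_id == "allelic"], 0.997)
    # audit: nothing retained at or above the reference ceiling
    expect_true(all(!hits$retained | hits$ref_gci < 0.997 | is.na(hits$ref_gci)))
  })
})

test_that("retention flips at the 0.3% reference-divergence boundary", {
  withr::with_seed(64, {
    gene <- rand_dna(1000)
    reference <- Biostrings::DNAStringSet(
      c(chr1 = paste0(rand_dna(2500), gene, rand_dna(2500))))
    # plant exact substitution counts: 1000 bp read, d subs -> gci = 1 - d/1000
    for (d in c(0, 2, 3, 4, 6, 12, 20)) {
      ch <- strsplit(gene, "")[[1]]
      pos <- sample(1000, d)
      for (j in pos) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      par <- paste(ch, collapse = "")
      hap <- Biostrings::DNAStringSet(
        c(h1 = paste0(rand_dna(2500), par, rand_dna(2500))))
      hits <- screen_reads(Biostrings::DNAStringSet(c(rd = par)),
                           list(hap = hap), reference)
      expect_equal(hits$hap_identity, 1.0)
      expect_equal(hits$ref_gci, 1 - d / 1000, tolerance = 1e-09)
      expect_identical(hits$retained, d / 1000 > 0.003,
                       label = paste("divergence", d / 1000))
    }
  })
})

test_that("novel-gene summary uses the max-over-haplotypes rule", {
  mk_hit <- function(read, hap, chrom, start, orf = 200L)
    data.frame(read_id = read, haplotype = hap, hap_chrom = chrom,
               hap_start = start, hap_end = start + 1000L,
               hap_identity = 1, ref_identity = 0.99, ref_gci = 0.99,
               aligned = TRUE, retained = TRUE, orf_aa = orf,
               stringsAsFactors = FALSE)
  # one paralog carried by 4 haplotypes: family total 1, not 4
  hits <- do.call(rbind, lapply(paste0("h", 1:4), function(h)
    mk_hit(paste0("r_", h), h, "chr1", 5000L)))
  fam <- data.frame(read_id = hits$read_id, family = "famA")
  s <- summarize_novel_genes(hits, fam)
  expect_equal(s$families$total, 1L)
  expect_equal(s$total, 1L)

  # haplotype A has 2 loci of a family, B has 3: total 3
  hits2 <- rbind(
    mk_hit("a1", "A", "chr1", 0L), mk_hit("a2", "A", "chr1", 50000L),
    mk_hit("b1", "B", "chr1", 0L), mk_hit("b2", "B", "chr1", 50000L),
    mk_hit("b3", "B", "chr2", 0L))
  fam2 <- data.frame(read_id = hits2$read_id, family = "famB")
  s2 <- summarize_novel_genes(hits2, fam2)
  expect_equal(s2$families$total, 3L)
  expect_equal(s2$families$haplotype, "B")

  # short-ORF hits are not putative protein-coding; zero hits -> empty
  short <- mk_hit("s", "A", "chr1", 0L, orf = 40L)
  s3 <- summarize_novel_genes(short)
  expect_equal(s3$total, 0L)
  s4 <- summarize_novel_genes(hits[hits$retained == FALSE, ])
  expect_equal(s4$total, 0L)
})
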