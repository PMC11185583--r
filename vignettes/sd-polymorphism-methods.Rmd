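---
title: "Methods: surveying segmental duplication polymorphism in haplotype assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying segmental duplication polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Segmental duplications (SDs) are blocks of homologous DNA longer than 1 kbp
that occur at two or more genomic locations with at least 90% sequence
identity. They mediate non-allelic homologous recombination, harbor most
copy-number polymorphic genes, and have historically been invisible to
short-read analyses because reads from paralogous copies cross-map. Phased
long-read haplotype assemblies finally make SDs directly observable per
haplotype, which allows a population-level survey: which duplications are
fixed in a cohort, which are polymorphic or private, how are polymorphic
duplications structured (orientation, distance to the progenitor), how does
duplicated-gene copy number vary between populations, and which transcripts
betray expressed paralogs missing from the reference?

`sdpoly` implements that survey as a desk-scale, fully testable pipeline.
Every stage can be exercised against a synthetic cohort with planted,
machine-readable ground truth, so the statistical and algorithmic behavior
of each component is verifiable end to end.

## Pipeline overview

1. **`synthetic_cohort`** — `cohort_config()`, `generate_reference()`,
   `sample_planted_events()`, `plant_duplications()`, `simulate_depth()`,
   `simulate_transcripts()`: a reference genome with annotated genes,
   tandem-repeat tracts and its own SDs; haplotype assemblies with planted
   duplication events; GC-biased Poisson read depth; spliced transcript
   reads.
2. **`sd_detect`** — `find_sd_pairs()`: all locus pairs ≥ 1 kbp at ≥ 90%
   identity within one assembly, with orientation;
   `merge_pair_intervals()` merges them into a nonoverlapping footprint.
3. **`pangenome_map`** — `project_to_reference()`, `build_regions()`,
   `accumulation_curve()`, `proximity_permutation_test()`: reference-space
   SD regions with carrier counts, frequency classes (fixed /
   polymorphic-known / polymorphic-novel / private) and chromosomal type.
4. **`polymorphism_stats`** — `classify_configuration()`,
   `rare_common_compare()`, `inverted_interspersed_test()`,
   `singleton_profile()`.
5. **`assembly_cn`** — `map_gene_copies()`, `assembly_cn_matrix()`,
   `dispersion_rank()`, `paralog_presence_matrix()`,
   `population_cn_tests()`, `assembly_vs_depth_concordance()`.
6. **`readdepth_cn`** — `window_depth()`, `recalibrate_gc()`,
   `window_cn()`, `gene_cn()`, `calibrate_adjustments()`.
7. **`transcript_screen`** — `screen_reads()`, `gap_compressed_identity()`,
   `find_orf()`, `summarize_novel_genes()`.

All tables use 0-based half-open coordinates (BED convention); on-disk
formats are FASTA, BED, GFF3 and TSV.

## The SD detector

The detector reproduces the operational SD contract (pairs ≥ 1 kbp, ≥ 90%
per-column identity) at desk scale with a classic three-stage design:

* **Masked k-mer seeding.** All sequences of one assembly are indexed with
  2-bit-encoded k-mers (default k = 15, minimum 11). Positions overlapping
  the tandem-repeat mask are excluded from the index, and k-mers occurring
  more than `max_kmer_occ` times (default 50) are ignored — a guard against
  unmasked low-complexity sequence. Forward-strand and reverse-complement
  matches are collected separately.
* **Collinear chaining.** Seed matches are grouped by sequence pair, strand
  and diagonal bin (`diag_band_bp`, default 100 bp) and split where
  consecutive seeds are more than `max_chain_gap_bp` (default 2 kbp) apart.
  Chains shorter than 60% of the minimum SD length, with fewer than 5 seeds,
  or with seed density below 0.02/bp are discarded; at the detector's
  identity floor (90%) true pairs have clean-k-mer densities an order of
  magnitude above this.
* **Banded extension.** Each candidate is verified by a banded
  Smith–Waterman (match +1, mismatch −3, gap −5; band = diagonal tolerance
  + 100 bp) around the chain diagonal, implemented in C++. Identity is
  matches / (matches + mismatches + gap columns) — each gap column counts
  individually. The gap-compressed variant (each gap run counts once) is
  used only in the transcript screen, mirroring where the two conventions
  apply.

Overlapping candidates are deduplicated keeping the higher-identity, then
longer, then leftmost pair; pairs wholly inside the tandem-repeat mask are
dropped. Tests verify the detector against an independent, unbanded
dynamic-programming oracle (Biostrings' full Smith–Waterman): coordinates
within ±50 bp and identity within ±0.01 on random sequences with planted
direct and inverted copies at up to 6% divergence.

The identity denominator convention (counting each gap column) is a declared
choice: published SD callers do not document theirs, and on the
substitution-dominated alignments this package verifies, the two conventions
differ by well under the test tolerances.

## Building the pangenome SD map

Per-haplotype footprints are projected onto the reference through an
alignment block table. The synthetic haplotypes are reference-collinear
outside planted insertions, so the generator emits the block table directly;
footprint segments inside haplotype-only insertions project to a zero-width
anchor at the insertion point, flagged as novel sequence.

`build_regions()` deliberately does **not** reduce the pooled footprints to
one merged interval per overlap cluster. A polymorphic extension abutting a
fixed region would then be absorbed, and its carrier count lost. Instead the
pooled union is disjoined at every breakpoint, each piece receives its
carrier set (haplotypes overlapping by ≥ 1 bp), and adjacent pieces with
identical carrier sets are re-merged. Region lengths therefore always sum to
the merged footprint (a conservation property the tests assert), and every
planted event's carrier count is recovered exactly on synthetic cohorts.
On real data, alignment jitter between haplotypes would fragment regions
whose carrier sets differ by near-boundary noise; a carrier-set similarity
merge would then be a natural extension. The 1-bp carrier overlap rule is
the least-surprising default and is configurable territory, not a finding.

Two polymorphism definitions coexist in the field: "not present in all
assemblies" and "allele frequency below 90%". The four-way `freq_class`
uses the first (fixed ⇔ carried by every haplotype); the second is exposed
as a separate `polymorphic_90` flag rather than silently conflated. Carrier
counting is per haplotype; rare (≤ 5 carriers) and common (6–20) bins follow
the published cutoffs.

The accumulation curve adds genomes in manifest order and counts footprint
bp unseen in the reference or prior genomes; the novel-SD proximity test
places each novel region uniformly within its chromosome arm (lengths
preserved) and compares the median distance to the nearest known SD, with
the +1-corrected empirical p-value. Permutation validity — P(p ≤ α) ≤ α +
1/(n_perm+1) under the null — is checked by Monte-Carlo calibration over 200
replicate null cohorts.

## Copy-number genotyping

**Assembly route.** Reference gene sequences are mapped to each haplotype
with the same seed–chain–extend machinery; an alignment counts when it
covers ≥ 60% of the gene at ≥ 90% identity. Genes with coding sequence
< 200 bp or a single exon are excluded before mapping. Alignments wholly
inside the repeat mask are removed; copies within 30 kbp of a contig end
are flagged unreliable rather than counted, and a paralog presence matrix
marks such haplotypes missing rather than zero. Non-redundant alignments
are selected greedily by score with mutual overlap < 50% of the shorter
alignment. Diploid copy number is the sum over a sample's two haplotypes.
Genes whose duplication appears in exactly one haplotype cohort-wide can be
flagged (`exclude_single_haplotype_duplicates`), the assembly-artifact guard
applied at the gene level after counting.

**Read-depth route.** Depth is summarized in fixed windows (default 1 kbp);
windows overlapping the tandem-repeat mask by more than 10% are masked.
The GC correction is anchored on a k-mer self-decomposition of the
reference (default 36-mers, the published read length): every window's
expected multiplicity for a perfectly matched sample is computed from
genome-wide k-mer counts, and the GC curve is then estimated from observed
depth of unmasked multiplicity-1 windows in 0.01-wide GC bins (factor =
global mean / bin mean; bins with under 50 windows are linearly interpolated
and flagged). Corrected depth is scaled so the modal unmasked
unique-sequence window sits at copy number 2 (a density-mode anchor — the
scale invariant tests require 2.0 ± 0.1 on every simulated sample). Gene
copy number is the median over unmasked windows fully contained in the gene.
Per-gene adjustment factors against assembly copy number follow the
published exclusion rule: genes needing more than a 50% adjustment
(|factor − 1| > 0.5; a symmetric |log2 factor| criterion is available behind
a flag) are dropped, and depth-zero/assembly-positive genes are excluded as
unalignable.

**Population tests.** Families with dispersion index ≥ 0.1 (sample
variance / mean, n − 1 denominator — the denominator is a declared choice)
and mean copy number > 2 in either population are compared between AFR and
non-AFR samples with a two-sided Mann–Whitney U test (exact where R's
implementation permits, normal approximation with tie correction
otherwise), Benjamini–Hochberg corrected. Among significant families the
direction summary is a one-sided exact binomial test of the count shifted
higher in AFR against 0.5. Variability rankings require mean diploid copy
number above 3, matching the published display threshold. Fisher's exact
test, BH and the Mann–Whitney statistic are delegated to base R and each is
cross-checked in the test suite against a brute-force oracle written from
its definition (hypergeometric enumeration; step-up rule; complete
enumeration of group assignments). The odds ratio is reported as the
cross-product ad/bc — not the conditional MLE that `fisher.test()` prints —
with degenerate zero cells flagged as unbounded rather than silently
clamped.

## The transcript screen

Reads are assigned candidate loci by k-mer seeding, then aligned with a
full dynamic-programming pass (pattern-global); the haplotype side is
scored with per-column identity and the reference side with gap-compressed
identity, exactly the asymmetry of the published thresholds: retained ⇔
haplotype identity ≥ 99.9% **and** reference gap-compressed identity
< 99.7%. Because spliced reads are aligned against genomic loci, alignment
deletions of at least `intron_min_bp` (default 30) are classified as introns
and excluded from both identity denominators — the same convention spliced
aligners use when scoring transcript alignments. The published gene-model
machinery (reference annotation transfer, transcript classification) is out
of scope; loci are instead clustered with a simple 10-kbp merge rule, and
"putative protein-coding" means a longest forward ATG-to-stop open reading
frame of at least 100 amino acids — a deterministic stand-in for an external
gene predictor, with the hook accepting external ORF calls implicitly via
the `orf_aa` column. Family totals count only the haplotype with the most
novel paralogs of that family, so a paralog carried by many haplotypes is
counted once.

Threshold sharpness is tested by planting exact substitution counts: on a
1,000-bp read, retention flips between 3 and 4 substitutions (0.3%
reference divergence), and an audit asserts no retained read ever sits at or
above the 99.7% reference ceiling.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults define the study conditions: iid background
composition at GC 0.41; 1–2-Mbp chromosomes; diploid samples labelled
AFR/non-AFR; multi-exon genes whose coding sequence is drawn at the genome's
base composition (so exons are not GC outliers); low-complexity tandem
tracts forming the repeat mask; reference-internal SD pairs at 2%
divergence; planted events of 1.5–6 kbp at 0–5% divergence across fixed /
high-frequency / common (6–20 carriers) / rare (2–5) / private classes,
direct and inverted, tandem, dispersed and interchromosomal; Poisson read
depth at 30× for copy number 2 with a monotone GC bias (factor
1 + 4·(GC − 0.41), bounded below) — a strong, recoverable trend over the
narrow GC range an iid background occupies.

Two generator constructions are worth spelling out. "Known polymorphic"
regions are produced by planting an SD pair in the reference itself and
replacing the copy with same-length neutral sequence in non-carrier
haplotypes; this keeps every haplotype reference-collinear while making the
region an SD in carriers only. And each insertion event's mutated copy is
realized once and shared by all carriers — a single mutational origin —
which is also what makes carrier counts exactly recoverable even for
divergent events.

What passing tests therefore show: the detector meets its contract against
a DP oracle; frequency classification, accumulation and the permutation,
Fisher, BH and Mann–Whitney machinery are correct and calibrated; GC bias
of the planted form is recovered within 5% per occupied bin and gene copy
number within ±0.5 copies for ≥ 95% of cells; the transcript thresholds cut
exactly where they should. What they do not show: performance on real
genomes with segmentally nested duplications, SNP/indel background
variation, assembly errors and collapses, alignment jitter, or sequencing
error models beyond substitutions — none of which the generator emulates.
The published genome-wide magnitudes (173.2 Mbp of SD, 47.4 Mbp novel,
408.3 kbp per added genome, odds ratio 1.99, R² = 0.94) derive from 170
real assemblies and are not reproducible at this scale; the pipeline
recomputes their synthetic-cohort analogues instead.

## Numerical choices and degenerate inputs

* One global seed; each stage (reference, events, planting, depth,
  transcripts, permutations) draws from its own derived stream
  (`derive_seed()`), so stages can be rerun independently and all outputs
  are bit-reproducible.
* Empirical p-values always use the +1 correction; one-sided direction is
  stated per test.
* Ties in candidate deduplication: identity, then length, then leftmost.
* Zero-margin 2×2 tables error; zero cells with positive margins yield an
  unbounded odds-ratio flag with an exact p-value.
* Empty footprints, empty event lists, zero singletons and zero retained
  transcript hits are empty results, not errors; an empty rare or common
  class, no eligible family, no novel regions, and n_haplotypes = 0 are
  errors naming the offending input.
* Windows larger than a chromosome truncate with a warning; genes with no
  eligible depth window are missing with a recorded reason.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: unit fixtures use 2 × 0.5 Mbp chromosomes and 5 samples; the
end-to-end recovery check uses a 5 × 1 Mbp reference, 20 samples (40
haplotypes) and 60 planted events; permutation calibration uses 200
replicate null cohorts at 99 permutations each; the acceptance script runs
3 × 2 Mbp chromosomes and 10 samples. These sizes are choices of the
package's validation design, balancing statistical resolution (binomial
confidence on recovery and calibration rates) against runtime.

## Known limitations

* The detector is not tuned for whole-genome scale or for deeply nested SD
  architectures; chains straddling a diagonal-bin boundary in the presence
  of large indels may be split (the banded extension re-merges most such
  cases, and the deduplicator keeps the best).
* Projection assumes reference-collinear haplotypes with insertions — the
  synthetic cohort's alignment model; complex rearrangement liftover is out
  of scope.
* The read-depth route does not realign reads: depth is either simulated or
  supplied per window, and fastCN binary compatibility is a non-goal.
* Acrocentric short arms, RepeatMasker classification, graph pangenomes,
  GO enrichment and HLA typing are out of scope end to end.
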