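# Synthetic cohort generator: a multi-chromosome reference with annotated
# genes, tandem-repeat tracts and its own segmental duplications, plus a set
# of haplotype assemblies with planted duplication events at chosen carrier
# frequencies, and a machine-readable truth table.

#' Configuration for a synthetic SD cohort
#'
#' @param n_chromosomes number of reference chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_samples number of diploid samples (haplotypes = 2 * n_samples).
#' @param populations per-sample population label in `{"AFR","nonAFR"}`;
#'   default assigns the first half `AFR`.
#' @param gc_target genome GC fraction in `[0, 1]`.
#' @param mutation_rate default substitution rate applied to duplicate copies.
#' @param base_depth haploid-pair (copy number 2) sequencing depth used by
#'   [simulate_depth()].
#' @param window_size read-depth window size in bp.
#' @param genes_per_chrom annotated multi-exon genes per chromosome.
#' @param gene_length_bp approximate annotated gene span.
#' @param ref_sds_per_chrom segmental duplication pairs planted in the
#'   reference itself (these define the reference's own SD footprint).
#' @param ref_sd_length_bp length of each reference SD copy.
#' @param ref_sd_divergence substitution divergence between reference SD
#'   copies.
#' @param tandem_repeats_per_chrom low-complexity tandem tracts per
#'   chromosome (these make up the tandem-repeat mask).
#' @param margin_bp feature-free margin kept at chromosome ends.
#' @param seed integer random seed; all stages derive their own stream from
#'   it.
#' @return a validated list of class `sd_config`.
#' @export
cohort_config <- function(n_chromosomes = 3L, chrom_length_bp = 1e6,
                          n_samples = 10L, populations = NULL,
                          gc_target = 0.41, mutation_rate = 0.02,
                          base_depth = 30, window_size = 1000L,
                          genes_per_chrom = 4L, gene_length_bp = 8000L,
                          ref_sds_per_chrom = 2L, ref_sd_length_bp = 3000L,
                          ref_sd_divergence = 0.02,
                          tandem_repeats_per_chrom = 3L,
                          margin_bp = 40000L, seed = 1L) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  if (chrom_length_bp <= 0 || window_size <= 0 || gene_length_bp <= 0)
    stop("all lengths must be positive")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (mutation_rate < 0 || mutation_rate >= 0.10)
    stop("mutation_rate must be in [0, 0.10) so planted copies stay detectable")
  if (is.null(populations))
    populations <- rep(c("AFR", "nonAFR"), c(ceiling(n_samples / 2),
                                             floor(n_samples / 2)))
  stopifnot(length(populations) == n_samples,
            all(populations %in% c("AFR", "nonAFR")))
  n_feat <- genes_per_chrom + tandem_repeats_per_chrom + 2L * ref_sds_per_chrom
  slot <- (chrom_length_bp - 2 * margin_bp) / max(n_feat, 1L)
  if (slot < max(gene_length_bp, ref_sd_length_bp) + 4000)
    stop("chrom_length_bp too small to host the requested annotations")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_samples = as.integer(n_samples),
    n_haplotypes = 2L * as.integer(n_samples),
    populations = populations,
    gc_target = gc_target, mutation_rate = mutation_rate,
    base_depth = base_depth, window_size = as.integer(window_size),
    genes_per_chrom = as.integer(genes_per_chrom),
    gene_length_bp = as.integer(gene_length_bp),
    ref_sds_per_chrom = as.integer(ref_sds_per_chrom),
    ref_sd_length_bp = as.integer(ref_sd_length_bp),
    ref_sd_divergence = ref_sd_divergence,
    tandem_repeats_per_chrom = as.integer(tandem_repeats_per_chrom),
    margin_bp = as.integer(margin_bp), seed = as.integer(seed)
  ), class = "sd_config")
}

.BASES <- c("A", "C", "G", "T")
.SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# substitute bases at iid rate; returns the mutated character vector
.mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  chars
}

.revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[chars]))
}

# evenly spaced, jittered feature slots; 0-based half-open intervals
.place_slots <- function(chrom_len, lens, margin) {
  n <- length(lens)
  span <- (chrom_len - 2 * margin) / n
  starts <- integer(n)
  for (i in seq_len(n)) {
    lo <- margin + (i - 1) * span
    hi <- margin + i * span - lens[i] - 2000
    if (hi <= lo) stop("chromosome length too small to host the requested annotations")
    starts[i] <- as.integer(floor(runif(1, lo, hi)))
  }
  starts
}

#' Generate a synthetic reference genome with annotations
#'
#' Builds `n_chromosomes` iid-composition sequences at the target GC, plants
#' low-complexity tandem tracts (returned as the tandem-repeat mask),
#' multi-exon protein-coding genes (each with a contiguous sense-codon CDS
#' spread across its exons), and the reference's own segmental duplication
#' pairs (divergent copies, alternating direct/inverted orientation and
#' intra-/interchromosomal placement).
#'
#' @param config an [cohort_config()] object.
#' @return a list of class `sd_reference`: `sequences` (DNAStringSet),
#'   `genes`, `exons`, `trf`, `ref_sd` (truth for the reference's SD pairs),
#'   `arms` (chromosome arm bounds) and `config`.  All tables use 0-based
#'   half-open coordinates.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sd_config"))
  with_seed(derive_seed(config$seed, "reference"), {
    L <- config$chrom_length_bp
    nchr <- config$n_chromosomes
    chrom_names <- paste0("chr", seq_len(nchr))
    probs <- c((1 - config$gc_target) / 2, config$gc_target / 2,
               config$gc_target / 2, (1 - config$gc_target) / 2)
    chars <- lapply(seq_len(nchr), function(i)
      sample(.BASES, L, replace = TRUE, prob = probs))

    genes <- list(); exons <- list(); trf <- list(); ref_sd <- list()
    # per-chromosome feature lengths: genes, tandem tracts, SD sources,
    # SD copy slots (targets of this chromosome's pairs, resolved below)
    pend_copy <- list()  # copy payloads to write after all sources exist
    for (ci in seq_len(nchr)) {
      lens <- c(rep(config$gene_length_bp, config$genes_per_chrom),
                rep(1500L, config$tandem_repeats_per_chrom),
                rep(config$ref_sd_length_bp, 2L * config$ref_sds_per_chrom))
      starts <- .place_slots(L, lens, config$margin_bp)
      idx <- 1L
      for (g in seq_len(config$genes_per_chrom)) {
        gs <- starts[idx]; idx <- idx + 1L
        # ~4 exons + introns sized so the gene spans most of its configured
        # length (several read-depth windows fall fully inside the gene)
        n_ex <- 4L
        exbp <- round(config$gene_length_bp * 0.13)
        inbp <- round(config$gene_length_bp * 0.08)
        ex_len <- sample(seq(exbp, exbp + 300L), n_ex, replace = TRUE)
        in_len <- sample(seq(inbp, inbp + 300L), n_ex - 1L, replace = TRUE)
        pos <- gs
        ex <- data.frame(start = integer(n_ex), end = integer(n_ex))
        for (e in seq_len(n_ex)) {
          ex$start[e] <- pos; ex$end[e] <- pos + ex_len[e]
          pos <- ex$end[e] + if (e < n_ex) in_len[e] else 0L
        }
        gid <- sprintf("gene_%s_%d", chrom_names[ci], g)
        # plant a CDS across the exons: ATG + sense codons + stop; codons are
        # drawn at the genome's base composition so exons are not GC outliers
        codon_w <- vapply(strsplit(.SENSE_CODONS, ""), function(b)
          prod(probs[match(b, .BASES)]), 1.0)
        cds_len <- sum(ex_len) %/% 3L * 3L
        codons <- c("ATG", sample(.SENSE_CODONS, cds_len / 3 - 2,
                                  replace = TRUE, prob = codon_w),
                    sample(c("TAA", "TAG", "TGA"), 1L))
        cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
        off <- 0L
        for (e in seq_len(n_ex)) {
          w <- min(ex_len[e], length(cds) - off)
          if (w <= 0) break
          chars[[ci]][(ex$start[e] + 1):(ex$start[e] + w)] <- cds[(off + 1):(off + w)]
          off <- off + w
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom_names[ci], start = gs, end = pos,
          strand = "+", cds_bp = length(cds), n_exons = n_ex,
          stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <- data.frame(
          gene_id = gid, exon = seq_len(n_ex), chrom = chrom_names[ci],
          start = ex$start, end = ex$end, stringsAsFactors = FALSE)
      }
      for (t in seq_len(config$tandem_repeats_per_chrom)) {
        ts <- starts[idx]; idx <- idx + 1L
        motif <- sample(.BASES, sample(4:7, 1L), replace = TRUE, prob = probs)
        tract <- rep(motif, length.out = 1500L)
        chars[[ci]][(ts + 1):(ts + 1500L)] <- tract
        trf[[length(trf) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = ts, end = ts + 1500L,
          motif = paste(motif, collapse = ""), stringsAsFactors = FALSE)
      }
      for (p in seq_len(config$ref_sds_per_chrom)) {
        src <- starts[idx]; idx <- idx + 1L
        dst <- starts[idx]; idx <- idx + 1L
        # alternate intra / inter placement; inter pairs write the copy on
        # the next chromosome, in this chromosome's reserved slot position
        inter <- nchr > 1L && p %% 2L == 0L
        dst_chrom <- if (inter) (ci %% nchr) + 1L else ci
        orientation <- if ((ci + p) %% 2L == 0L) "inverted" else "direct"
        pend_copy[[length(pend_copy) + 1L]] <- list(
          src_chrom = ci, src = src, dst_chrom = dst_chrom, dst = dst,
          orientation = orientation)
      }
    }
    sdlen <- config$ref_sd_length_bp
    for (pi in seq_along(pend_copy)) {
      pc <- pend_copy[[pi]]
      seq_src <- chars[[pc$src_chrom]][(pc$src + 1):(pc$src + sdlen)]
      cp <- .mutate_chars(seq_src, config$ref_sd_divergence)
      if (pc$orientation == "inverted") cp <- .revcomp_chars(cp)
      chars[[pc$dst_chrom]][(pc$dst + 1):(pc$dst + sdlen)] <- cp
      ref_sd[[pi]] <- data.frame(
        pair_id = sprintf("refsd_%02d", pi),
        chrom_a = paste0("chr", pc$src_chrom), start_a = pc$src,
        end_a = pc$src + sdlen,
        chrom_b = paste0("chr", pc$dst_chrom), start_b = pc$dst,
        end_b = pc$dst + sdlen,
        orientation = pc$orientation,
        divergence = config$ref_sd_divergence, stringsAsFactors = FALSE)
    }
    sequences <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
    names(sequences) <- chrom_names
    arms <- do.call(rbind, lapply(seq_len(nchr), function(ci) data.frame(
      chrom = chrom_names[ci], start = c(0L, L %/% 2L), end = c(L %/% 2L, L),
      arm = c("p", "q"), stringsAsFactors = FALSE)))
    structure(list(
      sequences = sequences,
      genes = do.call(rbind, genes),
      exons = do.call(rbind, exons),
      trf = do.call(rbind, trf),
      ref_sd = if (length(ref_sd)) do.call(rbind, ref_sd) else
        data.frame(pair_id = character(), chrom_a = character(),
                   start_a = integer(), end_a = integer(),
                   chrom_b = character(), start_b = integer(),
                   end_b = integer(), orientation = character(),
                   divergence = numeric()),
      arms = arms, config = config
    ), class = "sd_reference")
  })
}

#' Reference SD footprint from the planted truth
#'
#' Union of the reference's own SD pair intervals (the "known" footprint).
#' The same footprint is recovered by running [find_sd_pairs()] on the
#' reference and merging, which tests assert.
#'
#' @param reference an `sd_reference`.
#' @return BED-style data.frame.
#' @export
reference_sd_footprint <- function(reference) {
  rs <- reference$ref_sd
  merge_pair_intervals(data.frame(
    seq_a = rs$chrom_a, start_a = rs$start_a, end_a = rs$end_a,
    seq_b = rs$chrom_b, start_b = rs$start_b, end_b = rs$end_b))
}

# free background intervals of a chromosome (outside all annotations and
# existing event footprints), used for event target placement
.free_space <- function(reference, extra = NULL) {
  cfg <- reference$config
  occ <- rbind(
    reference$genes[, c("chrom", "start", "end")],
    reference$trf[, c("chrom", "start", "end")],
    data.frame(chrom = reference$ref_sd$chrom_a, start = reference$ref_sd$start_a,
               end = reference$ref_sd$end_a),
    data.frame(chrom = reference$ref_sd$chrom_b, start = reference$ref_sd$start_b,
               end = reference$ref_sd$end_b))
  if (!is.null(extra) && nrow(extra)) occ <- rbind(occ, extra[, c("chrom", "start", "end")])
  occ_gr <- GenomicRanges::reduce(bed_to_gr(occ) + 2000L)
  full <- bed_to_gr(data.frame(chrom = names(reference$sequences),
                               start = cfg$margin_bp,
                               end = cfg$chrom_length_bp - cfg$margin_bp))
  gr_to_bed(GenomicRanges::setdiff(full, occ_gr))
}

#' Sample planted duplication events across frequency classes
#'
#' Produces a mixture of event kinds:
#' * `insertion` events copy a reference source interval into carrier
#'   haplotypes (tandem = immediately 3' of the source, or at a dispersed
#'   target, possibly on another chromosome), optionally with substitution
#'   divergence; their SD footprint is novel relative to the reference.
#' * `ref_copy_loss` events take one of the reference's own SD pairs and
#'   replace the copy with same-length neutral sequence in non-carrier
#'   haplotypes, so the region is an SD only in carriers but is part of the
#'   reference's known footprint (a "known polymorphic" region).
#'
#' Carrier counts per class: fixed = all haplotypes, high_af = ~95% of
#' haplotypes, common = 6-20, rare = 2-5, private = 1.
#'
#' @param reference an `sd_reference`.
#' @param n_fixed,n_high_af,n_common,n_rare,n_private number of insertion
#'   events per frequency class.
#' @param n_known_poly number of `ref_copy_loss` events (bounded by the
#'   number of reference SD pairs).
#' @param n_gene_events how many of the insertion events must contain a full
#'   annotated gene (creating copy-number variation of that gene).
#' @param p_inverted probability an insertion event is inverted.
#' @param p_tandem probability an insertion event is tandem (otherwise a
#'   dispersed target is drawn, interchromosomal with probability 1/2 when
#'   possible).
#' @param divergences divergence values sampled per event.
#' @param length_range source length range in bp (min 1200).
#' @param afr_carrier_bias optional multiplicative sampling weight for
#'   haplotypes of AFR samples when drawing carriers of gene-overlapping
#'   events (creates population-differentiated copy number).
#' @param seed optional; defaults to the cohort seed's event stream.
#' @return events data.frame with one row per event; `carriers` is a list
#'   column of haplotype indices (1..n_haplotypes).
#' @export
sample_planted_events <- function(reference, n_fixed = 2L, n_high_af = 2L,
                                  n_common = 4L, n_rare = 4L, n_private = 4L,
                                  n_known_poly = 2L, n_gene_events = 2L,
                                  p_inverted = 0.4, p_tandem = 0.4,
                                  divergences = c(0, 0, 0.01, 0.02, 0.05),
                                  length_range = c(1500L, 6000L),
                                  afr_carrier_bias = 1,
                                  seed = NULL) {
  cfg <- reference$config
  nh <- cfg$n_haplotypes
  seed <- seed %||% derive_seed(cfg$seed, "events")
  with_seed(seed, {
    classes <- c(rep("fixed", n_fixed), rep("high_af", n_high_af),
                 rep("common", n_common), rep("rare", n_rare),
                 rep("private", n_private))
    n_ins <- length(classes)
    # gene-overlapping events occupy the first slots; give them polymorphic
    # classes (common, then rare) so planted gene CN actually varies
    if (n_gene_events > 0) {
      pref <- c(which(classes == "common"), which(classes == "rare"),
                which(classes == "high_af"))
      take <- head(pref[pref > n_gene_events], n_gene_events)
      for (j in seq_along(take)) {
        if (j > n_gene_events) break
        tmp <- classes[j]; classes[j] <- classes[take[j]]; classes[take[j]] <- tmp
      }
    }
    if (n_known_poly > nrow(reference$ref_sd))
      stop("n_known_poly exceeds available reference SD pairs")
    if (n_gene_events > nrow(reference$genes))
      stop("n_gene_events exceeds available genes")
    hap_pop <- rep(cfg$populations, each = 2L)
    draw_carriers <- function(class, biased) {
      n <- switch(class,
                  fixed = nh,
                  high_af = max(min(nh - 1L, ceiling(0.95 * nh)), 2L),
                  common = sample(6:min(20L, max(nh - 1L, 6L)), 1L),
                  rare = sample(2:min(5L, nh - 1L), 1L),
                  private = 1L)
      n <- min(n, nh)
      w <- rep(1, nh)
      if (biased && afr_carrier_bias != 1) w[hap_pop == "AFR"] <- afr_carrier_bias
      sort(sample.int(nh, n, prob = w))
    }
    # sources: gene events wrap a gene; the rest come from free space
    gene_rows <- reference$genes[sample.int(nrow(reference$genes), n_gene_events), ,
                                 drop = FALSE]
    sources <- list(); used <- NULL
    for (g in seq_len(n_gene_events)) {
      sources[[g]] <- data.frame(
        chrom = gene_rows$chrom[g], start = gene_rows$start[g] - 300L,
        end = gene_rows$end[g] + 300L, gene = gene_rows$gene_id[g],
        stringsAsFactors = FALSE)
    }
    for (i in seq(n_gene_events + 1L, length.out = n_ins - n_gene_events)) {
      free <- .free_space(reference, extra = used)
      free <- free[(free$end - free$start) > (length_range[2] + 8000L), , drop = FALSE]
      if (!nrow(free)) stop("no free space left to place event sources")
      row <- free[sample.int(nrow(free), 1L), ]
      len <- sample(length_range[1]:length_range[2], 1L)
      s <- as.integer(floor(runif(1, row$start + 2000, row$end - len - 2000)))
      sources[[i]] <- data.frame(chrom = row$chrom, start = s, end = s + len,
                                 gene = NA_character_, stringsAsFactors = FALSE)
      used <- rbind(used, sources[[i]][, c("chrom", "start", "end")])
    }
    src <- do.call(rbind, sources)
    used_all <- rbind(if (!is.null(used)) used else NULL,
                      src[, c("chrom", "start", "end")])
    # targets
    chrom_names <- names(reference$sequences)
    ev <- vector("list", n_ins)
    for (i in seq_len(n_ins)) {
      tandem <- runif(1) < p_tandem
      if (tandem) {
        tchrom <- src$chrom[i]; tpos <- src$end[i]; kind <- "tandem"
      } else {
        inter <- length(chrom_names) > 1L && runif(1) < 0.5
        tchrom <- if (inter) sample(setdiff(chrom_names, src$chrom[i]), 1L) else src$chrom[i]
        free <- .free_space(reference, extra = used_all)
        free <- free[free$chrom == tchrom & (free$end - free$start) > 10000L, , drop = FALSE]
        if (!nrow(free)) stop("no free space left to place event targets")
        row <- free[sample.int(nrow(free), 1L), ]
        tpos <- as.integer(floor(runif(1, row$start + 3000, row$end - 3000)))
        kind <- if (inter) "interchromosomal" else "dispersed"
        used_all <- rbind(used_all, data.frame(chrom = tchrom, start = tpos - 2500L,
                                               end = tpos + 2500L))
      }
      ev[[i]] <- data.frame(
        event_id = sprintf("ev_%03d", i), mode = "insertion",
        class = classes[i], chrom = src$chrom[i], start = src$start[i],
        end = src$end[i], target_chrom = tchrom, target_pos = tpos,
        target_kind = kind,
        orientation = if (runif(1) < p_inverted) "inverted" else "direct",
        divergence = sample(divergences, 1L),
        overlaps_gene = src$gene[i], stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev)
    events$carriers <- lapply(seq_len(n_ins), function(i)
      draw_carriers(events$class[i], biased = !is.na(events$overlaps_gene[i])))
    # known-polymorphic events on reference SD pairs
    if (n_known_poly > 0L) {
      rows <- reference$ref_sd[sample.int(nrow(reference$ref_sd), n_known_poly), ,
                               drop = FALSE]
      kp_class <- rep(c("common", "rare"), length.out = n_known_poly)
      kp <- data.frame(
        event_id = sprintf("ev_%03d", n_ins + seq_len(n_known_poly)),
        mode = "ref_copy_loss", class = kp_class,
        chrom = rows$chrom_a, start = rows$start_a, end = rows$end_a,
        target_chrom = rows$chrom_b, target_pos = rows$start_b,
        target_kind = "reference_pair", orientation = rows$orientation,
        divergence = rows$divergence, overlaps_gene = NA_character_,
        stringsAsFactors = FALSE)
      kp$carriers <- lapply(kp_class, function(cl) draw_carriers(cl, FALSE))
      kp$ref_pair_id <- rows$pair_id
      events$ref_pair_id <- NA_character_
      events <- rbind(events, kp)
    } else {
      events$ref_pair_id <- NA_character_
    }
    rownames(events) <- NULL
    events
  })
}

#' Plant duplication events into haplotype assemblies
#'
#' Builds one assembly per haplotype.  Carriers of an `insertion` event
#' receive one copy of the (singly realized, optionally mutated, optionally
#' reverse-complemented) source sequence at the event's target position;
#' non-carriers of a `ref_copy_loss` event have that reference SD copy
#' replaced by same-length neutral sequence.  Each event's copy sequence is
#' realized once, as for a single mutational origin, and shared by all
#' carriers.
#'
#' @param reference an `sd_reference`.
#' @param events events data.frame from [sample_planted_events()] (or built
#'   by hand with the same columns).
#' @param config optional; defaults to `reference$config`.
#' @return a list of class `sd_cohort`: `haplotypes` (named list of
#'   DNAStringSet), `manifest` (sample, haplotype, hap_index, population),
#'   `alignments` (per-haplotype collinear block table, see
#'   [project_to_reference()]), `truth` (events, per-haplotype planted
#'   copies, `gene_truth_cn` gene x sample matrix), `event_seqs` and the
#'   `reference`.
#' @export
plant_duplications <- function(reference, events, config = NULL) {
  config <- config %||% reference$config
  nh <- config$n_haplotypes
  L <- config$chrom_length_bp
  if (nrow(events) == 0) {
    events <- data.frame(event_id = character(), mode = character(),
                         chrom = character(), start = integer(),
                         end = integer(), target_chrom = character(),
                         target_pos = integer(), orientation = character(),
                         divergence = numeric(),
                         overlaps_gene = character(),
                         ref_pair_id = character(), stringsAsFactors = FALSE)
    events$carriers <- list()
  }
  if (nrow(events)) {
    if (!"mode" %in% names(events)) events$mode <- "insertion"
    if (!"overlaps_gene" %in% names(events)) events$overlaps_gene <- NA_character_
    if (!"orientation" %in% names(events)) events$orientation <- "direct"
    if (!"divergence" %in% names(events)) events$divergence <- 0
    if (!"event_id" %in% names(events))
      events$event_id <- sprintf("ev_%03d", seq_len(nrow(events)))
    if (any(events$end - events$start < 1000))
      stop("planted events must be at least 1 kbp")
    if (any(vapply(events$carriers, length, 1L) == 0))
      stop("every event needs a non-empty carrier set")
    if (any(unlist(events$carriers) > nh))
      stop("carrier haplotype index exceeds n_haplotypes")
    if (any(events$divergence >= 0.10))
      stop("event divergence must stay below 0.10")
    bad <- events$start < 0 | events$end > L
    if (any(bad)) stop("event source outside reference bounds: ",
                       paste(events$event_id[bad], collapse = ", "))
  }

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  manifest <- data.frame(
    sample = rep(samples, each = 2L),
    haplotype = paste0(rep(samples, each = 2L), "_h", rep(1:2, config$n_samples)),
    hap_index = seq_len(nh),
    population = rep(config$populations, each = 2L),
    stringsAsFactors = FALSE)

  # one realization per event
  event_seqs <- list(); loss_fill <- list()
  with_seed(derive_seed(config$seed, "plant"), {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      src <- strsplit(as.character(Biostrings::subseq(
        reference$sequences[[ev$chrom]], ev$start + 1L, ev$end)), "")[[1]]
      if (ev$mode == "insertion") {
        cp <- .mutate_chars(src, ev$divergence)
        if (ev$orientation == "inverted") cp <- .revcomp_chars(cp)
        event_seqs[[ev$event_id]] <- paste(cp, collapse = "")
      } else {
        w <- ev$target_pos  # copy interval start; same length as source
        probs <- c((1 - config$gc_target) / 2, config$gc_target / 2,
                   config$gc_target / 2, (1 - config$gc_target) / 2)
        loss_fill[[ev$event_id]] <- paste(
          sample(.BASES, length(src), replace = TRUE, prob = probs), collapse = "")
      }
    }
  })

  is_ins <- events$mode == "insertion"
  haplotypes <- vector("list", nh)
  alignments <- vector("list", nh)
  copies <- list()
  for (h in seq_len(nh)) {
    carried <- which(is_ins & vapply(events$carriers, function(cc) h %in% cc, TRUE))
    lost <- which(!is_ins & vapply(events$carriers, function(cc) !(h %in% cc), TRUE))
    seqs <- reference$sequences
    blocks <- list()
    for (chrom in names(seqs)) {
      ins_here <- carried[events$target_chrom[carried] == chrom]
      ins_pos <- events$target_pos[ins_here]
      if (anyDuplicated(ins_pos))
        stop("overlapping target positions for two events on haplotype ",
             manifest$haplotype[h])
      o <- order(ins_pos)
      ins_here <- ins_here[o]; ins_pos <- ins_pos[o]
      loss_here <- lost[events$target_chrom[lost] == chrom]
      x <- seqs[[chrom]]
      # same-length replacements first (coordinates unchanged)
      if (length(loss_here)) {
        at <- IRanges::IRanges(start = events$target_pos[loss_here] + 1L,
                               end = events$target_pos[loss_here] +
                                 (events$end[loss_here] - events$start[loss_here]))
        x <- Biostrings::replaceAt(x, at,
                                   as.character(unlist(loss_fill[events$event_id[loss_here]])))
      }
      if (length(ins_here)) {
        at <- IRanges::IRanges(start = ins_pos + 1L, width = 0L)
        vals <- unname(unlist(event_seqs[events$event_id[ins_here]]))
        x <- Biostrings::replaceAt(x, at, vals)
      }
      seqs[[chrom]] <- x
      # collinear blocks and insertion anchors (0-based half-open)
      ins_len <- if (length(ins_here))
        nchar(unname(unlist(event_seqs[events$event_id[ins_here]]))) else integer()
      bp <- c(0L, ins_pos, L)
      offs <- cumsum(c(0L, ins_len))
      blk <- list(); hoff <- 0L
      for (bi in seq_len(length(bp) - 1L)) {
        rs <- bp[bi]; re <- bp[bi + 1L]
        blk[[length(blk) + 1L]] <- data.frame(
          hap_chrom = chrom, hap_start = rs + offs[bi], hap_end = re + offs[bi],
          ref_chrom = chrom, ref_start = rs, ref_end = re, type = "block",
          event_id = NA_character_, stringsAsFactors = FALSE)
        if (bi < length(bp) - 1L) {
          ev_i <- ins_here[bi]
          hs <- re + offs[bi]
          blk[[length(blk) + 1L]] <- data.frame(
            hap_chrom = chrom, hap_start = hs, hap_end = hs + ins_len[bi],
            ref_chrom = chrom, ref_start = re, ref_end = re, type = "insertion",
            event_id = events$event_id[ev_i], stringsAsFactors = FALSE)
          copies[[length(copies) + 1L]] <- data.frame(
            event_id = events$event_id[ev_i], haplotype = manifest$haplotype[h],
            chrom = chrom, start = hs, end = hs + ins_len[bi],
            stringsAsFactors = FALSE)
        }
      }
      alignments[[h]] <- rbind(alignments[[h]], do.call(rbind, blk))
    }
    haplotypes[[h]] <- seqs
  }
  names(haplotypes) <- manifest$haplotype
  names(alignments) <- manifest$haplotype

  # truth copy number per gene x sample: 2 + planted gene-containing copies
  genes <- reference$genes
  cn <- matrix(2L, nrow = nrow(genes), ncol = config$n_samples,
               dimnames = list(genes$gene_id, samples))
  for (i in which(is_ins)) {
    gid <- events$overlaps_gene[i]
    if (is.na(gid)) {
      hit <- genes$chrom == events$chrom[i] & genes$start >= events$start[i] &
        genes$end <= events$end[i]
      if (!any(hit)) next
      gid <- genes$gene_id[which(hit)]
    }
    for (hh in events$carriers[[i]]) {
      s <- manifest$sample[hh]
      cn[gid, s] <- cn[gid, s] + 1L
    }
  }

  structure(list(
    haplotypes = haplotypes, manifest = manifest, alignments = alignments,
    truth = list(events = events,
                 copies = if (length(copies)) do.call(rbind, copies) else
                   data.frame(event_id = character(), haplotype = character(),
                              chrom = character(), start = integer(),
                              end = integer()),
                 gene_truth_cn = cn),
    event_seqs = event_seqs, reference = reference, config = config
  ), class = "sd_cohort")
}
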