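#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the simulated two-population study with its
#' default.  Defaults emulate the statistical structure of a divergent
#' pig-breed resequencing design at desk scale: a 20-Mb genome, 300 genes,
#' 20 + 20 diploid samples, background divergence F = 0.15 with ten planted
#' 200-kb sweeps, regulatory hd-variant enrichment concentrated in one
#' tissue, and ten expression/accessibility tissues.
#'
#' @param seed Mandatory integer seed; every emitted artifact is a pure
#'   function of (config, seed).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_genes Number of protein-coding genes.
#' @param exon_count_range,exon_len_range,intron_len_range,utr_len_range
#'   Gene-structure sampling ranges (bp).
#' @param repeat_fraction Fraction of the genome covered by the repeat
#'   mask (repeats avoid CDS).
#' @param n_per_pop Diploid samples per population.
#' @param pop_labels Two population labels; the first is the ratio
#'   numerator throughout.
#' @param n_sites Variant sites drawn before CDS thinning.
#' @param background_f Balding-Nichols divergence parameter F.
#' @param n_sweeps,sweep_length Planted sweep count and length (bp);
#'   sweeps alternate between the two populations.
#' @param sweep_beta Beta(shape1, shape2) for the swept-population allele
#'   frequency (near fixation).
#' @param hd_beta_high,hd_beta_low Beta parameters for planted highly
#'   differential variants (high in the sweep population, low in the
#'   other).
#' @param hd_fraction Probability that a background site inside a sweep is
#'   planted as highly differential.
#' @param hd_promoter_lambda Poisson mean for extra planted hd variants
#'   per targeted promoter (at least one is always planted).
#' @param n_planted_peaks Differential ATAC peaks planted inside sweeps
#'   with hd variants (in `enrich_tissue`).
#' @param cds_depletion Thinning factor for sites falling in CDS
#'   (purifying-selection analog).
#' @param indel_fraction Fraction of sites emitted as short indels.
#' @param indel_max Maximum indel length (bp).
#' @param missing_rate Per-genotype missingness.
#' @param tissues Tissue labels for expression/peak tables.
#' @param enrich_tissue Tissue carrying the planted regulatory signal.
#' @param deg_fraction Background probability that a gene is a DEG.
#' @param deg_cooccur Probability that a hd-promoter-targeted gene is a
#'   DEG in `enrich_tissue`.
#' @param n_peaks_per_tissue,diff_peak_fraction,peak_len_range Background
#'   ATAC peak counts, differential fraction and length range.
#' @param n_sim Default permutation rounds for downstream tests.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       n_genes = 300,
                       exon_count_range = c(2, 8),
                       exon_len_range = c(120, 300),
                       intron_len_range = c(500, 3000),
                       utr_len_range = c(20, 80),
                       repeat_fraction = 0.2,
                       n_per_pop = 20,
                       pop_labels = c("east", "west"),
                       n_sites = 30000,
                       background_f = 0.15,
                       n_sweeps = 10,
                       sweep_length = 2e5,
                       sweep_beta = c(20, 0.5),
                       hd_beta_high = c(50, 1),
                       hd_beta_low = c(1, 50),
                       hd_fraction = 0.02,
                       hd_promoter_lambda = 1.5,
                       n_planted_peaks = 20,
                       cds_depletion = 0.2,
                       indel_fraction = 0.02,
                       indel_max = 6,
                       missing_rate = 0.01,
                       tissues = c("muscle", "adipose", "cerebellum",
                                   "cerebrum", "heart", "liver", "lung",
                                   "pancreas", "small_intestine", "stomach"),
                       enrich_tissue = "muscle",
                       deg_fraction = 0.1,
                       deg_cooccur = 0.8,
                       n_peaks_per_tissue = 150,
                       diff_peak_fraction = 0.25,
                       peak_len_range = c(400, 1500),
                       n_sim = 1000) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(all(c(repeat_fraction, deg_fraction, deg_cooccur, hd_fraction,
                  diff_peak_fraction, indel_fraction, missing_rate) >= 0),
            all(c(repeat_fraction, deg_fraction, deg_cooccur,
                  diff_peak_fraction, indel_fraction, missing_rate) <= 1),
            background_f > 0, background_f < 1,
            sweep_length < min(chrom_lengths),
            length(pop_labels) == 2,
            enrich_tissue %in% tissues)
  class(cfg) <- "sim_config"
  cfg
}

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*" & names(gc) != "ATG"]
})
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

#' Simulate a genome with gene models and a repeat mask
#'
#' Builds random chromosome sequences, places non-overlapping genes with
#' exon/intron structure and a valid CDS (ATG start, sense internal
#' codons, terminal stop, length divisible by 3; the CDS sequence is
#' written into the chromosome on the gene's strand), and lays a repeat
#' mask avoiding CDS.  Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `layout`, `gene_models`, `repeat_mask` (interval
#'   data.frame) and `genome` (a [Biostrings::DNAStringSet]).
#' @export
simulate_genome <- function(config) {
  local_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  layout <- genome_layout(config$chrom_lengths)

  ## gene structures
  n <- config$n_genes
  structs <- lapply(seq_len(n), function(i) {
    ne <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]), 1)
    ex <- sample(seq(config$exon_len_range[1], config$exon_len_range[2]),
                 ne, replace = TRUE)
    intr <- if (ne > 1)
      sample(seq(config$intron_len_range[1], config$intron_len_range[2]),
             ne - 1, replace = TRUE) else integer(0)
    u5 <- sample(seq(config$utr_len_range[1], config$utr_len_range[2]), 1)
    u3 <- sample(seq(config$utr_len_range[1], config$utr_len_range[2]), 1)
    cds_len <- sum(ex) - u5 - u3
    u3 <- u3 + cds_len %% 3
    cds_len <- cds_len - cds_len %% 3
    stopifnot(cds_len >= 6)
    list(ex = ex, intr = intr, u5 = u5, u3 = u3, cds_len = cds_len,
         len = sum(ex) + sum(intr),
         strand = sample(c("+", "-"), 1))
  })

  ## distribute genes over chromosomes proportional to length, then place
  ## sequentially with random gaps
  chr_of <- sample(seq_along(layout$chrom), n, replace = TRUE,
                   prob = layout$length)
  genes <- list(); exons <- list(); cds <- list()
  gi <- 0
  for (ci in seq_along(layout$chrom)) {
    idx <- which(chr_of == ci)
    if (!length(idx)) next
    lens <- vapply(structs[idx], `[[`, numeric(1), "len")
    free <- layout$length[ci] - sum(lens)
    if (free <= length(idx) + 1)
      stop("cannot place ", length(idx), " genes on ", layout$chrom[ci],
           "; reduce n_genes")
    gaps <- stats::runif(length(idx) + 1)
    gaps <- floor(gaps / sum(gaps) * free)
    start <- cumsum(c(0, lens[-length(lens)])) + cumsum(gaps[-length(gaps)])
    for (k in seq_along(idx)) {
      gi <- gi + 1
      st <- structs[[idx[k]]]
      gid <- sprintf("gene%04d", gi)
      g0 <- start[k]
      ex_starts <- g0 + cumsum(c(0, st$ex[-length(st$ex)] + st$intr))
      ex_ends <- ex_starts + st$ex
      genes[[gi]] <- data.frame(
        gene_id = gid, chrom = layout$chrom[ci], strand = st$strand,
        start = g0, end = g0 + st$len,
        tss = if (st$strand == "+") g0 else g0 + st$len,
        transcript_id = paste0(gid, ".t1"), stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(gene_id = gid, start = ex_starts,
                                end = ex_ends, stringsAsFactors = FALSE)
      ## CDS occupies forward exon-space [a, b)
      E <- sum(st$ex)
      a <- if (st$strand == "+") st$u5 else st$u3
      b <- E - if (st$strand == "+") st$u3 else st$u5
      cum <- cumsum(c(0, st$ex))
      pieces <- list()
      for (e in seq_along(st$ex)) {
        lo <- max(a, cum[e]); hi <- min(b, cum[e + 1])
        if (lo < hi)
          pieces[[length(pieces) + 1]] <- data.frame(
            gene_id = gid,
            start = ex_starts[e] + (lo - cum[e]),
            end = ex_starts[e] + (hi - cum[e]),
            stringsAsFactors = FALSE)
      }
      cdf <- do.call(rbind, pieces)
      ## coding-order phase
      ord <- if (st$strand == "+") order(cdf$start) else order(-cdf$start)
      w <- (cdf$end - cdf$start)[ord]
      ph <- (3 - cumsum(c(0, w[-length(w)])) %% 3) %% 3
      cdf$phase <- 0L
      cdf$phase[ord] <- as.integer(ph)
      cds[[gi]] <- cdf
    }
  }
  gm <- structure(list(genes = do.call(rbind, genes),
                       exons = do.call(rbind, exons),
                       cds = do.call(rbind, cds)),
                  class = "gene_models")

  ## random sequence, then write valid CDS codons in place
  genome <- Biostrings::DNAStringSet(vapply(layout$length, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- layout$chrom
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    cd <- gm$cds[gm$cds$gene_id == g$gene_id, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    clen <- sum(cd$end - cd$start)
    ncod <- clen / 3
    coding <- paste0("ATG",
                     paste(sample(SENSE_CODONS, ncod - 2, replace = TRUE),
                           collapse = ""),
                     sample(STOP_CODONS, 1))
    fwd <- if (g$strand == "+") coding else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    offs <- cumsum(c(0, cd$end - cd$start))
    vals <- substring(fwd, offs[-length(offs)] + 1, offs[-1])
    genome[[g$chrom]] <- Biostrings::replaceAt(
      genome[[g$chrom]], IRanges::IRanges(cd$start + 1, cd$end),
      Biostrings::DNAStringSet(vals))
  }

  ## repeat mask avoiding CDS
  repeat_mask <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0))
  if (config$repeat_fraction > 0) {
    target <- config$repeat_fraction * genome_bp(layout)
    lens <- integer(0)
    while (sum(lens) < target) lens <- c(lens, sample(200:2000, 200, TRUE))
    lens <- lens[cumsum(lens) <= target]
    tmpl <- data.frame(chrom = "x", start = 0, end = lens)
    cds_all <- gm$cds[, c("start", "end")]
    cds_all <- data.frame(chrom = gm$genes$chrom[
      match(gm$cds$gene_id, gm$genes$gene_id)], cds_all)
    repeat_mask <- sample_matched_intervals(tmpl, layout, mask = cds_all)
    repeat_mask <- normalize_intervals(repeat_mask, layout, merge = TRUE)
  }

  list(layout = layout, gene_models = gm, repeat_mask = repeat_mask,
       genome = genome)
}

#' Plan the ground truth of a synthetic study
#'
#' Places the sweep intervals (alternating target population), selects the
#' promoter-targeted genes (genes whose promoter overlaps a sweep), plans
#' the differential ATAC peaks planted inside sweeps, and draws DEG labels
#' per tissue co-occurring with the targeted genes at the configured rate.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list of class `sim_truth`; see [simulate_study()].
#' @export
plan_truth <- function(config, genome) {
  local_seed(config$seed + 1L, plan_truth_impl(config, genome))
}

plan_truth_impl <- function(config, genome) {
  layout <- genome$layout
  ## non-overlapping sweep intervals, alternating populations
  sweeps <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), population = character(0))
  if (config$n_sweeps > 0) {
    tries <- 0
    while (nrow(sweeps) < config$n_sweeps && tries < 1000) {
      tries <- tries + 1
      ci <- sample(seq_along(layout$chrom), 1, prob = layout$length)
      s <- floor(stats::runif(1) * (layout$length[ci] - config$sweep_length))
      cand <- data.frame(chrom = layout$chrom[ci], start = s,
                         end = s + config$sweep_length)
      if (nrow(sweeps) == 0 ||
          !any(IRanges::overlapsAny(gr_from_df(cand, layout),
                                    gr_from_df(sweeps[, 1:3], layout))))
        sweeps <- rbind(sweeps[, 1:3], cand)
    }
    if (nrow(sweeps) < config$n_sweeps)
      stop("could not place ", config$n_sweeps, " non-overlapping sweeps")
    sweeps$population <- config$pop_labels[rep_len(1:2, nrow(sweeps))]
  }

  ## promoter-targeted genes: promoter overlaps a sweep
  index <- build_feature_index(genome$gene_models, layout)
  prom <- promoter_intervals(index)
  targeted <- character(0)
  if (nrow(sweeps) && nrow(prom)) {
    hit <- IRanges::overlapsAny(gr_from_df(prom), gr_from_df(sweeps[, 1:3]))
    targeted <- sort(unique(prom$gene_id[hit]))
  }

  ## planted differential peaks inside sweeps, avoiding promoters
  planted_peaks <- data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0))
  if (config$n_planted_peaks > 0 && nrow(sweeps)) {
    lens <- sample(seq(config$peak_len_range[1], config$peak_len_range[2]),
                   config$n_planted_peaks, replace = TRUE)
    ## sample placements uniformly inside the sweep set
    outside <- complement_intervals(sweeps[, 1:3], layout)
    mask <- normalize_intervals(rbind(outside, prom[, c("chrom", "start", "end")]),
                                layout, merge = TRUE)
    planted_peaks <- sample_matched_intervals(
      data.frame(chrom = "x", start = 0, end = lens), layout, mask = mask)
  }

  ## DEG labels per tissue; co-occurrence with targeted genes in the
  ## enrichment tissue
  gid <- genome$gene_models$genes$gene_id
  deg <- list()
  for (t in config$tissues) {
    is_t <- t == config$enrich_tissue
    p <- ifelse(is_t & gid %in% targeted, config$deg_cooccur,
                config$deg_fraction)
    deg[[t]] <- gid[stats::runif(length(gid)) < p]
  }

  structure(list(
    sweeps = sweeps,
    hd_promoter_genes = targeted,
    planted_peaks = planted_peaks,
    deg = deg,
    hd_variants = data.frame(chrom = character(0), pos = numeric(0),
                             feature = character(0)),
    config_digest = config_digest(config)
  ), class = "sim_truth")
}

#' Simulate two-population genotypes with planted sweeps and hd variants
#'
#' Background sites follow the Balding-Nichols model: ancestral frequency
#' p ~ U(0.05, 0.95) and per-population frequency
#' Beta(p (1-F)/F, (1-p)(1-F)/F), independently per population; genotypes
#' are Binomial(2, p_pop) per diploid sample.  Sites inside a sweep take
#' the swept-population frequency from a near-fixation Beta, producing
#' high F_ST and low swept-population diversity.  Highly differential (hd)
#' variants are planted in the targeted promoters and planted peaks (and
#' at a background rate across sweeps) with near-opposite-fixation
#' frequencies.  Sites falling in CDS are thinned by the depletion factor.
#' A fraction of sites is emitted as short indels.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [plan_truth()].
#' @return A list with `vt` (a `variant_table`), `sample_map` and the
#'   updated `truth` whose `hd_variants` records every planted variant.
#' @export
simulate_populations <- function(config, genome, truth) {
  local_seed(config$seed + 2L, simulate_populations_impl(config, genome, truth))
}

simulate_populations_impl <- function(config, genome, truth) {
  layout <- genome$layout
  gm <- genome$gene_models

  cds_all <- data.frame(
    chrom = gm$genes$chrom[match(gm$cds$gene_id, gm$genes$gene_id)],
    start = gm$cds$start, end = gm$cds$end)
  cds_gr <- gr_from_df(normalize_intervals(cds_all, layout, merge = TRUE))

  ## base positions: uniform, CDS thinned
  per_chrom <- stats::rmultinom(1, config$n_sites,
                                layout$length / sum(layout$length))[, 1]
  pos <- numeric(0); chrom <- character(0)
  for (ci in seq_along(layout$chrom)) {
    p <- sample.int(layout$length[ci] - config$indel_max - 1,
                    per_chrom[ci]) - 1
    pos <- c(pos, p)
    chrom <- c(chrom, rep(layout$chrom[ci], per_chrom[ci]))
  }
  pt <- gr_from_df(data.frame(chrom = chrom, start = pos, end = pos + 1))
  in_cds <- IRanges::overlapsAny(pt, cds_gr)
  keep <- !in_cds | stats::runif(length(pos)) < config$cds_depletion
  pos <- pos[keep]; chrom <- chrom[keep]
  feature <- rep("background", length(pos))

  ## planted hd variants: targeted promoters and planted peaks
  plant <- function(intervals, k_per, label) {
    if (!nrow(intervals)) return(NULL)
    res <- list()
    for (i in seq_len(nrow(intervals))) {
      k <- k_per()
      if (k < 1) next
      w <- intervals$end[i] - intervals$start[i]
      p <- intervals$start[i] + sample.int(w, min(k, w)) - 1
      res[[length(res) + 1]] <- data.frame(
        chrom = intervals$chrom[i], pos = p, feature = label,
        stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  index <- build_feature_index(gm, layout)
  prom_target <- promoter_intervals(index, truth$hd_promoter_genes)
  planted <- rbind(
    plant(prom_target, function() 1 + stats::rpois(1, config$hd_promoter_lambda),
          "promoter"),
    plant(truth$planted_peaks, function() 1 + stats::rpois(1, 0.5), "peak"))
  if (is.null(planted))
    planted <- data.frame(chrom = character(0), pos = numeric(0),
                          feature = character(0))

  chrom <- c(chrom, planted$chrom)
  pos <- c(pos, planted$pos)
  feature <- c(feature, planted$feature)

  ## dedupe, sort
  key <- paste(chrom, pos)
  dup <- duplicated(key)
  chrom <- chrom[!dup]; pos <- pos[!dup]; feature <- feature[!dup]
  ord <- order(match(chrom, layout$chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; feature <- feature[ord]
  n <- length(pos)

  ## sweep membership and background hd planting
  pgr <- gr_from_df(data.frame(chrom = chrom, start = pos, end = pos + 1))
  sweep_pop <- rep(NA_character_, n)
  if (nrow(truth$sweeps)) {
    hits <- GenomicRanges::findOverlaps(pgr, gr_from_df(truth$sweeps[, 1:3]))
    sweep_pop[S4Vectors::queryHits(hits)] <-
      truth$sweeps$population[S4Vectors::subjectHits(hits)]
  }
  is_planted <- feature != "background"
  bg_hd <- !is_planted & !is.na(sweep_pop) &
    stats::runif(n) < config$hd_fraction
  feature[bg_hd] <- "sweep_background"
  is_hd <- is_planted | bg_hd

  ## allele frequencies
  F <- config$background_f
  anc <- stats::runif(n, 0.05, 0.95)
  bn <- function(p) stats::rbeta(length(p), p * (1 - F) / F,
                                 (1 - p) * (1 - F) / F)
  p1 <- bn(anc); p2 <- bn(anc)
  in_sw1 <- !is.na(sweep_pop) & sweep_pop == config$pop_labels[1]
  in_sw2 <- !is.na(sweep_pop) & sweep_pop == config$pop_labels[2]
  swp <- function(k) stats::rbeta(k, config$sweep_beta[1], config$sweep_beta[2])
  p1[in_sw1 & !is_hd] <- swp(sum(in_sw1 & !is_hd))
  p2[in_sw2 & !is_hd] <- swp(sum(in_sw2 & !is_hd))
  ## hd sites: near-fixed high in the local sweep population (population 1
  ## when outside any sweep), near-zero in the other
  hi <- function(k) stats::rbeta(k, config$hd_beta_high[1], config$hd_beta_high[2])
  lo <- function(k) stats::rbeta(k, config$hd_beta_low[1], config$hd_beta_low[2])
  hd1 <- is_hd & (in_sw1 | is.na(sweep_pop))
  hd2 <- is_hd & in_sw2
  p1[hd1] <- hi(sum(hd1)); p2[hd1] <- lo(sum(hd1))
  p1[hd2] <- lo(sum(hd2)); p2[hd2] <- hi(sum(hd2))

  ## genotypes
  npop <- config$n_per_pop
  g1 <- matrix(stats::rbinom(n * npop, 2, p1), nrow = n)
  g2 <- matrix(stats::rbinom(n * npop, 2, p2), nrow = n)
  geno <- cbind(g1, g2)
  storage.mode(geno) <- "double"
  if (config$missing_rate > 0)
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA
  colnames(geno) <- c(sprintf("%s_s%02d", config$pop_labels[1], 1:npop),
                      sprintf("%s_s%02d", config$pop_labels[2], 1:npop))

  ## ref/alt from the reference sequence; a fraction become short indels
  chrom_str <- stats::setNames(
    lapply(seq_along(genome$genome), function(i) as.character(genome$genome[[i]])),
    names(genome$genome))
  base_at <- function(ch, p0, len = 1)
    substring(chrom_str[[ch]], p0 + 1, p0 + len)
  ref <- vapply(seq_len(n), function(i) base_at(chrom[i], pos[i]), character(1))
  other <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  alt <- vapply(ref, function(b) {
    o <- strsplit(other[[b]], "")[[1]]; sample(o, 1)
  }, character(1), USE.NAMES = FALSE)
  vclass <- rep("snp", n)
  make_indel <- !is_planted & stats::runif(n) < config$indel_fraction
  for (i in which(make_indel)) {
    d <- sample.int(config$indel_max, 1)
    if (stats::runif(1) < 0.5) {   # deletion
      ref[i] <- base_at(chrom[i], pos[i], d + 1)
      alt[i] <- substr(ref[i], 1, 1)
    } else {                       # insertion
      ref[i] <- base_at(chrom[i], pos[i])
      alt[i] <- paste0(ref[i], paste(sample(c("A", "C", "G", "T"), d,
                                            replace = TRUE), collapse = ""))
    }
    vclass[i] <- "indel"
  }

  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         vclass = vclass, stringsAsFactors = FALSE)
  vt <- structure(list(variants = variants, geno = geno, layout = layout),
                  class = "variant_table")
  sample_map <- as_sample_map(colnames(geno),
                              rep(config$pop_labels, each = npop))
  truth$hd_variants <- data.frame(chrom = chrom[is_hd], pos = pos[is_hd],
                                  feature = feature[is_hd],
                                  stringsAsFactors = FALSE)
  list(vt = vt, sample_map = sample_map, truth = truth)
}

#' Simulate expression and ATAC peak tables
#'
#' Expression rows carry the planned DEG labels (log2 fold changes and
#' FDRs drawn consistently with the default DEG thresholds).  Peak tables
#' combine the planted differential peaks of the enrichment tissue with
#' random background peaks, a configured fraction of which are
#' differential.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [plan_truth()].
#' @return A list with `expression` and `peaks` data.frames.
#' @export
simulate_omics <- function(config, genome, truth) {
  local_seed(config$seed + 3L, simulate_omics_impl(config, genome, truth))
}

simulate_omics_impl <- function(config, genome, truth) {
  gid <- genome$gene_models$genes$gene_id
  layout <- genome$layout
  expr <- list()
  for (t in config$tissues) {
    is_deg <- gid %in% truth$deg[[t]]
    nD <- sum(is_deg)
    lfc <- ifelse(is_deg,
                  sample(c(-1, 1), length(gid), TRUE) *
                    (1 + stats::rexp(length(gid), 1)),
                  stats::rnorm(length(gid), 0, 0.3))
    fdr <- ifelse(is_deg, stats::runif(length(gid), 0, 0.049),
                  stats::runif(length(gid), 0.051, 1))
    expr[[t]] <- data.frame(gene_id = gid, tissue = t,
                            log2fc = round(lfc, 4), fdr = round(fdr, 5),
                            is_deg = is_deg, stringsAsFactors = FALSE)
  }
  expression <- do.call(rbind, expr)
  rownames(expression) <- NULL

  peaks <- list()
  for (t in config$tissues) {
    nbg <- config$n_peaks_per_tissue
    lens <- sample(seq(config$peak_len_range[1], config$peak_len_range[2]),
                   nbg, replace = TRUE)
    bg <- sample_matched_intervals(
      data.frame(chrom = "x", start = 0, end = lens), layout, mask = NULL)
    bg$tissue <- t
    bg$is_diff <- stats::runif(nbg) < config$diff_peak_fraction
    if (t == config$enrich_tissue && nrow(truth$planted_peaks)) {
      pl <- truth$planted_peaks[, c("chrom", "start", "end")]
      pl$tissue <- t
      pl$is_diff <- TRUE
      bg <- rbind(pl, bg)
    }
    bg$fdr <- round(ifelse(bg$is_diff, stats::runif(nrow(bg), 0, 0.049),
                           stats::runif(nrow(bg), 0.051, 1)), 5)
    peaks[[t]] <- bg
  }
  peaks <- do.call(rbind, peaks)
  ord <- order(peaks$tissue, match(peaks$chrom, layout$chrom), peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  list(expression = expression, peaks = peaks)
}

#' Generate a complete synthetic study
#'
#' Orchestrates [simulate_genome()], [plan_truth()],
#' [simulate_populations()] and [simulate_omics()].
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with `config`, `layout`,
#'   `gene_models`, `repeat_mask`, `genome`, `vt`, `sample_map`,
#'   `expression`, `peaks` and `truth`.
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  truth <- plan_truth(config, genome)
  pops <- simulate_populations(config, genome, truth)
  omics <- simulate_omics(config, genome, pops$truth)
  structure(c(list(config = config), genome,
              list(vt = pops$vt, sample_map = pops$sample_map,
                   expression = omics$expression, peaks = omics$peaks,
                   truth = pops$truth)),
            class = "sim_study")
}

#' Place query points with a configured relative density in target intervals
#'
#' Draws `n_queries` point positions over the mask-excluded genome such
#' that the per-bp density inside the target intervals is `rel_density`
#' times the density outside; the synthetic ground truth behind planted
#' enrichment/depletion recovery tests.
#'
#' @param layout A [genome_layout()].
#' @param targets Target interval data.frame.
#' @param mask Excluded intervals (may be `NULL`).
#' @param n_queries Number of points.
#' @param rel_density True relative density (1 = uniform null).
#' @return A data.frame (`chrom`, `pos`) of query positions.
#' @export
simulate_enrichment_queries <- function(layout, targets, mask = NULL,
                                        n_queries, rel_density = 1) {
  unmasked <- if (is.null(mask) || nrow(mask) == 0)
    data.frame(chrom = layout$chrom, start = 0, end = layout$length)
  else complement_intervals(normalize_intervals(mask, layout, merge = TRUE),
                            layout)
  tgt <- normalize_intervals(targets[, c("chrom", "start", "end")],
                             layout, merge = TRUE)
  inside <- df_from_gr(GenomicRanges::intersect(gr_from_df(unmasked),
                                                gr_from_df(tgt)))
  outside <- df_from_gr(GenomicRanges::setdiff(gr_from_df(unmasked),
                                               gr_from_df(tgt)))
  Tbp <- sum(inside$end - inside$start)
  Bbp <- sum(outside$end - outside$start)
  p_in <- rel_density * Tbp / (rel_density * Tbp + Bbp)
  n_in <- stats::rbinom(1, n_queries, p_in)
  draw_from <- function(iv, k) {
    if (k == 0) return(data.frame(chrom = character(0), pos = numeric(0)))
    w <- iv$end - iv$start
    u <- floor(stats::runif(k) * sum(w))
    cs <- cumsum(w)
    gi <- findInterval(u, cs) + 1
    data.frame(chrom = iv$chrom[gi], pos = iv$start[gi] + u - c(0, cs)[gi],
               stringsAsFactors = FALSE)
  }
  out <- rbind(draw_from(inside, n_in), draw_from(outside, n_queries - n_in))
  ord <- order(match(out$chrom, layout$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

config_digest <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config[order(names(unclass(config)))]), f)
  unname(tools::md5sum(f))
}

#' Write a synthetic study to a fixture directory
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.bed`, `variants.vcf`,
#' `samples.tsv`, `expression.tsv`, `peaks.tsv`, `truth.json` and a
#' `MANIFEST` carrying the config digest and seed.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing fixture directory.
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(study, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("fixture directory exists: ", outdir, " (use overwrite = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  Biostrings::writeXStringSet(study$genome, p("genome.fa"))
  write_gff_genes(study$gene_models, p("genes.gff3"))
  if (nrow(study$repeat_mask)) write_intervals(study$repeat_mask, p("repeats.bed"))
  else writeLines(character(0), p("repeats.bed"))
  write_vcf(study$vt, p("variants.vcf"))
  utils::write.table(study$sample_map, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$peaks, p("peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- study$truth
  jsonlite::write_json(list(
    schema = "sweepcis-truth/1",
    sweeps = truth$sweeps,
    hd_promoter_genes = truth$hd_promoter_genes,
    planted_peaks = truth$planted_peaks,
    hd_variants = truth$hd_variants,
    deg = truth$deg,
    config_digest = truth$config_digest
  ), p("truth.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(paste0("config_digest\t", config_digest(study$config)),
               paste0("seed\t", study$config$seed)),
             p("MANIFEST"))
  invisible(outdir)
}

#' Read a truth.json back
#' @param path Path to `truth.json`.
#' @return The `sim_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sweeps", "planted_peaks", "hd_variants"))
    if (!is.data.frame(x[[f]]))
      x[[f]] <- as.data.frame(x[[f]])
  x
}

## Minimal deterministic writers for formats the simulator emits.

write_vcf <- function(vt, path) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(vt$layout))
             sprintf("##contig=<ID=%s,length=%d>", vt$layout$chrom,
                     as.integer(vt$layout$length)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(vt$geno)), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[vt$geno + 1],
               nrow(vt$geno), ncol(vt$geno))
  gt[is.na(vt$geno)] <- "./."
  body <- paste(vt$variants$chrom, format(vt$variants$pos + 1, scientific = FALSE,
                                          trim = TRUE),
                ".", vt$variants$ref, vt$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_gff_genes <- function(gm, path) {
  fmt <- function(chrom, type, start, end, strand, phase, attrs)
    paste(chrom, "sweepcis", type,
          format(start + 1, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE),
          ".", strand, phase, attrs, sep = "\t")
  lines <- character(0)
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    cd <- gm$cds[gm$cds$gene_id == g$gene_id, , drop = FALSE]
    lines <- c(lines,
      fmt(g$chrom, "gene", g$start, g$end, g$strand, ".",
          paste0("ID=", g$gene_id)),
      fmt(g$chrom, "mRNA", g$start, g$end, g$strand, ".",
          paste0("ID=", g$transcript_id, ";Parent=", g$gene_id)),
      fmt(g$chrom, "exon", ex$start, ex$end, g$strand, ".",
          paste0("ID=", g$transcript_id, ".e", seq_len(nrow(ex)),
                 ";Parent=", g$transcript_id)),
      fmt(g$chrom, "CDS", cd$start, cd$end, g$strand, cd$phase,
          paste0("ID=", g$transcript_id, ".c", seq_len(nrow(cd)),
                 ";Parent=", g$transcript_id)))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
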