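#' Empirical quantile cutoffs for sweep calling
#'
#' Rank-based cutoffs over the analyzable windows: a window is "top q" iff
#' its value is at least the ceiling(q * m)-th largest value (ties
#' inclusive), and symmetrically for lower tails.  Windows with undefined
#' F_ST are excluded from the F_ST cutoff; windows with undefined
#' diversity ratio are excluded from the ratio cutoffs (they remain
#' eligible for the low-diversity rule).
#'
#' @param ws A `window_stats` data.frame.
#' @param fst_top Upper-tail mass for F_ST (default 0.10).
#' @param tail Tail mass for the ratio and per-population diversity
#'   (default 0.05).
#' @return A list of class `quantile_cutoffs` with `fst_top_cut`,
#'   `ratio_low_cut`, `ratio_high_cut`, `pi_low_cut` (length-2, per
#'   population) and the tail masses.
#' @export
compute_cutoffs <- function(ws, fst_top = 0.10, tail = 0.05) {
  if (nrow(ws) < 20)
    stop("too few windows (", nrow(ws), ") for empirical quantiles")
  fst <- ws$fst[!is.na(ws$fst)]
  if (!length(fst)) stop("all windows have undefined F_ST")
  ratio <- ws$ratio[ws$ratio_defined]
  if (!length(ratio)) stop("all windows have undefined diversity ratio")
  kth_largest <- function(x, q) sort(x, decreasing = TRUE)[ceiling(q * length(x))]
  kth_smallest <- function(x, q) sort(x)[ceiling(q * length(x))]
  structure(list(
    fst_top_cut = kth_largest(fst, fst_top),
    ratio_low_cut = kth_smallest(ratio, tail),
    ratio_high_cut = kth_largest(ratio, tail),
    pi_low_cut = c(kth_smallest(ws$pi_pop1, tail),
                   kth_smallest(ws$pi_pop2, tail)),
    fst_top = fst_top, tail = tail,
    populations = attr(ws, "populations")
  ), class = "quantile_cutoffs")
}

#' Flag windows under the quantile-combination calling rules
#'
#' Rule A combines high differentiation with an extreme diversity ratio: a
#' window in the top F_ST tail whose ratio (pi_pop1 / pi_pop2) falls in the
#' low tail is called swept in population 1 (the numerator population has
#' lost diversity); a ratio in the high tail calls population 2.  Rule B
#' combines high differentiation with absolutely low diversity: a window in
#' the top F_ST tail whose pi for population X is in that population's low
#' tail is called swept in X.  A window may carry both rules and, rarely,
#' both populations.
#'
#' @param ws A `window_stats` data.frame.
#' @param cutoffs A `quantile_cutoffs` from [compute_cutoffs()] computed on
#'   the same window set.
#' @return `ws` with logical columns `ruleA_pop1`, `ruleA_pop2`,
#'   `ruleB_pop1`, `ruleB_pop2` and the convenience columns `swept_pop1`,
#'   `swept_pop2`.
#' @export
call_windows <- function(ws, cutoffs) {
  fst_hi <- !is.na(ws$fst) & ws$fst >= cutoffs$fst_top_cut
  ratio_lo <- ws$ratio_defined & ws$ratio <= cutoffs$ratio_low_cut
  ratio_hi <- ws$ratio_defined & ws$ratio >= cutoffs$ratio_high_cut
  out <- ws
  out$ruleA_pop1 <- fst_hi & ratio_lo
  out$ruleA_pop2 <- fst_hi & ratio_hi
  out$ruleB_pop1 <- fst_hi & ws$pi_pop1 <= cutoffs$pi_low_cut[1]
  out$ruleB_pop2 <- fst_hi & ws$pi_pop2 <= cutoffs$pi_low_cut[2]
  out$swept_pop1 <- out$ruleA_pop1 | out$ruleB_pop1
  out$swept_pop2 <- out$ruleA_pop2 | out$ruleB_pop2
  attr(out, "populations") <- attr(ws, "populations")
  class(out) <- class(ws)
  out
}

#' Merge flagged windows into sweep regions
#'
#' Per population, overlapping or book-ended flagged windows are merged
#' into maximal regions; the calling rules of the member windows are
#' unioned.  The result is independent of input window order and
#' idempotent.
#'
#' @param called Output of [call_windows()].
#' @return A data.frame of class `sweep_regions`: `chrom`, `start`, `end`,
#'   `population`, `rules` (e.g. `"A"`, `"B"`, `"AB"`), `window_count`.
#' @export
merge_regions <- function(called) {
  pops <- attr(called, "populations")
  if (is.null(pops)) pops <- c("pop1", "pop2")
  out <- list()
  for (k in 1:2) {
    sel <- called[[paste0("swept_pop", k)]]
    if (!any(sel)) next
    w <- called[sel, , drop = FALSE]
    gr <- GenomicRanges::reduce(gr_from_df(w))
    hits <- GenomicRanges::findOverlaps(gr_from_df(w), gr)
    reg <- df_from_gr(gr)
    rs <- S4Vectors::subjectHits(hits); qs <- S4Vectors::queryHits(hits)
    ruleA <- tapply(w[[paste0("ruleA_pop", k)]][qs], rs, any)
    ruleB <- tapply(w[[paste0("ruleB_pop", k)]][qs], rs, any)
    cnt <- tapply(qs, rs, length)
    i <- as.character(seq_len(nrow(reg)))
    reg$population <- pops[k]
    reg$rules <- paste0(ifelse(ruleA[i], "A", ""), ifelse(ruleB[i], "B", ""))
    reg$window_count <- as.integer(cnt[i])
    out[[length(out) + 1]] <- reg
  }
  if (!length(out))
    out <- list(data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), population = character(0),
                           rules = character(0), window_count = integer(0)))
  res <- do.call(rbind, out)
  ord <- order(res$population, match(res$chrom, unique(called$chrom)), res$start)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("sweep_regions", "data.frame")
  res
}

#' Genes overlapping sweep regions
#'
#' A gene is selected iff its span overlaps a region by at least 1 bp
#' (half-open intervals, so a gene ending where a region starts does not
#' overlap).
#'
#' @param regions A `sweep_regions` data.frame.
#' @param gene_models A `gene_models` object.
#' @return A data.frame `gene_id`, `population`, `rules`, `chrom`,
#'   `region_start`, `region_end`, one row per (gene, region) pair.
#' @export
genes_in_regions <- function(regions, gene_models) {
  g <- gene_models$genes
  if (nrow(regions) == 0 || nrow(g) == 0)
    return(data.frame(gene_id = character(0), population = character(0),
                      rules = character(0), chrom = character(0),
                      region_start = numeric(0), region_end = numeric(0)))
  hits <- GenomicRanges::findOverlaps(gr_from_df(g), gr_from_df(regions))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = g$gene_id[qi],
    population = regions$population[si],
    rules = regions$rules[si],
    chrom = regions$chrom[si],
    region_start = regions$start[si],
    region_end = regions$end[si],
    stringsAsFactors = FALSE)
  out <- out[order(out$population, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome fraction covered by sweep regions
#'
#' Merges regions across populations and reports total covered bp and its
#' fraction of the genome.
#'
#' @param regions A `sweep_regions` data.frame.
#' @param layout A [genome_layout()].
#' @return A list with `bp` and `fraction`.
#' @export
region_genome_fraction <- function(regions, layout) {
  if (nrow(regions) == 0) return(list(bp = 0, fraction = 0))
  merged <- df_from_gr(GenomicRanges::reduce(gr_from_df(regions, layout)))
  bp <- sum(merged$end - merged$start)
  list(bp = bp, fraction = bp / genome_bp(layout))
}
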