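#' Sample count-and-length-matched random intervals
#'
#' Draws one random interval per template interval, matched in length,
#' uniformly over all genomic placements whose full span avoids the mask.
#' Intervals are drawn independently and may overlap one another.
#'
#' @param template Interval data.frame whose lengths are to be matched.
#' @param layout A [genome_layout()].
#' @param mask Interval data.frame of excluded regions (e.g. repeats); may
#'   be empty or `NULL`.
#' @param n_sets Number of matched sets to draw at once (default 1); all
#'   sets are drawn from the current RNG state, so seed the generator
#'   before calling for reproducibility.
#' @return For `n_sets = 1` an interval data.frame; otherwise a list of
#'   `n_sets` interval data.frames.
#' @export
sample_matched_intervals <- function(template, layout, mask = NULL,
                                     n_sets = 1) {
  gaps <- if (is.null(mask) || nrow(mask) == 0)
    data.frame(chrom = layout$chrom, start = 0, end = layout$length)
  else complement_intervals(normalize_intervals(mask, layout, merge = TRUE),
                            layout)
  gapw <- gaps$end - gaps$start
  lens <- template$end - template$start
  ulen <- sort(unique(lens))

  total <- nrow(template) * n_sets
  out_chrom <- character(total); out_start <- numeric(total)
  for (L in ulen) {
    avail <- pmax(gapw - L + 1, 0)
    T_L <- sum(avail)
    if (T_L <= 0)
      stop("no mask-free placement for template length ", L)
    rows <- which(rep(lens == L, n_sets))
    u <- floor(stats::runif(length(rows)) * T_L) + 1   # uniform in 1..T_L
    u <- pmin(u, T_L)
    cs <- cumsum(avail)
    gi <- findInterval(u - 1, cs) + 1                  # gap index
    off <- u - c(0, cs)[gi] - 1                        # 0-based offset in gap
    out_chrom[rows] <- gaps$chrom[gi]
    out_start[rows] <- gaps$start[gi] + off
  }
  lens_all <- rep(lens, n_sets)
  res <- data.frame(chrom = out_chrom, start = out_start,
                    end = out_start + lens_all, stringsAsFactors = FALSE)
  if (n_sets == 1) return(res)
  split(res, rep(seq_len(n_sets), each = nrow(template)))
}

#' Count-and-length-matched permutation enrichment/depletion test
#'
#' Counts query variants overlapping the target intervals (each query
#' counted at most once), then redraws `n_sim` random target sets matched
#' in interval count and length from the mask-excluded genome and recounts.
#' The mean simulated count is `rand`; the enrichment fold is
#' `obs / rand`.  The strict empirical P-values are
#' `p_enrich = #\{sim >= obs\} / n_sim` and
#' `p_deplete = #\{sim < obs\} / n_sim` (they sum to exactly 1);
#' pseudocount-corrected companions `(x + 1) / (n_sim + 1)` are also
#' reported.
#'
#' @param query Variant position data.frame (`chrom`, `pos`) or a variant
#'   table's `variants` component.
#' @param targets Target interval data.frame.
#' @param layout A [genome_layout()].
#' @param mask Excluded intervals (may be `NULL`).
#' @param n_sim Number of simulation rounds (default 1000).
#' @param seed Integer seed driving the permutation RNG.
#' @return A list of class `enrichment_result`: `obs`, `sims`, `rand`,
#'   `fold` (`NA` when `rand` is 0), `p_enrich`, `p_deplete`,
#'   `p_enrich_corrected`, `p_deplete_corrected`, `n_sim`, `seed`.
#' @export
permutation_interval_test <- function(query, targets, layout, mask = NULL,
                                      n_sim = 1000, seed) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (missing(seed)) stop("seed is required")
  qgr <- gr_from_df(data.frame(chrom = query$chrom, start = query$pos,
                               end = query$pos + 1))
  obs <- count_covered(qgr, targets)
  sims <- local_seed(seed, {
    sets <- sample_matched_intervals(targets, layout, mask, n_sets = n_sim)
    all <- do.call(rbind, sets)
    sim_id <- rep(seq_len(n_sim), each = nrow(targets))
    hits <- GenomicRanges::findOverlaps(qgr, gr_from_df(all))
    pair <- unique(cbind(S4Vectors::queryHits(hits),
                         sim_id[S4Vectors::subjectHits(hits)]))
    counts <- numeric(n_sim)
    if (nrow(pair)) {
      tab <- table(pair[, 2])
      counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    counts
  })
  rand <- mean(sims)
  structure(list(
    obs = obs, sims = sims, rand = rand,
    fold = if (rand > 0) obs / rand else NA_real_,
    p_enrich = sum(sims >= obs) / n_sim,
    p_deplete = sum(sims < obs) / n_sim,
    p_enrich_corrected = (sum(sims >= obs) + 1) / (n_sim + 1),
    p_deplete_corrected = (sum(sims < obs) + 1) / (n_sim + 1),
    n_sim = n_sim, seed = seed
  ), class = "enrichment_result")
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: obs=%d rand=%.2f fold=%.3f p_enrich=%.4g p_deplete=%.4g (n_sim=%d)\n",
    x$obs, x$rand, x$fold, x$p_enrich, x$p_deplete, x$n_sim))
  invisible(x)
}

count_covered <- function(qgr, intervals) {
  if (nrow(intervals) == 0) return(0L)
  sum(IRanges::overlapsAny(qgr, gr_from_df(intervals)))
}

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Drop regions near functional coding variants
#'
#' Removes every region whose span intersects `[v - flank, v + flank]`
#' (closed, in bp) around any of the given variant positions; used to
#' remove regions under selection within 50 kb of highly differential
#' functional coding variants before regulatory enrichment tests.
#'
#' @param regions Interval data.frame.
#' @param variants Variant data.frame (`chrom`, `pos`) of functional
#'   coding variants.
#' @param flank Exclusion distance in bp (default 50 kb).
#' @return The retained region rows.
#' @export
exclude_near_coding <- function(regions, variants, flank = 50000) {
  if (nrow(regions) == 0 || nrow(variants) == 0) return(regions)
  zones <- data.frame(chrom = variants$chrom,
                      start = pmax(0, variants$pos - flank),
                      end = variants$pos + flank + 1)
  hit <- IRanges::overlapsAny(gr_from_df(regions), gr_from_df(zones))
  out <- regions[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set test
#'
#' Upper-tail probability P(X >= k) of drawing `k` or more trait genes
#' when `n` genes are sampled from a universe of `N` genes of which `K`
#' carry the trait.
#'
#' @param k Observed overlap.
#' @param K Trait-set size.
#' @param n Selected-set size.
#' @param N Universe size.
#' @return The upper-tail P-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k > pmin(K, n)) || any(K > N) || any(n > N) || any(k < 0))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set tests over QTL/GWAS traits
#'
#' For each trait, tests whether the selected genes are enriched among the
#' trait's genes by [hypergeom_test()], with Benjamini-Hochberg FDR across
#' traits.
#'
#' @param trait_sets Named list of character vectors: genes per trait.
#' @param selected_genes Character vector of genes under selection.
#' @param universe Character vector of all genes considered.
#' @return A data.frame `trait`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
gene_set_tests <- function(trait_sets, selected_genes, universe) {
  selected_genes <- intersect(unique(selected_genes), universe)
  n <- length(selected_genes); N <- length(universe)
  rows <- lapply(names(trait_sets), function(tr) {
    Kset <- intersect(unique(trait_sets[[tr]]), universe)
    k <- length(intersect(Kset, selected_genes))
    data.frame(trait = tr, k = k, K = length(Kset), n = n, N = N,
               p = hypergeom_test(k, length(Kset), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Genes attached to QTL intervals and GWAS tag points
#'
#' QTL: genes whose span overlaps the interval.  GWAS: genes whose span
#' overlaps a window of `2 * half_width` bp centered at the tag midpoint
#' (clipped at the chromosome bounds).
#'
#' @param gene_models A `gene_models` object.
#' @param qtl_intervals Interval data.frame.
#' @return Character vector of gene ids.
#' @export
qtl_gene_set <- function(gene_models, qtl_intervals) {
  g <- gene_models$genes
  if (nrow(qtl_intervals) == 0) return(character(0))
  hit <- IRanges::overlapsAny(gr_from_df(g), gr_from_df(qtl_intervals))
  sort(unique(g$gene_id[hit]))
}

#' @rdname qtl_gene_set
#' @param tag_points Data.frame (`chrom`, `pos`) of GWAS tag positions.
#' @param half_width Half-window in bp (default 1 Mb, giving 2-Mb regions).
#' @param layout Optional [genome_layout()] for clipping.
#' @export
gwas_gene_set <- function(gene_models, tag_points, half_width = 1e6,
                          layout = NULL) {
  if (nrow(tag_points) == 0) return(character(0))
  win <- data.frame(chrom = tag_points$chrom,
                    start = pmax(0, tag_points$pos - half_width),
                    end = tag_points$pos + half_width)
  if (!is.null(layout))
    win$end <- pmin(win$end, chrom_length(layout, win$chrom))
  g <- gene_models$genes
  hit <- IRanges::overlapsAny(gr_from_df(g), gr_from_df(win))
  sort(unique(g$gene_id[hit]))
}
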