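#' Categorize selected genes by their highly differential variants
#'
#' For each gene under selection, flags whether any highly differential
#' (hd) variant restricted to sweep regions is (i) a functional coding or
#' splice variant of the gene, (ii) a promoter variant of the gene,
#' (iii) a protein-truncating variant of the gene, and whether both coding
#' and promoter classes co-occur.  Summary proportions are reported over
#' the pooled selected-gene set and per population.
#'
#' @param selected_genes Output of [genes_in_regions()].
#' @param hd_annotations Annotated hd variants (rows of
#'   [classify_variants()] output restricted to deltaAF-flagged variants in
#'   sweep regions).
#' @param gene_models A `gene_models` object (every selected gene must be
#'   present).
#' @return A list with `genes` (data.frame `gene_id`, `selected_pop`,
#'   `has_functional_coding_hd`, `has_promoter_hd`, `has_ptv_hd`,
#'   `has_both_coding_and_promoter`) and `proportions` (data.frame of the
#'   pooled class proportions: coding-only, promoter-only, both, none).
#' @export
categorize_selected_genes <- function(selected_genes, hd_annotations,
                                      gene_models) {
  ids <- unique(selected_genes$gene_id)
  missing <- setdiff(ids, gene_models$genes$gene_id)
  if (length(missing))
    stop("selected gene(s) absent from models: ", paste(missing, collapse = ", "))
  pop <- tapply(selected_genes$population, selected_genes$gene_id,
                function(p) paste(sort(unique(p)), collapse = "+"))

  coding_genes <- unique(hd_annotations$gene_id[
    hd_annotations$is_functional_coding & !is.na(hd_annotations$gene_id)])
  prom_genes <- unique(hd_annotations$gene_id[
    hd_annotations$category == "promoter" & !is.na(hd_annotations$gene_id)])
  ptv_genes <- unique(hd_annotations$gene_id[
    hd_annotations$is_ptv & !is.na(hd_annotations$gene_id)])

  genes <- data.frame(
    gene_id = ids,
    selected_pop = unname(pop[ids]),
    has_functional_coding_hd = ids %in% coding_genes,
    has_promoter_hd = ids %in% prom_genes,
    has_ptv_hd = ids %in% ptv_genes,
    stringsAsFactors = FALSE)
  genes$has_both_coding_and_promoter <-
    genes$has_functional_coding_hd & genes$has_promoter_hd
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  n <- nrow(genes)
  both <- sum(genes$has_both_coding_and_promoter)
  proportions <- data.frame(
    class = c("functional_coding_only", "promoter_only", "both", "none"),
    count = c(sum(genes$has_functional_coding_hd) - both,
              sum(genes$has_promoter_hd) - both,
              both,
              sum(!genes$has_functional_coding_hd & !genes$has_promoter_hd)),
    stringsAsFactors = FALSE)
  proportions$proportion <- if (n > 0) proportions$count / n else NA_real_
  list(genes = genes, proportions = proportions)
}

#' Link differentially expressed genes to highly differential promoter variants
#'
#' A DEG of the given tissue is linked iff at least one hd variant inside a
#' sweep region falls in its promoter.  Non-DEG genes are excluded from
#' both numerator and denominator.
#'
#' @param expression Expression table (see [read_expression()]).
#' @param hd_annotations Annotated hd variants restricted to sweep regions.
#' @param index A `feature_index` (supplies the promoter definition used
#'   to annotate).
#' @param tissue Tissue label to summarize.
#' @return A one-row data.frame `tissue`, `n_deg`, `n_deg_promoter_hd`,
#'   `prop_promoter_hd`, plus `linked_genes` as attribute.
#' @export
deg_promoter_links <- function(expression, hd_annotations, index, tissue) {
  ex <- expression[expression$tissue == tissue, , drop = FALSE]
  if (!nrow(ex)) stop("tissue absent from expression table: ", tissue)
  degs <- unique(ex$gene_id[ex$is_deg])
  prom_hits <- unique(hd_annotations$gene_id[
    hd_annotations$category == "promoter" & !is.na(hd_annotations$gene_id)])
  linked <- intersect(degs, prom_hits)
  out <- data.frame(tissue = tissue, n_deg = length(degs),
                    n_deg_promoter_hd = length(linked),
                    prop_promoter_hd = if (length(degs))
                      length(linked) / length(degs) else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "linked_genes") <- sort(linked)
  out
}

#' Link DEG to distal differential chromatin with hd variants
#'
#' A DEG of the given tissue is linked iff some differential ATAC peak of
#' that tissue (i) overlaps a sweep region, (ii) contains at least one hd
#' variant, (iii) lies within `max_dist` bp of the gene span (nearest-edge
#' distance), and (iv) does not overlap any promoter (distal peaks only).
#'
#' @param expression Expression table.
#' @param peaks Peak table (see [read_peaks()]).
#' @param sweep_regions A `sweep_regions` data.frame.
#' @param hd_variants Data.frame (`chrom`, `pos`) of hd variants.
#' @param gene_models A `gene_models` object.
#' @param index A `feature_index` (supplies promoter intervals).
#' @param tissue Tissue label.
#' @param max_dist Maximum peak-to-gene distance in bp (default 1 Mb).
#' @return A one-row data.frame `tissue`, `n_deg`, `n_deg_distal_diffca_hd`,
#'   `prop_distal_diffca_hd`, with `linked_genes` attribute.
#' @export
deg_distal_links <- function(expression, peaks, sweep_regions, hd_variants,
                             gene_models, index, tissue, max_dist = 1e6) {
  ex <- expression[expression$tissue == tissue, , drop = FALSE]
  if (!nrow(ex)) stop("tissue absent from expression table: ", tissue)
  degs <- unique(ex$gene_id[ex$is_deg])
  pk <- peaks[peaks$tissue == tissue & peaks$is_diff, , drop = FALSE]
  linked <- character(0)
  if (nrow(pk) && length(degs)) {
    pgr <- gr_from_df(pk)
    keep <- rep(TRUE, nrow(pk))
    prom <- index$promoter
    if (nrow(prom)) keep <- keep & !IRanges::overlapsAny(pgr, gr_from_df(prom))
    if (nrow(sweep_regions))
      keep <- keep & IRanges::overlapsAny(pgr, gr_from_df(sweep_regions))
    else keep <- rep(FALSE, nrow(pk))
    if (nrow(hd_variants))
      keep <- keep & IRanges::overlapsAny(
        pgr, gr_from_df(data.frame(chrom = hd_variants$chrom,
                                   start = hd_variants$pos,
                                   end = hd_variants$pos + 1)))
    else keep <- rep(FALSE, nrow(pk))
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk)) {
      g <- gene_models$genes[gene_models$genes$gene_id %in% degs, , drop = FALSE]
      if (nrow(g)) {
        ## nearest-edge distance <= max_dist: expand peaks by max_dist
        expanded <- data.frame(chrom = pk$chrom,
                               start = pmax(0, pk$start - max_dist),
                               end = pk$end + max_dist)
        hit <- IRanges::overlapsAny(gr_from_df(g), gr_from_df(expanded))
        linked <- g$gene_id[hit]
      }
    }
  }
  out <- data.frame(tissue = tissue, n_deg = length(degs),
                    n_deg_distal_diffca_hd = length(linked),
                    prop_distal_diffca_hd = if (length(degs))
                      length(linked) / length(degs) else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "linked_genes") <- sort(unique(linked))
  out
}

#' Ranked candidate gene report
#'
#' Combines gene categorization, DEG-link summaries and hd-variant
#' annotations into one evidence table per candidate gene, sorted by
#' (evidence count desc, max deltaAF desc, gene_id).
#'
#' @param gene_categories Output of [categorize_selected_genes()].
#' @param promoter_links,distal_links Lists (per tissue) of the outputs of
#'   [deg_promoter_links()] / [deg_distal_links()]; may be empty.
#' @param hd_annotations Annotated hd variants with a `delta_af` column.
#' @return A data.frame, one row per selected gene, with columns
#'   `gene_id`, `selected_pop`, `has_functional_coding_hd`,
#'   `has_promoter_hd`, `has_ptv_hd`, `deg_promoter_tissues`,
#'   `deg_distal_tissues`, `max_delta_af`, `evidence_count`.
#' @export
candidate_report <- function(gene_categories, promoter_links = list(),
                             distal_links = list(), hd_annotations = NULL) {
  genes <- gene_categories$genes
  if (nrow(genes) == 0) return(data.frame(
    gene_id = character(0), selected_pop = character(0),
    has_functional_coding_hd = logical(0), has_promoter_hd = logical(0),
    has_ptv_hd = logical(0), deg_promoter_tissues = character(0),
    deg_distal_tissues = character(0), max_delta_af = numeric(0),
    evidence_count = integer(0)))

  tissues_of <- function(links) {
    m <- stats::setNames(rep("", nrow(genes)), genes$gene_id)
    for (l in links) {
      hit <- intersect(attr(l, "linked_genes"), names(m))
      m[hit] <- ifelse(nzchar(m[hit]), paste(m[hit], l$tissue, sep = ","),
                       l$tissue)
    }
    unname(m)
  }
  out <- genes
  out$deg_promoter_tissues <- tissues_of(promoter_links)
  out$deg_distal_tissues <- tissues_of(distal_links)
  out$max_delta_af <- 0
  if (!is.null(hd_annotations) && nrow(hd_annotations) &&
      "delta_af" %in% names(hd_annotations)) {
    ok <- !is.na(hd_annotations$gene_id)
    mx <- tapply(hd_annotations$delta_af[ok], hd_annotations$gene_id[ok], max)
    hit <- intersect(names(mx), out$gene_id)
    out$max_delta_af[match(hit, out$gene_id)] <- unname(mx[hit])
  }
  out$evidence_count <- as.integer(
    out$has_functional_coding_hd + out$has_promoter_hd + out$has_ptv_hd +
      nzchar(out$deg_promoter_tissues) + nzchar(out$deg_distal_tissues))
  ord <- order(-out$evidence_count, -out$max_delta_af, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$has_both_coding_and_promoter <- NULL
  rownames(out) <- NULL
  out
}
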