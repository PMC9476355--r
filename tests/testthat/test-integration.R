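mk_sel <- function(ids, pop = "east") {
  data.frame(gene_id = ids, population = rep(pop, length(ids)),
             rules = rep("A", length(ids)), chrom = rep("chr1", length(ids)),
             region_start = rep(0, length(ids)),
             region_end = rep(1e5, length(ids)), stringsAsFactors = FALSE)
}
mk_ann <- function(gene_id, category, pos = seq_along(gene_id) * 100,
                   delta_af = 0.95) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
             vclass = "snp", category = category, gene_id = gene_id,
             is_functional_coding = category %in%
               c("cds_missense", "cds_stop_gain", "cds_stop_loss",
                 "cds_frameshift", "splice_site"),
             is_ptv = category %in% c("cds_frameshift", "cds_stop_gain"),
             delta_af = delta_af, stringsAsFactors = FALSE)
}
mk_gm <- function(ids) {
  genes <- data.frame(
    gene_id = ids, chrom = "chr1", strand = "+",
    start = seq_along(ids) * 1e4, end = seq_along(ids) * 1e4 + 5e3,
    tss = seq_along(ids) * 1e4,
    transcript_id = paste0(ids, ".t1"), stringsAsFactors = FALSE)
  structure(list(
    genes = genes,
    exons = data.frame(gene_id = ids, start = genes$start, end = genes$end,
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = ids, start = genes$start, end = genes$end,
                     phase = 0L, stringsAsFactors = FALSE)),
    class = "gene_models")
}

test_that("gene categories flag coding/promoter/PTV and the both class", {
  sel <- mk_sel(c("gA", "gB", "gC", "gD"))
  ann <- rbind(mk_ann("gA", "cds_missense"),
               mk_ann("gB", "cds_missense"),
               mk_ann("gB", "promoter"),
               mk_ann("gC", "cds_frameshift"))
  cats <- categorize_selected_genes(sel, ann, mk_gm(c("gA", "gB", "gC", "gD")))
  g <- cats$genes
  expect_equal(g$has_functional_coding_hd, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(g$has_promoter_hd, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(g$has_ptv_hd, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(g$has_both_coding_and_promoter, c(FALSE, TRUE, FALSE, FALSE))
  ## proportions partition the selected set exactly
  pr <- cats$proportions
  expect_equal(sum(pr$count), 4)
  expect_equal(sum(pr$proportion), 1)
  expect_equal(pr$count[pr$class == "both"], 1)
  expect_equal(pr$count[pr$class == "none"], 1)
  expect_error(categorize_selected_genes(sel, ann, mk_gm(c("gA", "gB"))),
               "absent")
})

test_that("DEG promoter links require DEG status and promoter-hd co-occurrence", {
  expr <- data.frame(gene_id = c("gA", "gB", "gC"), tissue = "muscle",
                     log2fc = c(2, 2, 0.1), fdr = c(0.01, 0.01, 0.9),
                     is_deg = c(TRUE, TRUE, FALSE))
  ann <- rbind(mk_ann("gA", "promoter"),   # DEG with promoter hd -> linked
               mk_ann("gC", "promoter"))   # non-DEG: excluded entirely
  out <- deg_promoter_links(expr, ann, NULL, "muscle")
  expect_equal(out$n_deg, 2)
  expect_equal(out$n_deg_promoter_hd, 1)
  expect_equal(out$prop_promoter_hd, 0.5)
  expect_equal(attr(out, "linked_genes"), "gA")
  expect_error(deg_promoter_links(expr, ann, NULL, "kidney"), "tissue absent")
})

test_that("distal links need sweep overlap, an hd variant, distance and no promoter", {
  ids <- c("gA", "gB")
  gm <- mk_gm(ids)
  gm$genes$start <- c(1e4, 5e6); gm$genes$end <- c(1.5e4, 5.005e6)
  gm$genes$tss <- gm$genes$start
  layout <- genome_layout(c(chr1 = 1e7))
  idx <- build_feature_index(gm, layout)
  expr <- data.frame(gene_id = ids, tissue = "muscle", log2fc = 2,
                     fdr = 0.01, is_deg = TRUE)
  regions <- data.frame(chrom = "chr1", start = 4e5, end = 6e5,
                        population = "east", rules = "A")
  peak <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    tissue = "muscle", is_diff = TRUE,
                                    fdr = 0.01)
  hd <- data.frame(chrom = "chr1", pos = 500500)
  # peak 500 kb from gA, inside sweep, carrying the hd variant -> gA linked
  out <- deg_distal_links(expr, peak(5e5, 501000), regions, hd, gm, idx,
                          "muscle", max_dist = 1e6)
  expect_equal(attr(out, "linked_genes"), "gA")
  # same peak is 4.5 Mb from gB -> gB not linked
  expect_false("gB" %in% attr(out, "linked_genes"))
  # outside every sweep region -> nothing
  out2 <- deg_distal_links(expr, peak(7e5, 701000), regions,
                           data.frame(chrom = "chr1", pos = 700500),
                           gm, idx, "muscle")
  expect_equal(out2$n_deg_distal_diffca_hd, 0)
  # peak overlapping a promoter is dropped from the distal analysis
  pk_prom <- peak(gm$genes$tss[1] - 100, gm$genes$tss[1] + 100)
  regions_all <- data.frame(chrom = "chr1", start = 0, end = 1e7,
                            population = "east", rules = "A")
  out3 <- deg_distal_links(expr, pk_prom, regions_all,
                           data.frame(chrom = "chr1", pos = gm$genes$tss[1]),
                           gm, idx, "muscle")
  expect_equal(out3$n_deg_distal_diffca_hd, 0)
  # monotone in max_dist: 1 Mb links contain 0.5 Mb links
  out_half <- deg_distal_links(expr, peak(5e5, 501000), regions, hd, gm, idx,
                               "muscle", max_dist = 5e5)
  expect_true(all(attr(out_half, "linked_genes") %in%
                    attr(out, "linked_genes")))
})

test_that("candidate report counts evidence and breaks ties by gene id", {
  sel <- mk_sel(c("gB", "gA", "gC"))
  ann <- rbind(mk_ann("gA", "promoter", delta_af = 0.92),
               mk_ann("gB", "promoter", delta_af = 0.98))
  cats <- categorize_selected_genes(sel, ann, mk_gm(c("gA", "gB", "gC")))
  pl <- list(muscle = structure(
    data.frame(tissue = "muscle", n_deg = 2, n_deg_promoter_hd = 2,
               prop_promoter_hd = 1),
    linked_genes = c("gA", "gB")))
  rep <- candidate_report(cats, pl, list(), ann)
  expect_equal(rep$gene_id, c("gB", "gA", "gC"))  # gB wins on deltaAF
  expect_equal(rep$evidence_count, c(2, 2, 0))
  expect_equal(rep$max_delta_af[1], 0.98)
  expect_equal(rep$deg_promoter_tissues[1:2], c("muscle", "muscle"))
  ## ties on all evidence: ordered by gene_id
  ann_tie <- rbind(mk_ann("gA", "promoter", delta_af = 0.95),
                   mk_ann("gB", "promoter", delta_af = 0.95))
  cats_tie <- categorize_selected_genes(sel, ann_tie, mk_gm(c("gA", "gB", "gC")))
  rep_tie <- candidate_report(cats_tie, list(), list(), ann_tie)
  expect_equal(rep_tie$gene_id, c("gA", "gB", "gC"))
  ## empty inputs produce an empty report
  empty <- categorize_selected_genes(mk_sel(character(0)),
                                     ann[0, , drop = FALSE],
                                     mk_gm(c("gA")))
  expect_equal(nrow(candidate_report(empty)), 0)
})

test_that("planted DEG/promoter-hd co-occurrence rate is recovered", {
  cfg <- small_sim_config(seed = 88, chrom_lengths = c(chr1 = 4e6, chr2 = 4e6),
                          n_genes = 500, n_sites = 12000, n_sweeps = 8,
                          deg_cooccur = 0.8)
  st <- simulate_study(cfg)
  idx <- build_feature_index(st$gene_models, st$layout)
  ann <- classify_variants(st$vt$variants, idx, st$genome)
  sf <- site_frequencies(st$vt, st$sample_map)
  ann$delta_af <- ifelse(sf$ok, abs(sf$p1 - sf$p2), NA)
  hd <- ann[!is.na(ann$delta_af) & ann$delta_af >= 0.9, , drop = FALSE]
  hd_sweep <- hd[sweepcis:::overlaps_points(hd, st$truth$sweeps), ,
                 drop = FALSE]
  planted <- st$truth$hd_promoter_genes
  linked <- attr(deg_promoter_links(st$expression, hd_sweep, idx, "muscle"),
                 "linked_genes")
  est <- length(intersect(linked, planted)) / length(planted)
  expect_gt(est, 0.8 - 0.1)
  expect_lt(est, 0.8 + 0.1)
})
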