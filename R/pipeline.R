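#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the inputs (or a `simulate` block), the output
#' directory, the seed, and every analysis threshold.  Defaults are the
#' study parameters used throughout the package: 50-kb windows with 10-kb
#' steps, 10-SNP minimum per window, 5\% MAF filter, deltaAF >= 0.9,
#' top-10\% F_ST with 5\% diversity tails, 1000 permutation rounds, 50-kb
#' coding-variant exclusion and 1-Mb distal linking.
#'
#' @param config A named list, or a path to a YAML file holding one.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    outdir = "sweepcis_out",
    seed = NULL,
    simulate = NULL,          # list of sim_config() overrides, or NULL
    inputs = list(),          # genome_fa, gff, vcf, samples, repeats_bed,
                              # expression, peaks, qtl_bed, gwas_tsv
    window_size = 50000, window_step = 10000, min_snps = 10,
    maf = 0.05, delta_af = 0.9,
    fst_top = 0.10, tail = 0.05,
    promoter_up = 2000, promoter_down = 200, splice_bp = 2,
    n_sim = 1000, exclude_flank = 50000, link_dist = 1e6,
    ld_max_dist = 300000, ld_bin = 100, ld_max_sites = 400)
  cfg <- utils::modifyList(defaults, config)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$window_step > 0 && cfg$window_size >= cfg$window_step,
      "window_step must satisfy 0 < step <= size")
  chk(cfg$maf >= 0 && cfg$maf <= 0.5, "maf must be in [0, 0.5]")
  chk(cfg$delta_af >= 0 && cfg$delta_af <= 1, "delta_af must be in [0, 1]")
  chk(cfg$fst_top > 0 && cfg$fst_top < 1, "fst_top must be in (0, 1)")
  chk(cfg$tail > 0 && cfg$tail < 0.5, "tail must be in (0, 0.5)")
  chk(cfg$min_snps >= 0, "min_snps must be >= 0")
  chk(cfg$n_sim >= 1, "n_sim must be >= 1")
  needs_seed <- !is.null(cfg$simulate) || TRUE   # permutations always run
  chk(!needs_seed || (length(cfg$seed) == 1 && is.finite(cfg$seed)),
      "seed is required")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

pipeline_version <- function() {
  as.character(utils::packageVersion("sweepcis"))
}

write_tsv_prov <- function(df, path, cfg, stage, extra = character(0)) {
  hdr <- c(paste0("# sweepcis ", pipeline_version()),
           paste0("# stage ", stage),
           paste0("# seed ", cfg$seed),
           if (length(extra)) paste0("# ", names(extra), " ", unname(extra)))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

fixture_inputs <- function(dir) {
  list(genome_fa = file.path(dir, "genome.fa"),
       gff = file.path(dir, "genes.gff3"),
       vcf = file.path(dir, "variants.vcf"),
       samples = file.path(dir, "samples.tsv"),
       repeats_bed = file.path(dir, "repeats.bed"),
       expression = file.path(dir, "expression.tsv"),
       peaks = file.path(dir, "peaks.tsv"),
       truth = file.path(dir, "truth.json"))
}

load_shared <- function(cfg) {
  inp <- cfg$inputs
  need <- c("genome_fa", "gff", "vcf", "samples")
  miss <- need[!vapply(need, function(k)
    !is.null(inp[[k]]) && file.exists(inp[[k]]), logical(1))]
  if (length(miss)) stop("missing input(s): ", paste(miss, collapse = ", "))
  genome <- Biostrings::readDNAStringSet(inp$genome_fa)
  names(genome) <- sub("\\s.*", "", names(genome))
  layout <- genome_layout(stats::setNames(Biostrings::width(genome),
                                          names(genome)))
  sm <- read_sample_map(inp$samples)
  vt <- read_vcf(inp$vcf, sample_map = sm)
  gm <- read_gff_genes(inp$gff)
  repeats <- if (!is.null(inp$repeats_bed) && file.exists(inp$repeats_bed) &&
                 file.size(inp$repeats_bed) > 0)
    read_intervals(inp$repeats_bed, layout, merge = TRUE)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  list(genome = genome, layout = layout, sm = sm, vt = vt, gm = gm,
       repeats = repeats)
}

#' Pipeline stage commands
#'
#' Each stage reads its inputs (files from `config$inputs`, plus the
#' outputs of earlier stages under `config$outdir`), applies the
#' configured thresholds, and writes plain-text outputs with a provenance
#' header.  Given identical inputs and seed, every stage is
#' byte-deterministic.  `run_all()` runs simulate (when configured), scan,
#' annotate, enrich and integrate in sequence and is equivalent to running
#' the stage commands one by one.
#'
#' @param config A [run_config()] (or list/YAML path coerced through it).
#' @return The output directory, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  cfg <- run_config(unclass(config))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  args <- cfg$simulate
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- cfg$seed
  study <- simulate_study(do.call(sim_config, args))
  fixdir <- file.path(cfg$outdir, "fixture")
  write_fixture(study, fixdir, overwrite = TRUE)
  invisible(cfg$outdir)
}

resolve_inputs <- function(cfg) {
  fixdir <- file.path(cfg$outdir, "fixture")
  if (!is.null(cfg$simulate) && dir.exists(fixdir))
    cfg$inputs <- utils::modifyList(fixture_inputs(fixdir), cfg$inputs)
  cfg
}

#' @rdname pipeline
#' @export
run_scan <- function(config) {
  cfg <- resolve_inputs(run_config(unclass(config)))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sh <- load_shared(cfg)
  pops <- population_labels(sh$sm)

  sf <- site_frequencies(sh$vt, sh$sm)
  sf <- maf_filter(sf, cfg$maf)
  windows <- make_windows(sh$layout, cfg$window_size, cfg$window_step)
  ws <- window_stats(sf, windows, min_snps = cfg$min_snps)
  cuts <- compute_cutoffs(ws, fst_top = cfg$fst_top, tail = cfg$tail)
  called <- call_windows(ws, cuts)
  regions <- merge_regions(called)
  sel <- genes_in_regions(regions, sh$gm)
  frac <- region_genome_fraction(regions, sh$layout)
  ld <- ld_decay(sh$vt, max_dist = cfg$ld_max_dist, bin = cfg$ld_bin,
                 max_sites = cfg$ld_max_sites)

  prov <- c(populations = paste(pops, collapse = "/"),
            ratio_orientation = paste0("pi_", pops[1], "/pi_", pops[2]),
            window = paste0(cfg$window_size, "/", cfg$window_step),
            min_snps = cfg$min_snps, maf = cfg$maf,
            fst_top = cfg$fst_top, tail = cfg$tail,
            region_bp = frac$bp,
            region_fraction = signif(frac$fraction, 6))
  out <- function(f) file.path(cfg$outdir, f)
  write_tsv_prov(as.data.frame(called), out("windows.tsv"), cfg, "scan", prov)
  bed <- regions
  bed$name <- paste0(bed$population, ";", bed$rules)
  writeLines(c(sprintf("%s\t%d\t%d\t%s", bed$chrom, as.integer(bed$start),
                       as.integer(bed$end), bed$name)),
             out("sweep_regions.bed"))
  write_tsv_prov(sel, out("selected_genes.tsv"), cfg, "scan", prov)
  write_tsv_prov(ld, out("ld_decay.tsv"), cfg, "scan")
  invisible(cfg$outdir)
}

read_sweep_regions <- function(path) {
  if (file.size(path) == 0)
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), population = character(0),
                                rules = character(0)),
                     class = c("sweep_regions", "data.frame")))
  df <- read_intervals(path)
  parts <- strsplit(df$name, ";", fixed = TRUE)
  df$population <- vapply(parts, `[`, character(1), 1)
  df$rules <- vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                     character(1))
  df$name <- NULL
  class(df) <- c("sweep_regions", "data.frame")
  df
}

#' @rdname pipeline
#' @export
run_annotate <- function(config) {
  cfg <- resolve_inputs(run_config(unclass(config)))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sh <- load_shared(cfg)
  index <- build_feature_index(sh$gm, sh$layout,
                               promoter_up = cfg$promoter_up,
                               promoter_down = cfg$promoter_down,
                               splice_bp = cfg$splice_bp)
  ann <- classify_variants(sh$vt$variants, index, sh$genome)
  sf <- site_frequencies(sh$vt, sh$sm)
  ann$delta_af <- ifelse(sf$ok, abs(sf$p1 - sf$p2), NA_real_)
  ann$is_hd <- !is.na(ann$delta_af) & ann$delta_af >= cfg$delta_af
  write_tsv_prov(ann, file.path(cfg$outdir, "annotations.tsv"), cfg,
                 "annotate",
                 c(promoter = paste0(cfg$promoter_up, "/", cfg$promoter_down),
                   splice_bp = cfg$splice_bp, delta_af = cfg$delta_af))
  invisible(cfg$outdir)
}

#' @rdname pipeline
#' @export
run_enrich <- function(config) {
  cfg <- resolve_inputs(run_config(unclass(config)))
  out <- function(f) file.path(cfg$outdir, f)
  sh <- load_shared(cfg)
  ann <- read_tsv(out("annotations.tsv"))
  regions <- read_sweep_regions(out("sweep_regions.bed"))
  index <- build_feature_index(sh$gm, sh$layout,
                               promoter_up = cfg$promoter_up,
                               promoter_down = cfg$promoter_down,
                               splice_bp = cfg$splice_bp)

  hd <- ann[ann$is_hd, , drop = FALSE]
  hd_fc <- hd[hd$is_functional_coding, , drop = FALSE]
  kept_regions <- exclude_near_coding(regions, hd_fc, cfg$exclude_flank)
  in_kept <- overlaps_points(hd, kept_regions)
  queries <- hd[in_kept, c("chrom", "pos")]

  results <- list()
  add <- function(analysis_id, tissue, res) {
    results[[length(results) + 1]] <<- data.frame(
      analysis_id = analysis_id, tissue = tissue, obs = res$obs,
      rand = res$rand, fold = res$fold,
      log2fold = ifelse(!is.na(res$fold) && res$fold > 0, log2(res$fold), NA),
      p_enrich = res$p_enrich, p_deplete = res$p_deplete,
      n_sim = res$n_sim, seed = res$seed, stringsAsFactors = FALSE)
  }

  expr <- peaks <- NULL
  if (!is.null(cfg$inputs$expression) && file.exists(cfg$inputs$expression))
    expr <- read_expression(cfg$inputs$expression)
  if (!is.null(cfg$inputs$peaks) && file.exists(cfg$inputs$peaks))
    peaks <- read_peaks(cfg$inputs$peaks, sh$layout)

  aid <- 0
  if (!is.null(expr) && nrow(queries)) {
    for (t in unique(expr$tissue)) {
      aid <- aid + 1
      degs <- unique(expr$gene_id[expr$tissue == t & expr$is_deg])
      tgt <- promoter_intervals(index, degs)
      if (!nrow(tgt)) next
      add(paste0("deg_promoters_", t), t,
          permutation_interval_test(queries, tgt, sh$layout, sh$repeats,
                                    n_sim = cfg$n_sim, seed = cfg$seed + aid))
    }
    aid <- aid + 1
    add("all_promoters_baseline", NA,
        permutation_interval_test(queries, promoter_intervals(index),
                                  sh$layout, sh$repeats,
                                  n_sim = cfg$n_sim, seed = cfg$seed + aid))
  }
  if (!is.null(peaks) && nrow(queries)) {
    prom <- promoter_intervals(index)
    for (t in unique(peaks$tissue)) {
      aid <- aid + 1
      pk <- peaks[peaks$tissue == t & peaks$is_diff, , drop = FALSE]
      if (nrow(pk) && nrow(prom))
        pk <- pk[!IRanges::overlapsAny(gr_from_df(pk), gr_from_df(prom)), ,
                 drop = FALSE]
      if (!nrow(pk)) next
      add(paste0("diff_peaks_", t), t,
          permutation_interval_test(queries, pk[, c("chrom", "start", "end")],
                                    sh$layout, sh$repeats,
                                    n_sim = cfg$n_sim, seed = cfg$seed + aid))
    }
  }
  ## CDS depletion of all SNPs
  aid <- aid + 1
  cds <- normalize_intervals(data.frame(
    chrom = sh$gm$genes$chrom[match(sh$gm$cds$gene_id, sh$gm$genes$gene_id)],
    start = sh$gm$cds$start, end = sh$gm$cds$end), sh$layout, merge = TRUE)
  snps <- ann[ann$vclass == "snp", c("chrom", "pos")]
  add("cds_all_snps", NA,
      permutation_interval_test(snps, cds, sh$layout, sh$repeats,
                                n_sim = cfg$n_sim, seed = cfg$seed + aid))

  enr <- do.call(rbind, results)
  write_tsv_prov(enr, out("enrichment.tsv"), cfg, "enrich",
                 c(n_sim = cfg$n_sim, exclude_flank = cfg$exclude_flank,
                   n_queries = nrow(queries)))

  ## QTL/GWAS gene-set tests when interval inputs are provided
  gs <- NULL
  sel <- read_tsv(out("selected_genes.tsv"))
  universe <- sh$gm$genes$gene_id
  trait_sets <- list()
  if (!is.null(cfg$inputs$qtl_bed) && file.exists(cfg$inputs$qtl_bed)) {
    qtl <- read_intervals(cfg$inputs$qtl_bed, sh$layout)
    if (is.null(qtl$name)) qtl$name <- "qtl"
    for (tr in unique(qtl$name))
      trait_sets[[paste0("qtl:", tr)]] <-
        qtl_gene_set(sh$gm, qtl[qtl$name == tr, , drop = FALSE])
  }
  if (!is.null(cfg$inputs$gwas_tsv) && file.exists(cfg$inputs$gwas_tsv)) {
    gw <- read_tsv(cfg$inputs$gwas_tsv)   # trait, chrom, pos
    for (tr in unique(gw$trait))
      trait_sets[[paste0("gwas:", tr)]] <-
        gwas_gene_set(sh$gm, gw[gw$trait == tr, , drop = FALSE],
                      layout = sh$layout)
  }
  if (length(trait_sets)) {
    gs <- gene_set_tests(trait_sets, unique(sel$gene_id), universe)
    write_tsv_prov(gs, out("geneset_tests.tsv"), cfg, "enrich")
  }
  invisible(cfg$outdir)
}

overlaps_points <- function(points, intervals) {
  if (nrow(points) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(points)))
  IRanges::overlapsAny(
    gr_from_df(data.frame(chrom = points$chrom, start = points$pos,
                          end = points$pos + 1)),
    gr_from_df(intervals))
}

#' @rdname pipeline
#' @export
run_integrate <- function(config) {
  cfg <- resolve_inputs(run_config(unclass(config)))
  out <- function(f) file.path(cfg$outdir, f)
  sh <- load_shared(cfg)
  ann <- read_tsv(out("annotations.tsv"))
  regions <- read_sweep_regions(out("sweep_regions.bed"))
  sel <- read_tsv(out("selected_genes.tsv"))
  index <- build_feature_index(sh$gm, sh$layout,
                               promoter_up = cfg$promoter_up,
                               promoter_down = cfg$promoter_down,
                               splice_bp = cfg$splice_bp)

  hd <- ann[ann$is_hd, , drop = FALSE]
  hd_sweep <- hd[overlaps_points(hd, regions), , drop = FALSE]

  cats <- categorize_selected_genes(sel, hd_sweep, sh$gm)

  plinks <- list(); dlinks <- list()
  if (!is.null(cfg$inputs$expression) && file.exists(cfg$inputs$expression)) {
    expr <- read_expression(cfg$inputs$expression)
    peaks <- if (!is.null(cfg$inputs$peaks) && file.exists(cfg$inputs$peaks))
      read_peaks(cfg$inputs$peaks, sh$layout) else NULL
    for (t in unique(expr$tissue)) {
      plinks[[t]] <- deg_promoter_links(expr, hd_sweep, index, t)
      if (!is.null(peaks) && t %in% peaks$tissue)
        dlinks[[t]] <- deg_distal_links(expr, peaks, regions,
                                        hd_sweep[, c("chrom", "pos")],
                                        sh$gm, index, t,
                                        max_dist = cfg$link_dist)
    }
  }
  links <- do.call(rbind, c(
    lapply(plinks, function(x) { x$kind <- "promoter"; names(x)[2:4] <-
      c("n_deg", "n_linked", "prop_linked"); x }),
    lapply(dlinks, function(x) { x$kind <- "distal"; names(x)[2:4] <-
      c("n_deg", "n_linked", "prop_linked"); x })))
  if (is.null(links))
    links <- data.frame(tissue = character(0), n_deg = integer(0),
                        n_linked = integer(0), prop_linked = numeric(0),
                        kind = character(0))
  rownames(links) <- NULL

  report <- candidate_report(cats, plinks, dlinks, hd_sweep)

  write_tsv_prov(cats$genes, out("gene_categories.tsv"), cfg, "integrate")
  write_tsv_prov(cats$proportions, out("gene_category_proportions.tsv"),
                 cfg, "integrate")
  write_tsv_prov(links, out("tissue_links.tsv"), cfg, "integrate",
                 c(link_dist = cfg$link_dist))
  write_tsv_prov(report, out("candidates.tsv"), cfg, "integrate")
  invisible(cfg$outdir)
}

#' @rdname pipeline
#' @export
run_all <- function(config) {
  cfg <- run_config(if (is.character(config)) config else unclass(config))
  if (!is.null(cfg$simulate)) run_simulate(cfg)
  run_scan(cfg)
  run_annotate(cfg)
  run_enrich(cfg)
  run_integrate(cfg)
  invisible(cfg$outdir)
}
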