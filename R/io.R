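#' Read a VCF of biallelic variants into a variant table
#'
#' Parses a VCF 4.x file (plain or gzipped) via \pkg{vcfR} and returns the
#' package's internal variant table: a record data.frame plus a sites x
#' samples genotype-dosage matrix (0/1/2 alternate-allele copies, `NA` for
#' missing).  Positions are converted to 0-based.  Multiallelic rows are
#' either split into one biallelic record per alternate allele (genotypes
#' carrying a different alternate allele are set to missing) or rejected,
#' depending on `multiallelic`.
#'
#' @param path Path to a VCF file.
#' @param sample_map Optional sample map (see [read_sample_map()]); when
#'   given, every sample named in the map must be present in the VCF and
#'   genotype columns are restricted to (and ordered as) the map.
#' @param multiallelic `"split"` (default) or `"reject"`.
#' @return An object of class `variant_table`: a list with
#'   `variants` (data.frame: `chrom`, `pos`, `ref`, `alt`, `vclass`),
#'   `geno` (numeric matrix, sites x samples), and `layout` (a
#'   [genome_layout()] built from `##contig` header lines, or `NULL`).
#' @export
read_vcf <- function(path, sample_map = NULL,
                     multiallelic = c("split", "reject")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))

  layout <- layout_from_vcf_meta(vcf@meta)

  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"]) - 1
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "reject")
    stop("multiallelic record at ", chrom[which(multi)[1]], ":",
         pos[which(multi)[1]] + 1)

  dose <- gt_to_dosage(gt)

  if (any(multi)) {
    keep <- !multi
    rows <- list(data.frame(chrom = chrom[keep], pos = pos[keep],
                            ref = ref[keep], alt = alt[keep],
                            stringsAsFactors = FALSE))
    doses <- list(dose[keep, , drop = FALSE])
    for (i in which(multi)) {
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      gts <- gt[i, ]
      for (k in seq_along(alts)) {
        d <- dosage_for_allele(gts, k)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[k],
          stringsAsFactors = FALSE)
        doses[[length(doses) + 1L]] <- matrix(d, nrow = 1)
      }
    }
    variants <- do.call(rbind, rows)
    dose <- do.call(rbind, doses)
    colnames(dose) <- colnames(gt)
    ord <- order(match(variants$chrom, unique(chrom)), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    dose <- dose[ord, , drop = FALSE]
  } else {
    variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
  }

  if (any(variants$ref == variants$alt)) stop("record with REF == ALT")
  variants$vclass <- ifelse(nchar(variants$ref) == 1 & nchar(variants$alt) == 1,
                            "snp", "indel")
  rownames(variants) <- NULL

  if (!is.null(sample_map)) {
    missing <- setdiff(sample_map$sample, colnames(dose))
    if (length(missing))
      stop("sample(s) in map absent from VCF: ", paste(missing, collapse = ", "))
    dose <- dose[, sample_map$sample, drop = FALSE]
  }

  if (!is.null(layout)) {
    if (length(setdiff(unique(variants$chrom), layout$chrom)))
      stop("contig absent from VCF header: ",
           paste(setdiff(unique(variants$chrom), layout$chrom), collapse = ", "))
    if (any(variants$pos >= chrom_length(layout, variants$chrom)))
      stop("variant position beyond contig length")
  }

  structure(list(variants = variants, geno = dose, layout = layout),
            class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$variants), "record(s),",
      ncol(x$geno), "sample(s);",
      sum(x$variants$vclass == "snp"), "SNP(s),",
      sum(x$variants$vclass == "indel"), "indel(s)\n")
  invisible(x)
}

layout_from_vcf_meta <- function(meta) {
  contig <- grep("^##contig=", meta, value = TRUE)
  if (!length(contig)) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
  has_len <- grepl("length=", contig)
  if (!all(has_len)) return(NULL)
  lens <- as.numeric(sub('.*length=([0-9]+).*', "\\1", contig))
  genome_layout(stats::setNames(lens, ids))
}

## GT strings -> alt-dosage.  Accepts "/" or "|" separators; any allele call
## that is not 0/1 and any missing allele renders the genotype missing for
## biallelic rows (half-calls are treated as missing: the caller's chain is
## not specified, so we take the conservative policy).
gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean == "0/0"] <- 0
  d[clean == "0/1" | clean == "1/0"] <- 1
  d[clean == "1/1"] <- 2
  bad <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.",
                                        ".", "./0", "0/.", "./1", "1/."))
  if (any(bad)) {
    ok <- grepl("^[0-9.]+/[0-9.]+$", clean[bad])
    if (!all(ok)) stop("malformed GT field: ", clean[bad][!ok][1])
  }
  d
}

## Dosage of the k-th alternate allele for a multiallelic row; genotypes
## carrying any other non-reference allele become missing.
dosage_for_allele <- function(gts, k) {
  vapply(gts, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(al == ".")) return(NA_real_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || length(al) != 2) return(NA_real_)
    if (any(al != 0 & al != k)) return(NA_real_)
    sum(al == k)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS features and keeps, for each gene, the
#' transcript with the longest total CDS.  Coordinates are converted to
#' 0-based half-open.  The TSS is the 5'-most position of the retained
#' transcript on its strand: the transcript start (0-based) on `+`, the
#' half-open transcript end on `-`.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gene_models`: a list of data.frames
#'   `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `transcript_id`), `exons` (`gene_id`, `start`, `end`) and
#'   `cds` (`gene_id`, `start`, `end`, `phase`).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  getid <- function(x) as.character(x)
  parent1 <- vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                    character(1))

  mrna <- gr[type == "mRNA"]
  mrna_parent <- parent1[type == "mRNA"]
  mrna_id <- getid(mrna$ID)
  cds <- gr[type == "CDS"]
  cds_parent <- parent1[type == "CDS"]
  exon <- gr[type == "exon"]
  exon_parent <- parent1[type == "exon"]
  if (anyNA(cds_parent)) stop("CDS feature without parent mRNA")

  ## pick longest-CDS transcript per gene
  cds_len <- tapply(GenomicRanges::width(cds), cds_parent, sum)
  keep_tx <- character(0)
  for (g in unique(mrna_parent)) {
    tx <- mrna_id[mrna_parent == g]
    tx <- tx[tx %in% names(cds_len)]
    if (!length(tx)) next
    keep_tx[g] <- tx[which.max(cds_len[tx])]
  }
  if (!length(keep_tx)) stop("no coding transcripts in ", path)

  genes <- do.call(rbind, lapply(names(keep_tx), function(g) {
    tx <- keep_tx[[g]]
    m <- mrna[mrna_id == tx]
    strand <- as.character(GenomicRanges::strand(m))
    start0 <- GenomicRanges::start(m) - 1
    end0 <- GenomicRanges::end(m)
    data.frame(gene_id = g, chrom = as.character(GenomicRanges::seqnames(m)),
               strand = strand, start = start0, end = end0,
               tss = if (strand == "+") start0 else end0,
               transcript_id = tx, stringsAsFactors = FALSE)
  }))

  tx_of <- stats::setNames(names(keep_tx), keep_tx)
  sel_cds <- cds_parent %in% names(tx_of)
  cds_df <- data.frame(
    gene_id = unname(tx_of[cds_parent[sel_cds]]),
    start = GenomicRanges::start(cds)[sel_cds] - 1,
    end = GenomicRanges::end(cds)[sel_cds],
    phase = as_phase(cds$phase[sel_cds]),
    stringsAsFactors = FALSE)
  sel_ex <- exon_parent %in% names(tx_of)
  exon_df <- data.frame(
    gene_id = unname(tx_of[exon_parent[sel_ex]]),
    start = GenomicRanges::start(exon)[sel_ex] - 1,
    end = GenomicRanges::end(exon)[sel_ex],
    stringsAsFactors = FALSE)

  ord <- function(d) { d <- d[order(d$gene_id, d$start), , drop = FALSE]; rownames(d) <- NULL; d }
  cds_df <- ord(cds_df); exon_df <- ord(exon_df)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  bad_len <- tapply(cds_df$end - cds_df$start, cds_df$gene_id, sum) %% 3 != 0
  if (any(bad_len))
    warning("CDS length not a multiple of 3 for gene(s): ",
            paste(names(bad_len)[bad_len], collapse = ", "))

  structure(list(genes = genes, exons = exon_df, cds = cds_df),
            class = "gene_models")
}

as_phase <- function(p) {
  p <- suppressWarnings(as.integer(as.character(p)))
  p[is.na(p)] <- 0L
  p
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "gene(s) on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read and write BED interval sets
#'
#' BED3+ files are read into the internal 0-based half-open interval
#' data.frame; `write_intervals()` is the exact inverse on normalized input.
#'
#' @param path Path to a BED file.
#' @param layout Optional [genome_layout()] for validation.
#' @param merge Merge overlapping/bookended intervals after reading.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`.
#' @export
read_intervals <- function(path, layout = NULL, merge = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) <= 0))
    stop("empty interval (start >= end) in ", path)
  df <- df_from_gr(gr)
  if (!is.null(gr$name) && !all(is.na(gr$name))) df$name <- gr$name
  normalize_intervals(df, layout = layout, merge = merge)
}

#' @rdname read_intervals
#' @param intervals Interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`).
#' @export
write_intervals <- function(intervals, path) {
  intervals <- normalize_intervals(intervals)
  gr <- gr_from_df(intervals)
  if (!is.null(intervals$name)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated file with header columns `sample` and `population`.
#'
#' @param path Path to the TSV.
#' @return A data.frame (`sample`, `population`) of class `sample_map`;
#'   population order (pop1 first) follows first appearance in the file.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(df)))
    stop("sample map requires columns 'sample' and 'population'")
  if (anyDuplicated(df$sample))
    stop("duplicate sample: ", df$sample[duplicated(df$sample)][1])
  as_sample_map(df$sample, df$population)
}

#' @rdname read_sample_map
#' @param sample,population Character vectors of equal length.
#' @export
as_sample_map <- function(sample, population) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  tab <- table(df$population)
  if (any(tab < 2))
    stop("each population needs >= 2 samples; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  class(df) <- c("sample_map", "data.frame")
  df
}

population_labels <- function(sample_map) unique(sample_map$population)

#' Read an expression table with DEG flags
#'
#' Tab-separated file with header columns `gene_id`, `tissue`, `log2fc`,
#' `fdr` and optionally `is_deg`.  When `is_deg` is absent it is recomputed
#' from the thresholds `fdr <= fdr_max` and `|log2fc| >= lfc_min`.
#'
#' @param path Path to the TSV.
#' @param fdr_max,lfc_min DEG thresholds used when the flag is absent.
#' @return A data.frame with a logical `is_deg` column.
#' @export
read_expression <- function(path, fdr_max = 0.05, lfc_min = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("expression table requires columns: ", paste(need, collapse = ", "))
  if (any(df$fdr < 0 | df$fdr > 1)) stop("fdr outside [0, 1]")
  if (!"is_deg" %in% names(df))
    df$is_deg <- df$fdr <= fdr_max & abs(df$log2fc) >= lfc_min
  df$is_deg <- as.logical(df$is_deg)
  df
}

#' Read an ATAC peak table
#'
#' Tab-separated file with header columns `chrom`, `start`, `end`,
#' `tissue`, `is_diff` and optionally `fdr` (0-based half-open intervals).
#'
#' @param path Path to the TSV.
#' @param layout Optional [genome_layout()] for validation.
#' @return A data.frame with a logical `is_diff` column.
#' @export
read_peaks <- function(path, layout = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "tissue", "is_diff")
  if (!all(need %in% names(df)))
    stop("peak table requires columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start)) stop("peak with end <= start")
  if (!is.null(layout)) {
    bad <- setdiff(unique(df$chrom), layout$chrom)
    if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
    if (any(df$end > chrom_length(layout, df$chrom)))
      stop("peak extends past chromosome end")
  }
  df$is_diff <- as.logical(df$is_diff)
  df
}
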