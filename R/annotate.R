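FUNCTIONAL_CODING_CATEGORIES <- c("cds_missense", "cds_stop_gain",
                                  "cds_stop_loss", "cds_frameshift",
                                  "splice_site")
PTV_CATEGORIES <- c("cds_frameshift", "cds_stop_gain")

#' Build a genomic feature index from gene models
#'
#' Precomputes per-category interval sets with gene back-references: CDS,
#' splice sites (the first and last `splice_bp` intronic bases of every
#' intron), 5'/3' UTRs (exon minus CDS, split by strand), promoters
#' (`[tss - up, tss + down)` on the coding strand, clipped to the
#' chromosome) and introns.
#'
#' @param gene_models A `gene_models` object.
#' @param layout A [genome_layout()].
#' @param promoter_up,promoter_down Promoter span upstream/downstream of
#'   the TSS in bp (defaults 2000 and 200).
#' @param splice_bp Intronic bases flanking each exon-intron junction that
#'   count as splice site (default 2).
#' @return An object of class `feature_index`: a list of interval
#'   data.frames (`chrom`, `start`, `end`, `gene_id`) per category, in
#'   classification priority order, plus the parameters used.
#' @export
build_feature_index <- function(gene_models, layout,
                                promoter_up = 2000, promoter_down = 200,
                                splice_bp = 2) {
  genes <- gene_models$genes
  if (any(genes$tss < 0 | genes$tss > chrom_length(layout, genes$chrom)))
    stop("TSS outside chromosome bounds")

  exl <- split(IRanges::IRanges(gene_models$exons$start + 1,
                                gene_models$exons$end),
               gene_models$exons$gene_id)
  cdl <- split(IRanges::IRanges(gene_models$cds$start + 1,
                                gene_models$cds$end),
               gene_models$cds$gene_id)
  gid <- genes$gene_id
  span <- IRanges::IRanges(genes$start + 1, genes$end)

  introns <- list(); utr5 <- list(); utr3 <- list(); splice <- list()
  for (i in seq_along(gid)) {
    g <- gid[i]
    ex <- IRanges::reduce(exl[[g]])
    cd <- if (g %in% names(cdl)) IRanges::reduce(cdl[[g]]) else IRanges::IRanges()
    intr <- IRanges::setdiff(span[i], ex)
    utr <- IRanges::setdiff(ex, cd)
    mk <- function(ir) if (length(ir))
      data.frame(chrom = genes$chrom[i],
                 start = IRanges::start(ir) - 1, end = IRanges::end(ir),
                 gene_id = g, stringsAsFactors = FALSE)
    introns[[i]] <- mk(intr)
    if (length(utr) && length(cd)) {
      cds_lo <- min(IRanges::start(cd)); cds_hi <- max(IRanges::end(cd))
      before <- IRanges::end(utr) < cds_lo
      after <- IRanges::start(utr) > cds_hi
      if (genes$strand[i] == "+") {
        utr5[[i]] <- mk(utr[before]); utr3[[i]] <- mk(utr[after])
      } else {
        utr5[[i]] <- mk(utr[after]); utr3[[i]] <- mk(utr[before])
      }
    }
    if (length(intr) && splice_bp > 0) {
      s <- IRanges::start(intr); e <- IRanges::end(intr)
      left <- IRanges::IRanges(s, pmin(s + splice_bp - 1, e))
      right <- IRanges::IRanges(pmax(e - splice_bp + 1, s), e)
      sp <- IRanges::reduce(c(left, right))
      splice[[i]] <- data.frame(chrom = genes$chrom[i],
                                start = IRanges::start(sp) - 1,
                                end = IRanges::end(sp),
                                gene_id = g, stringsAsFactors = FALSE)
    }
  }
  bindl <- function(l) {
    l <- Filter(Negate(is.null), l)
    if (!length(l)) data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), gene_id = character(0))
    else do.call(rbind, l)
  }

  up <- ifelse(genes$strand == "+", promoter_up, promoter_down)
  dn <- ifelse(genes$strand == "+", promoter_down, promoter_up)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - up),
                     end = pmin(chrom_length(layout, genes$chrom),
                                genes$tss + dn),
                     gene_id = gid, stringsAsFactors = FALSE)
  prom <- prom[prom$end > prom$start, , drop = FALSE]

  cds_df <- gene_models$cds[, c("start", "end")]
  cds_df <- data.frame(chrom = genes$chrom[match(gene_models$cds$gene_id, gid)],
                       cds_df, gene_id = gene_models$cds$gene_id,
                       stringsAsFactors = FALSE)

  structure(list(
    cds = cds_df,
    splice_site = bindl(splice),
    utr5 = bindl(utr5),
    utr3 = bindl(utr3),
    promoter = prom,
    intron = bindl(introns),
    params = list(promoter_up = promoter_up, promoter_down = promoter_down,
                  splice_bp = splice_bp),
    gene_models = gene_models,
    layout = layout
  ), class = "feature_index")
}

#' Promoter intervals of a gene set
#'
#' @param index A `feature_index`.
#' @param gene_ids Optional character vector restricting the genes.
#' @return Interval data.frame (`chrom`, `start`, `end`, `gene_id`).
#' @export
promoter_intervals <- function(index, gene_ids = NULL) {
  p <- index$promoter
  if (!is.null(gene_ids)) p <- p[p$gene_id %in% gene_ids, , drop = FALSE]
  rownames(p) <- NULL
  p
}

## Affected genomic span of a variant, 0-based half-open.  For indels the
## shared leading base(s) of REF/ALT are stripped so the span starts at the
## first changed base; pure insertions are represented by the single base
## after the insertion point.
variant_spans <- function(variants) {
  ref <- variants$ref; alt <- variants$alt
  cp <- integer(nrow(variants))
  ind <- variants$vclass == "indel"
  if (any(ind)) {
    cp[ind] <- vapply(which(ind), function(i) {
      a <- ref[i]; b <- alt[i]
      k <- 0L
      while (k < nchar(a) && k < nchar(b) &&
             substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1L
      k
    }, integer(1))
  }
  start <- variants$pos + cp
  width <- pmax(nchar(ref) - cp, 1L)
  data.frame(chrom = variants$chrom, start = start, end = start + width)
}

#' Classify variants by genomic feature and coding consequence
#'
#' Assigns every variant exactly one category by feature precedence
#' (CDS > splice site > UTR5/UTR3 > promoter > intron > intergenic) and
#' refines CDS hits into a coding consequence using the reference sequence
#' (see [coding_consequence()]).  A variant hitting the CDS of one gene and
#' the promoter of another is assigned to the CDS gene.
#'
#' @param variants Variant data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `vclass`), e.g. `vt$variants`.
#' @param index A `feature_index`.
#' @param genome A [Biostrings::DNAStringSet] of the reference chromosomes
#'   (names matching the layout).
#' @return The variant data.frame with added columns `category`,
#'   `gene_id` (`NA` for intergenic), `is_functional_coding`, `is_ptv`.
#' @export
classify_variants <- function(variants, index, genome) {
  n <- nrow(variants)
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  spans <- variant_spans(variants)
  qgr <- gr_from_df(spans)
  for (cat in c("cds", "splice_site", "utr5", "utr3", "promoter", "intron")) {
    tbl <- index[[cat]]
    if (!nrow(tbl)) next
    hits <- GenomicRanges::findOverlaps(qgr, gr_from_df(tbl))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- is.na(category[qi])
    qi <- qi[keep]; si <- si[keep]
    if (!length(qi)) next
    ord <- order(qi, tbl$gene_id[si])
    first <- !duplicated(qi[ord])
    category[qi[ord][first]] <- cat
    gene_id[qi[ord][first]] <- tbl$gene_id[si[ord]][first]
  }
  category[is.na(category)] <- "intergenic"

  in_cds <- which(category == "cds")
  if (length(in_cds)) {
    cons <- coding_consequence(variants[in_cds, , drop = FALSE],
                               gene_id[in_cds], index$gene_models, genome)
    category[in_cds] <- cons
  }
  out <- variants
  out$category <- category
  out$gene_id <- gene_id
  out$is_functional_coding <- category %in% FUNCTIONAL_CODING_CATEGORIES
  out$is_ptv <- category %in% PTV_CATEGORIES
  out
}

#' Coding consequence of CDS-overlapping variants
#'
#' SNPs are spliced into the coding sequence of the assigned gene's
#' retained transcript (strand-aware), the affected codon is translated
#' under the standard genetic code and compared with the reference codon:
#' identical amino acid is synonymous, a gained stop is `cds_stop_gain`, a
#' lost reference stop is `cds_stop_loss`, any other change is
#' `cds_missense`.  Indels are classified by length: a REF/ALT length
#' difference not divisible by 3 is `cds_frameshift`, otherwise
#' `cds_inframe_indel`.
#'
#' @param variants Variant data.frame rows overlapping CDS.
#' @param gene_ids Character vector assigning each row to a gene.
#' @param gene_models A `gene_models` object.
#' @param genome Reference [Biostrings::DNAStringSet].
#' @return Character vector of `cds_*` categories.
#' @export
coding_consequence <- function(variants, gene_ids, gene_models, genome) {
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  ind <- variants$vclass == "indel"
  shift <- abs(nchar(variants$ref) - nchar(variants$alt))
  out[ind] <- ifelse(shift[ind] %% 3 != 0, "cds_frameshift", "cds_inframe_indel")

  snp_idx <- which(!ind)
  if (!length(snp_idx)) return(out)
  code <- Biostrings::GENETIC_CODE
  for (g in unique(gene_ids[snp_idx])) {
    rows <- snp_idx[gene_ids[snp_idx] == g]
    info <- gene_cds_info(g, gene_models, genome)
    pos <- variants$pos[rows]
    idx <- map_to_cds(pos, info)
    if (anyNA(idx)) stop("position not in CDS of ", g)
    refb <- substring(info$fwd_seq, pos_in_fwd(pos, info) + 1,
                      pos_in_fwd(pos, info) + 1)
    if (any(refb != variants$ref[rows]))
      stop("reference mismatch at ",
           paste0(variants$chrom[rows], ":", pos + 1)[refb != variants$ref[rows]][1])
    altb <- variants$alt[rows]
    if (info$strand == "-") altb <- chartr("ACGT", "TGCA", altb)
    codon_i <- idx %/% 3
    within <- idx %% 3
    ref_codon <- substring(info$cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
    alt_codon <- ref_codon
    substr(alt_codon, within + 1, within + 1) <- altb
    aa_ref <- code[ref_codon]; aa_alt <- code[alt_codon]
    out[rows] <- ifelse(aa_ref == aa_alt, "cds_synonymous",
                 ifelse(aa_alt == "*", "cds_stop_gain",
                 ifelse(aa_ref == "*", "cds_stop_loss", "cds_missense")))
  }
  out
}

## Cached-free helper: CDS structure and sequence of a gene.
## fwd_seq: concatenation of CDS intervals in genomic order (plus strand
## orientation); cds_seq: coding orientation.
gene_cds_info <- function(gene_id, gene_models, genome) {
  cd <- gene_models$cds[gene_models$cds$gene_id == gene_id, , drop = FALSE]
  if (!nrow(cd)) stop("gene without CDS: ", gene_id)
  cd <- cd[order(cd$start), , drop = FALSE]
  g <- gene_models$genes[gene_models$genes$gene_id == gene_id, ]
  chrom_seq <- genome[[g$chrom]]
  pieces <- Biostrings::extractAt(chrom_seq,
                                  IRanges::IRanges(cd$start + 1, cd$end))
  fwd <- paste0(as.character(pieces), collapse = "")
  cds_seq <- if (g$strand == "+") fwd else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  list(gene_id = gene_id, strand = g$strand, starts = cd$start, ends = cd$end,
       widths = cd$end - cd$start, total = sum(cd$end - cd$start),
       fwd_seq = fwd, cds_seq = cds_seq)
}

## Forward (genomic-order) CDS index of genomic positions; NA when outside.
pos_in_fwd <- function(pos, info) {
  cum <- c(0, cumsum(info$widths))
  out <- rep(NA_real_, length(pos))
  for (k in seq_along(info$starts)) {
    inside <- pos >= info$starts[k] & pos < info$ends[k]
    out[inside] <- cum[k] + (pos[inside] - info$starts[k])
  }
  out
}

## Coding-order CDS index (0-based).
map_to_cds <- function(pos, info) {
  f <- pos_in_fwd(pos, info)
  if (info$strand == "+") f else info$total - 1 - f
}

#' Functional-coding and protein-truncating variant subsets
#'
#' Functional coding variants are missense, stop gain, stop loss,
#' frameshift and splice-site variants; protein-truncating variants (PTV)
#' are frameshift and stop gain.
#'
#' @param annotations Output of [classify_variants()].
#' @return The subset of annotation rows.
#' @export
functional_coding_set <- function(annotations) {
  out <- annotations[annotations$is_functional_coding, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname functional_coding_set
#' @export
ptv_set <- function(annotations) {
  out <- annotations[annotations$is_ptv, , drop = FALSE]
  rownames(out) <- NULL
  out
}
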