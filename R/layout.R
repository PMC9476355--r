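#' Genome layout
#'
#' A minimal description of the coordinate system every other object in the
#' package is validated against: an ordered set of chromosome names and their
#' lengths in base pairs.  All coordinates in the package are 0-based,
#' half-open; external formats (VCF, GFF3, BED) are converted at the I/O
#' boundary.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.  Names
#'   are the chromosome identifiers; order is preserved.
#' @return An object of class `genome_layout`: a list with `chrom`
#'   (character) and `length` (numeric) components.
#' @examples
#' gl <- genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' genome_bp(gl)
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(
    list(chrom = names(lengths), length = as.numeric(unname(lengths))),
    class = "genome_layout"
  )
}

#' @exportS3Method base::print
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp\n")
  invisible(x)
}

#' @rdname genome_layout
#' @param layout A `genome_layout`.
#' @export
genome_bp <- function(layout) sum(layout$length)

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Sliding windows over a genome
#'
#' Generates windows of `size` bp advancing by `step` bp along each
#' chromosome.  A window starts at every multiple of `step` below the
#' chromosome length; the final windows are truncated at the chromosome end,
#' so short chromosomes still receive (shortened) windows.
#'
#' @param layout A [genome_layout()].
#' @param size Window width in bp (default 50 kb).
#' @param step Step between window starts in bp (default 10 kb).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `window_id`.
#' @export
make_windows <- function(layout, size = 50000, step = 10000) {
  stopifnot(size >= step, step > 0)
  pieces <- lapply(seq_along(layout$chrom), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + size, len))
  })
  out <- do.call(rbind, pieces)
  out$window_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## Conversion between internal 0-based half-open interval data.frames and
## GRanges (1-based closed).  All overlap machinery goes through these two.
gr_from_df <- function(df, layout = NULL) {
  seqinfo <- NULL
  if (!is.null(layout)) {
    bad <- setdiff(unique(df$chrom), layout$chrom)
    if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
    seqinfo <- GenomeInfoDb::Seqinfo(layout$chrom, layout$length)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  gr
}

df_from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

## Normalize an interval data.frame: validate, order by (chrom, start, end).
normalize_intervals <- function(df, layout = NULL, merge = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(df)
  if (any(df$start >= df$end))
    stop("empty or inverted interval (start >= end)")
  if (any(df$start < 0)) stop("negative interval start")
  if (!is.null(layout)) {
    bad <- setdiff(unique(df$chrom), layout$chrom)
    if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
    if (any(df$end > chrom_length(layout, df$chrom)))
      stop("interval extends past chromosome end")
  }
  if (merge) {
    gr <- GenomicRanges::reduce(gr_from_df(df))
    df <- df_from_gr(gr)
  }
  ord <- order(match(df$chrom, unique(df$chrom)), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Complement of a (merged) interval set within the layout: the mask-free
## gaps used by the matched-interval sampler.
complement_intervals <- function(df, layout) {
  all_chr <- data.frame(chrom = layout$chrom, start = 0, end = layout$length)
  if (nrow(df) == 0) return(all_chr)
  gr <- gr_from_df(df, layout)
  gaps <- GenomicRanges::setdiff(gr_from_df(all_chr, layout),
                                 GenomicRanges::reduce(gr))
  df_from_gr(gaps)
}
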