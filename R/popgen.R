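#' Per-site allele frequencies for two populations
#'
#' Counts called alleles per population at every variant site.  Missing
#' genotypes are excluded from the allele totals; observed heterozygosity is
#' computed over called individuals only.  The minor allele frequency is
#' taken from the pooled called allele counts of both populations, not from
#' the mean of the per-population frequencies.
#'
#' @param vt A `variant_table` from [read_vcf()] or the simulator.
#' @param sample_map A sample map with exactly two population labels; the
#'   first label (by appearance) is population 1, fixing the orientation of
#'   every downstream ratio and deltaAF sign convention.
#' @return A data.frame of class `site_freq` with one row per variant:
#'   record columns plus, per population `1`/`2`: `n` (called alleles),
#'   `j` (alt-allele count), `p` (= j/n), `het` (observed heterozygote
#'   fraction); and `maf`, `ok1`, `ok2`, `ok` (both populations have at
#'   least one called diploid).  The population labels are attached as
#'   attribute `populations`.
#' @export
site_frequencies <- function(vt, sample_map) {
  pops <- population_labels(sample_map)
  if (length(pops) != 2)
    stop("exactly two populations required, got: ", paste(pops, collapse = ", "))
  miss <- setdiff(sample_map$sample, colnames(vt$geno))
  if (length(miss)) stop("sample(s) absent from genotypes: ",
                         paste(miss, collapse = ", "))
  out <- vt$variants
  for (k in 1:2) {
    g <- vt$geno[, sample_map$sample[sample_map$population == pops[k]],
                 drop = FALSE]
    ncalled <- rowSums(!is.na(g))
    j <- rowSums(g, na.rm = TRUE)
    nhet <- rowSums(g == 1, na.rm = TRUE)
    out[[paste0("n", k)]] <- 2 * ncalled
    out[[paste0("j", k)]] <- j
    out[[paste0("p", k)]] <- ifelse(ncalled > 0, j / (2 * ncalled), NA_real_)
    out[[paste0("het", k)]] <- ifelse(ncalled > 0, nhet / ncalled, NA_real_)
    out[[paste0("ok", k)]] <- ncalled >= 1
  }
  ptot <- (out$j1 + out$j2) / (out$n1 + out$n2)
  out$maf <- pmin(ptot, 1 - ptot)
  out$ok <- out$ok1 & out$ok2
  attr(out, "populations") <- pops
  class(out) <- c("site_freq", "data.frame")
  out
}

#' Minor allele frequency filter
#'
#' Retains sites with pooled MAF at or above the threshold (boundary
#' inclusive, so the default keeps MAF >= 5\%).
#'
#' @param sites A `site_freq` data.frame.
#' @param threshold Minimum pooled MAF (default 0.05).
#' @export
maf_filter <- function(sites, threshold = 0.05) {
  keep <- !is.na(sites$maf) & sites$maf >= threshold
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- attr(sites, "populations")
  class(out) <- class(sites)
  out
}

#' Allele-frequency differential between the two populations
#'
#' `delta_af()` returns |p1 - p2| per site; `is_highly_differential()`
#' flags sites whose differential reaches the threshold (boundary
#' inclusive, so deltaAF of exactly 0.9 is flagged under the default).
#'
#' @param sites A `site_freq` data.frame; every site must be computable in
#'   both populations.
#' @param threshold Flagging threshold (default 0.9).
#' @export
delta_af <- function(sites) {
  if (any(!sites$ok))
    stop("deltaAF undefined: site(s) with no called genotypes in one population")
  abs(sites$p1 - sites$p2)
}

#' @rdname delta_af
#' @export
is_highly_differential <- function(sites, threshold = 0.9) {
  delta_af(sites) >= threshold
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site pairwise diversity 2 j (n - j) / (n (n - 1)) for a
#' sample of `n` called alleles of which `j` carry the alternate allele:
#' the fraction of allele pairs that differ.
#'
#' @param n Called allele count(s).
#' @param j Alternate-allele count(s).
#' @return Numeric vector; `NA` where `n < 2`.
#' @export
site_pi <- function(n, j) {
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

#' Weir-Cockerham (1984) variance components for two populations
#'
#' Computes the between-population (`a`), between-individual (`b`) and
#' within-individual (`c`) variance components of the Weir-Cockerham
#' F-statistic estimator from per-population sample sizes, allele
#' frequencies and observed heterozygosity.  The windowed weighted
#' estimator is `sum(a) / sum(a + b + c)`.
#'
#' @param sites A `site_freq` data.frame.
#' @return A data.frame with columns `a`, `b`, `cc` and `abc`
#'   (= a + b + c); rows where either population has fewer than one called
#'   diploid are `NA`.
#' @export
wc_fst_components <- function(sites) {
  r <- 2
  n1 <- sites$n1 / 2; n2 <- sites$n2 / 2        # diploid counts
  p1 <- sites$p1; p2 <- sites$p2
  h1 <- sites$het1; h2 <- sites$het2
  nbar <- (n1 + n2) / r
  ok <- sites$ok & nbar > 1                      # n_c needs nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  data.frame(a = a, b = b, cc = cc, abc = a + b + cc)
}

#' Genome-wide weighted Weir-Cockerham F_ST
#'
#' @param sites A `site_freq` data.frame (typically SNPs after MAF
#'   filtering).
#' @return `sum(a) / sum(a + b + c)` over sites with computable components.
#' @export
weighted_fst <- function(sites) {
  comp <- wc_fst_components(sites)
  ok <- !is.na(comp$abc)
  sum(comp$a[ok]) / sum(comp$abc[ok])
}

#' Windowed population-genetic statistics
#'
#' Aggregates per-site diversity and Weir-Cockerham components into sliding
#' windows.  Only SNPs contribute.  Per-population pi is the sum of
#' per-site pi over SNPs in the window divided by the full window span in
#' bp (the per-variant normalization is available via
#' `normalize = "variant"`).  The window F_ST is the weighted ratio
#' `sum(a) / sum(a+b+c)`.  Windows with fewer than `min_snps` SNPs are
#' dropped.
#'
#' @param sites A MAF-filtered `site_freq` data.frame.
#' @param windows Window data.frame from [make_windows()].
#' @param min_snps Minimum SNPs per analyzable window (default 10).
#' @param normalize `"span"` (default; divide by window width) or
#'   `"variant"` (divide by the number of contributing SNPs).
#' @return A data.frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `n_snps`, `pi_pop1`, `pi_pop2`, `fst`, `ratio` (pi_pop1/pi_pop2; `NA`
#'   with `ratio_defined = FALSE` when pi_pop2 is 0).  Population labels
#'   are carried through as attribute `populations`.
#' @export
window_stats <- function(sites, windows, min_snps = 10,
                         normalize = c("span", "variant")) {
  normalize <- match.arg(normalize)
  snps <- sites[sites$vclass == "snp", , drop = FALSE]
  comp <- wc_fst_components(snps)
  pi1 <- site_pi(snps$n1, snps$j1)
  pi2 <- site_pi(snps$n2, snps$j2)

  size <- max(windows$end - windows$start)
  step <- min(diff(sort(unique(windows$start[windows$chrom == windows$chrom[1]]))),
              size)

  ## map each SNP to the (possibly several) overlapping windows
  assign <- site_window_pairs(snps, windows, size, step)
  si <- assign$site; wi <- assign$window

  m <- nrow(windows)
  nz <- sort(unique(wi))
  zeros <- numeric(m)
  sum_by <- function(v, na_zero = TRUE) {
    x <- v[si]
    if (na_zero) x[is.na(x)] <- 0
    out <- zeros
    out[nz] <- rowsum(x, wi)[, 1]
    out
  }
  n_snps <- sum_by(rep(1, nrow(snps)))
  s_pi1 <- sum_by(pi1)
  s_pi2 <- sum_by(pi2)
  s_a <- sum_by(comp$a)
  s_abc <- sum_by(comp$abc)
  n_pi1 <- sum_by(as.numeric(!is.na(pi1)))
  n_pi2 <- sum_by(as.numeric(!is.na(pi2)))

  span <- windows$end - windows$start
  denom1 <- if (normalize == "span") span else pmax(n_pi1, 1)
  denom2 <- if (normalize == "span") span else pmax(n_pi2, 1)
  out <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    n_snps = n_snps,
    pi_pop1 = s_pi1 / denom1,
    pi_pop2 = s_pi2 / denom2,
    fst = ifelse(s_abc != 0, s_a / s_abc, NA_real_)
  )
  out$ratio_defined <- out$pi_pop2 > 0
  out$ratio <- ifelse(out$ratio_defined, out$pi_pop1 / out$pi_pop2, NA_real_)
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- attr(sites, "populations")
  class(out) <- c("window_stats", "data.frame")
  out
}

## Expanded (site, window) index pairs for sliding windows with fixed
## size/step starting at 0 on each chromosome.
site_window_pairs <- function(snps, windows, size, step) {
  si_all <- integer(0); wi_all <- integer(0)
  for (ch in unique(windows$chrom)) {
    w <- which(windows$chrom == ch)
    s <- which(snps$chrom == ch)
    if (!length(s) || !length(w)) next
    pos <- snps$pos[s]
    lo <- pmax(0, ceiling((pos - size + 1) / step))   # first window index (0-based)
    hi <- pmin(floor(pos / step), length(w) - 1)
    cnt <- pmax(hi - lo + 1, 0)
    si <- rep(s, cnt)
    wi <- w[sequence(cnt) - 1 + rep(lo, cnt) + 1]
    si_all <- c(si_all, si); wi_all <- c(wi_all, wi)
  }
  list(site = si_all, window = wi_all)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples.
#'
#' @param gi,gj Numeric dosage vectors (0/1/2, `NA` missing).
#' @return r-squared in [0, 1], or `NA` if either site has zero variance
#'   over the complete pairs.
#' @export
ld_r2 <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2) return(NA_real_)
  v <- stats::var(gi[ok]) > 0 && stats::var(gj[ok]) > 0
  if (!v) return(NA_real_)
  stats::cor(gi[ok], gj[ok])^2
}

#' LD decay table
#'
#' Averages dosage r-squared in fixed-width physical-distance bins over all
#' SNP pairs on the same chromosome closer than `max_dist`.  Pairs where
#' either site is monomorphic over the complete samples are skipped.
#'
#' @param vt A `variant_table` (SNPs are selected internally).
#' @param max_dist Maximum pair distance in bp (default 300 kb).
#' @param bin Bin width in bp (default 100).
#' @param max_sites Optional cap on the number of SNPs per chromosome
#'   (evenly subsampled) to bound the quadratic pair cost.
#' @return A data.frame `bin_start`, `mean_r2`, `n_pairs` covering
#'   `[0, max_dist)`.
#' @export
ld_decay <- function(vt, max_dist = 300000, bin = 100, max_sites = Inf) {
  snp <- vt$variants$vclass == "snp"
  v <- vt$variants[snp, , drop = FALSE]
  g <- vt$geno[snp, , drop = FALSE]
  nb <- ceiling(max_dist / bin)
  sums <- numeric(nb); cnts <- numeric(nb)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) > max_sites)
      idx <- idx[unique(round(seq(1, length(idx), length.out = max_sites)))]
    idx <- idx[order(v$pos[idx])]
    pos <- v$pos[idx]
    gm <- g[idx, , drop = FALSE]
    obs <- !is.na(gm)
    s <- gm; s[!obs] <- 0
    M <- obs * 1
    np <- M %*% t(M)
    Sxy <- s %*% t(s)
    Sx <- s %*% t(M); Sy <- t(Sx)
    Sxx <- (s * s) %*% t(M); Syy <- t(Sxx)
    num <- np * Sxy - Sx * Sy
    den <- (np * Sxx - Sx^2) * (np * Syy - Sy^2)
    r2 <- ifelse(den > 0, num^2 / den, NA_real_)
    d <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(d) & d < max_dist & !is.na(r2)
    if (!any(sel)) next
    b <- floor(d[sel] / bin) + 1
    sums_ch <- rowsum(r2[sel], b)
    ib <- as.integer(rownames(sums_ch))
    sums[ib] <- sums[ib] + sums_ch[, 1]
    cnts_ch <- rowsum(rep(1, length(b)), b)
    cnts[ib] <- cnts[ib] + cnts_ch[, 1]
  }
  data.frame(bin_start = (seq_len(nb) - 1) * bin,
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
             n_pairs = cnts)
}
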