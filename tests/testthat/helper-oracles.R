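# Independent oracles and tiny fixture builders shared across the suite.
# Oracles deliberately use brute force / literal transcriptions so they stay
# independent of the package's vectorized implementations.

# Fraction of differing allele pairs by explicit enumeration.
pi_oracle <- function(n, j) {
  alleles <- c(rep(1, j), rep(0, n - j))
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Literal scalar transcription of the Weir & Cockerham (1984) a, b, c
# variance components for r populations (here r = 2), from diploid sample
# sizes n_i, allele frequencies p_i and observed het fractions h_i.
wc_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, cc = cc)
}

# Consequence oracle: rebuild the full mutant CDS in genomic space, extract
# and translate both proteins with Biostrings, and classify from the diff.
consequence_oracle <- function(variant, gene_id, gm, genome) {
  g <- gm$genes[gm$genes$gene_id == gene_id, ]
  cd <- gm$cds[gm$cds$gene_id == gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  chrom <- as.character(genome[[g$chrom]])
  if (variant$vclass == "indel") {
    shift <- abs(nchar(variant$ref) - nchar(variant$alt))
    return(if (shift %% 3 != 0) "cds_frameshift" else "cds_inframe_indel")
  }
  mutant <- chrom
  substr(mutant, variant$pos + 1, variant$pos + 1) <- variant$alt
  get_cds <- function(seqstr) {
    pieces <- substring(seqstr, cd$start + 1, cd$end)
    s <- paste(pieces, collapse = "")
    if (g$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(get_cds(chrom))
  p_alt <- tr(get_cds(mutant))
  if (p_ref == p_alt) return("cds_synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  aa_ref <- substr(p_ref, d, d); aa_alt <- substr(p_alt, d, d)
  if (aa_alt == "*") "cds_stop_gain"
  else if (aa_ref == "*") "cds_stop_loss"
  else "cds_missense"
}

# Small deterministic genotype table for popgen unit tests: explicit dosage
# matrix plus sample map.
toy_variant_table <- function(geno, chrom = "chr1", pos = NULL,
                              layout = genome_layout(c(chr1 = 1e6))) {
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n)
  variants <- data.frame(chrom = rep(chrom, n), pos = pos,
                         ref = rep("A", n), alt = rep("G", n),
                         vclass = rep("snp", n), stringsAsFactors = FALSE)
  colnames(geno) <- sprintf("s%d", seq_len(ncol(geno)))
  structure(list(variants = variants, geno = geno, layout = layout),
            class = "variant_table")
}

toy_sample_map <- function(n1 = 3, n2 = 3, labels = c("east", "west")) {
  sweepcis::as_sample_map(sprintf("s%d", seq_len(n1 + n2)),
                          rep(labels, c(n1, n2)))
}

# A hand-built two-gene model (one per strand) with known structure on a
# 10-kb chromosome, plus the matching genome sequence carrying valid CDS.
toy_gene_models <- function(seed = 1) {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(1000, 6000), end = c(2000, 7000),
    tss = c(1000, 7000),
    transcript_id = c("gplus.t1", "gminus.t1"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    start = c(1000, 1600, 6000, 6600),
    end = c(1300, 2000, 6300, 7000),
    stringsAsFactors = FALSE)
  # CDS: gplus transcript-order [1060,1300)+[1600,1940); lengths 240+340=580
  # -> trim 580 %% 3 = 1 -> use [1060,1300) + [1600,1939) = 240 + 339 = 579 = 3*193
  cds <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    start = c(1060, 1600, 6061, 6600),
    end = c(1300, 1939, 6300, 6940),
    stringsAsFactors = FALSE)
  cds$phase <- 0L
  gm <- structure(list(genes = genes, exons = exons, cds = cds),
                  class = "gene_models")

  set.seed(seed)
  seqchars <- sample(c("A", "C", "G", "T"), 10000, replace = TRUE)
  write_cds <- function(seqchars, gid, strand) {
    cd <- cds[cds$gene_id == gid, , drop = FALSE]
    len <- sum(cd$end - cd$start)
    stopifnot(len %% 3 == 0)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    coding <- c("ATG", sample(sense, len / 3 - 2, replace = TRUE), "TAA")
    coding <- paste(coding, collapse = "")
    fwd <- if (strand == "+") coding else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    offs <- cumsum(c(0, cd$end - cd$start))
    for (k in seq_len(nrow(cd))) {
      piece <- substring(fwd, offs[k] + 1, offs[k + 1])
      seqchars[(cd$start[k] + 1):cd$end[k]] <- strsplit(piece, "")[[1]]
    }
    seqchars
  }
  seqchars <- write_cds(seqchars, "gplus", "+")
  seqchars <- write_cds(seqchars, "gminus", "-")
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- "chr1"
  list(gm = gm, genome = genome, layout = genome_layout(c(chr1 = 10000)))
}

# Balding-Nichols two-population genotype simulator used as an independent
# route for parameter-recovery checks (kept separate from the package's
# simulator on purpose: same model, different code path).
bn_genotypes <- function(n_sites, n_per_pop, F, seed) {
  set.seed(seed)
  anc <- runif(n_sites, 0.05, 0.95)
  p1 <- rbeta(n_sites, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  p2 <- rbeta(n_sites, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  g <- cbind(matrix(rbinom(n_sites * n_per_pop, 2, p1), nrow = n_sites),
             matrix(rbinom(n_sites * n_per_pop, 2, p2), nrow = n_sites))
  colnames(g) <- c(sprintf("e%d", 1:n_per_pop), sprintf("w%d", 1:n_per_pop))
  g
}

small_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
    n_genes = 60, n_sites = 6000, n_sweeps = 4, n_planted_peaks = 8,
    tissues = c("muscle", "liver"), n_peaks_per_tissue = 60),
    list(...))
  do.call(sweepcis::sim_config, args)
}
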