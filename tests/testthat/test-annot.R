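test_that("promoters are strand-aware windows around the TSS", {
  gm <- structure(list(
    genes = data.frame(gene_id = c("p", "m"), chrom = "chr1",
                       strand = c("+", "-"), start = c(10000, 8000),
                       end = c(12000, 10000), tss = c(10000, 10000),
                       transcript_id = c("p.t1", "m.t1")),
    exons = data.frame(gene_id = c("p", "m"), start = c(10000, 8000),
                       end = c(12000, 10000)),
    cds = data.frame(gene_id = c("p", "m"), start = c(10000, 8000),
                     end = c(12000, 10000), phase = 0L)),
    class = "gene_models")
  idx <- build_feature_index(gm, genome_layout(c(chr1 = 20000)))
  pp <- idx$promoter[idx$promoter$gene_id == "p", ]
  expect_equal(c(pp$start, pp$end), c(8000, 10200))
  pm <- idx$promoter[idx$promoter$gene_id == "m", ]
  expect_equal(c(pm$start, pm$end), c(9800, 12000))
  ## clipped at chromosome bounds
  gm$genes$tss <- c(1000, 19950)
  idx2 <- build_feature_index(gm, genome_layout(c(chr1 = 20000)))
  expect_equal(idx2$promoter$start[idx2$promoter$gene_id == "p"], 0)
  expect_equal(idx2$promoter$end[idx2$promoter$gene_id == "m"], 20000)
})

test_that("splice sites are the first/last two intronic bases", {
  toy <- toy_gene_models()
  idx <- build_feature_index(toy$gm, toy$layout)
  # gplus intron is [1300, 1600)
  sp <- idx$splice_site[idx$splice_site$gene_id == "gplus", ]
  expect_equal(sp$start, c(1300, 1598))
  expect_equal(sp$end, c(1302, 1600))
  # splice sites are inside introns
  intr <- idx$intron
  gr_s <- sweepcis:::gr_from_df(sp)
  gr_i <- sweepcis:::gr_from_df(intr)
  expect_true(all(IRanges::overlapsAny(gr_s, gr_i)))
})

test_that("classification follows feature precedence and fills gene ids", {
  toy <- toy_gene_models()
  idx <- build_feature_index(toy$gm, toy$layout)
  mkv <- function(pos, ref, alt) {
    vclass <- if (nchar(ref) == 1 && nchar(alt) == 1) "snp" else "indel"
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               vclass = vclass, stringsAsFactors = FALSE)
  }
  base_at <- function(pos) substr(as.character(toy$genome[[1]]),
                                  pos + 1, pos + 1)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  # intergenic
  v <- mkv(5000, base_at(5000), other(base_at(5000)))
  ann <- classify_variants(v, idx, toy$genome)
  expect_equal(ann$category, "intergenic")
  expect_true(is.na(ann$gene_id))
  # 1 bp inside the intron from the junction -> splice_site
  v2 <- mkv(1301, base_at(1301), other(base_at(1301)))
  expect_equal(classify_variants(v2, idx, toy$genome)$category, "splice_site")
  # 3 bp into the intron -> intron
  v3 <- mkv(1303, base_at(1303), other(base_at(1303)))
  expect_equal(classify_variants(v3, idx, toy$genome)$category, "intron")
  # CDS beats the other gene's promoter when overlapping both
  ann4 <- classify_variants(mkv(1100, base_at(1100), other(base_at(1100))),
                            idx, toy$genome)
  expect_match(ann4$category, "^cds_")
  expect_equal(ann4$gene_id, "gplus")
  # UTR5 of gplus: exon bases before the CDS start
  v5 <- mkv(1020, base_at(1020), other(base_at(1020)))
  expect_equal(classify_variants(v5, idx, toy$genome)$category, "utr5")
  # promoter of the minus-strand gene sits right of its span
  v6 <- mkv(7500, base_at(7500), other(base_at(7500)))
  ann6 <- classify_variants(v6, idx, toy$genome)
  expect_equal(ann6$category, "promoter")
  expect_equal(ann6$gene_id, "gminus")
})

test_that("coding consequences match known codon edits", {
  toy <- toy_gene_models()
  idx <- build_feature_index(toy$gm, toy$layout)
  # gplus CDS starts at 1060 with ATG on the + strand
  chrom <- as.character(toy$genome[[1]])
  # codon GCC -> GTC is missense (Ala -> Val): write GCC at CDS codon 2
  g2 <- Biostrings::replaceAt(toy$genome[[1]],
                              IRanges::IRanges(1064, 1066),
                              Biostrings::DNAStringSet("GCC"))
  genome2 <- Biostrings::DNAStringSet(list(chr1 = g2))
  v <- data.frame(chrom = "chr1", pos = 1064, ref = "C", alt = "T",
                  vclass = "snp")
  expect_equal(classify_variants(v, idx, genome2)$category, "cds_missense")
  # TGC -> TGA is stop gain
  g3 <- Biostrings::replaceAt(toy$genome[[1]],
                              IRanges::IRanges(1064, 1066),
                              Biostrings::DNAStringSet("TGC"))
  genome3 <- Biostrings::DNAStringSet(list(chr1 = g3))
  v3 <- data.frame(chrom = "chr1", pos = 1065, ref = "C", alt = "A",
                   vclass = "snp")
  expect_equal(classify_variants(v3, idx, genome3)$category, "cds_stop_gain")
  # synonymous third-position edit: GCC -> GCT both Ala
  v4 <- data.frame(chrom = "chr1", pos = 1065, ref = "C", alt = "T",
                   vclass = "snp")
  expect_equal(classify_variants(v4, idx, genome2)$category, "cds_synonymous")
  # 3-bp deletion inside CDS -> inframe; 2-bp -> frameshift (PTV)
  del3 <- data.frame(chrom = "chr1", pos = 1100,
                     ref = substr(chrom, 1101, 1104),
                     alt = substr(chrom, 1101, 1101), vclass = "indel")
  expect_equal(classify_variants(del3, idx, toy$genome)$category,
               "cds_inframe_indel")
  del2 <- data.frame(chrom = "chr1", pos = 1100,
                     ref = substr(chrom, 1101, 1103),
                     alt = substr(chrom, 1101, 1101), vclass = "indel")
  ann <- classify_variants(del2, idx, toy$genome)
  expect_equal(ann$category, "cds_frameshift")
  expect_true(ann$is_ptv)
  # VCF REF disagreeing with the reference sequence is an error
  bad <- data.frame(chrom = "chr1", pos = 1064,
                    ref = setdiff(c("A", "C", "G", "T"),
                                  substr(chrom, 1065, 1065))[1],
                    alt = substr(chrom, 1065, 1065), vclass = "snp")
  expect_error(classify_variants(bad, idx, toy$genome), "reference mismatch")
})

test_that("consequences agree with the full-retranslation oracle on both strands", {
  toy <- toy_gene_models(seed = 42)
  idx <- build_feature_index(toy$gm, toy$layout)
  chrom <- as.character(toy$genome[[1]])
  set.seed(99)
  cds_pos <- c(sample(c(1060:1299, 1600:1938), 150),
               sample(c(6061:6299, 6600:6939), 150))
  gene_of <- ifelse(cds_pos < 3000, "gplus", "gminus")
  ref <- substring(chrom, cds_pos + 1, cds_pos + 1)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
    USE.NAMES = FALSE)
  vars <- data.frame(chrom = "chr1", pos = cds_pos, ref = ref, alt = alt,
                     vclass = "snp", stringsAsFactors = FALSE)
  got <- classify_variants(vars, idx, toy$genome)$category
  want <- vapply(seq_along(cds_pos), function(i)
    consequence_oracle(vars[i, ], gene_of[i], toy$gm, toy$genome),
    character(1))
  expect_identical(got, want)
})

test_that("every variant gets exactly one category and the sets partition", {
  cfg <- small_sim_config(seed = 17)
  st <- simulate_study(cfg)
  idx <- build_feature_index(st$gene_models, st$layout)
  ann <- classify_variants(st$vt$variants, idx, st$genome)
  expect_equal(nrow(ann), nrow(st$vt$variants))
  expect_false(any(is.na(ann$category)))
  cats <- c("cds_synonymous", "cds_missense", "cds_stop_gain", "cds_stop_loss",
            "cds_frameshift", "cds_inframe_indel", "splice_site", "utr5",
            "utr3", "promoter", "intron", "intergenic")
  expect_true(all(ann$category %in% cats))
  expect_equal(sum(table(ann$category)), nrow(ann))
  fc <- functional_coding_set(ann); ptv <- ptv_set(ann)
  expect_true(all(ptv$category %in% c("cds_frameshift", "cds_stop_gain")))
  expect_true(all(ptv$chrom %in% fc$chrom))   # PTV subset of functional coding
  expect_true(all(paste(ptv$chrom, ptv$pos) %in% paste(fc$chrom, fc$pos)))
  expect_false(any(fc$category %in% c("cds_synonymous", "utr5", "utr3",
                                      "promoter", "intron", "intergenic",
                                      "cds_inframe_indel")))
})
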