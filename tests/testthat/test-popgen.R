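test_that("site frequencies count called alleles and pooled MAF", {
  g <- rbind(c(0, 1, 2, 0, 0, 0),
             c(NA, NA, NA, 0, 1, 1),
             c(2, 2, 2, 0, 0, 1))
  vt <- toy_variant_table(g)
  sf <- site_frequencies(vt, toy_sample_map())
  # pop1 genotypes [0,1,2] -> n=6, j=3, p=0.5, het over individuals = 1/3
  expect_equal(sf$n1[1], 6); expect_equal(sf$j1[1], 3)
  expect_equal(sf$p1[1], 0.5); expect_equal(sf$het1[1], 1 / 3)
  # all missing in pop1 -> uncomputable
  expect_false(sf$ok1[2]); expect_false(sf$ok[2])
  # MAF from pooled counts, not mean of p: site 3 p1=1, p2=1/6 -> pooled 7/12
  expect_equal(sf$maf[3], 5 / 12)
  expect_error(delta_af(sf), "no called genotypes")
})

test_that("MAF filter boundary is inclusive and threshold 0 is identity", {
  g <- rbind(rep(0:2, 2), c(0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, 0))
  vt <- toy_variant_table(g)
  sf <- site_frequencies(vt, toy_sample_map())
  expect_equal(sf$maf, c(0.5, 1 / 12, 0))
  expect_equal(nrow(maf_filter(sf, 1 / 12)), 2)  # boundary retained
  expect_equal(nrow(maf_filter(sf, 1 / 12 + 1e-9)), 1)
  expect_equal(nrow(maf_filter(sf, 0)), 3)
})

test_that("deltaAF is |p1 - p2| with inclusive 0.9 flagging", {
  g <- rbind(c(2, 2, 1, 0, 0, 0),    # p1 = 5/6 ~ 0.833, p2 = 0
             c(1, 1, 1, 1, 1, 1),    # p1 = p2 = 0.5
             c(2, 2, 2, 0, 0, 0))    # deltaAF = 1
  vt <- toy_variant_table(g)
  sf <- site_frequencies(vt, toy_sample_map())
  d <- delta_af(sf)
  expect_equal(d[1], 5 / 6)
  expect_equal(d[2], 0)
  hd <- is_highly_differential(sf)
  expect_false(hd[2])
  expect_true(hd[3])
  # exact 0.9 flags: construct p1 = 0.9, p2 = 0 with 5 + 5 samples
  g2 <- rbind(c(2, 2, 2, 2, 1, 0, 0, 0, 0, 0))
  vt2 <- toy_variant_table(g2)
  sf2 <- site_frequencies(vt2, toy_sample_map(5, 5))
  expect_equal(delta_af(sf2), 0.9)
  expect_true(is_highly_differential(sf2))
})

test_that("site_pi matches brute-force pair counting on random sites", {
  expect_equal(site_pi(4, 2), 2 / 3, tolerance = 1e-12)
  expect_equal(site_pi(2, 1), 1)
  expect_equal(site_pi(10, 0), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_true(is.na(site_pi(1, 0)))
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:30, 1); j <- sample(0:n, 1)
    expect_equal(site_pi(n, j), pi_oracle(n, j), tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham components match the literal 1984 formulas", {
  set.seed(5)
  for (i in 1:100) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    g2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    g <- matrix(c(g1, g2), nrow = 1)
    vt <- toy_variant_table(g)
    sf <- site_frequencies(vt, toy_sample_map(n1, n2))
    comp <- wc_fst_components(sf)
    o <- wc_oracle(c(n1, n2), c(mean(g1) / 2, mean(g2) / 2),
                   c(mean(g1 == 1), mean(g2 == 1)))
    expect_equal(comp$a, unname(o["a"]), tolerance = 1e-12)
    expect_equal(comp$b, unname(o["b"]), tolerance = 1e-12)
    expect_equal(comp$cc, unname(o["cc"]), tolerance = 1e-12)
  }
})

test_that("fixed differences give per-site FST 1; identical frequencies give a <= 0", {
  # p1=1, p2=0, no hets, equal sizes
  g <- matrix(c(2, 2, 2, 0, 0, 0), nrow = 1)
  sf <- site_frequencies(toy_variant_table(g), toy_sample_map())
  comp <- wc_fst_components(sf)
  expect_gt(comp$a, 0)
  expect_equal(comp$b, 0); expect_equal(comp$cc, 0)
  expect_equal(comp$a / comp$abc, 1)
  # p1=p2=0.5, het_obs=0.5: estimator noise makes a negative
  g2 <- matrix(c(2, 0, 1, 1, 2, 0, 1, 1), nrow = 1)
  sf2 <- site_frequencies(toy_variant_table(g2), toy_sample_map(4, 4))
  comp2 <- wc_fst_components(sf2)
  expect_lt(comp2$a, 0)
  # monomorphic same allele in both: all components zero
  g3 <- matrix(rep(0, 6), nrow = 1)
  sf3 <- site_frequencies(toy_variant_table(g3), toy_sample_map())
  comp3 <- wc_fst_components(sf3)
  expect_equal(comp3$abc, 0)
})

test_that("FST is symmetric in populations and pi invariant to allele relabeling", {
  set.seed(9)
  g <- matrix(rbinom(40 * 6, 2, runif(40, 0.1, 0.9)), nrow = 40)
  vt <- toy_variant_table(g)
  sm <- toy_sample_map()
  sm_swapped <- sweepcis::as_sample_map(sm$sample, ifelse(sm$population == "east",
                                                          "west2", "east2"))
  f1 <- weighted_fst(site_frequencies(vt, sm))
  ## swapping which population is "first" leaves the weighted FST unchanged
  sm2 <- sweepcis::as_sample_map(rev(sm$sample), rev(sm$population))
  f2 <- weighted_fst(site_frequencies(vt, sm2))
  expect_equal(f1, f2, tolerance = 1e-12)
  ## relabel ref/alt (dosage g -> 2 - g): pi unchanged
  sf <- site_frequencies(vt, sm)
  sf_flip <- site_frequencies(toy_variant_table(2 - g), sm)
  expect_equal(site_pi(sf$n1, sf$j1), site_pi(sf_flip$n1, sf_flip$j1),
               tolerance = 1e-12)
  expect_equal(weighted_fst(sf), weighted_fst(sf_flip), tolerance = 1e-12)
})

test_that("windows enumerate with truncation at chromosome ends", {
  w <- make_windows(genome_layout(c(c1 = 100000)))
  expect_equal(nrow(w), 10)
  expect_equal(c(w$start[1], w$end[1]), c(0, 50000))
  expect_equal(c(w$start[10], w$end[10]), c(90000, 100000))
  w2 <- make_windows(genome_layout(c(c1 = 30000)))
  expect_equal(nrow(w2), 3)
  expect_true(all(w2$end == 30000))
  w3 <- make_windows(genome_layout(c(c1 = 100000)), size = 50000, step = 50000)
  expect_equal(nrow(w3), 2)
  expect_equal(w3$start, c(0, 50000))
})

test_that("window stats normalize pi by span, drop sparse windows, weight FST", {
  # one SNP with site_pi(6, 3) = 0.6 in a 50-kb window
  g <- matrix(c(0, 1, 2, 0, 1, 2), nrow = 1)
  vt <- toy_variant_table(g, pos = 1000, layout = genome_layout(c(chr1 = 50000)))
  sf <- site_frequencies(vt, toy_sample_map())
  w <- make_windows(vt$layout)
  ws <- window_stats(sf, w, min_snps = 1)
  expect_equal(ws$pi_pop1[1], 0.6 / 50000, tolerance = 1e-12)
  expect_equal(ws$n_snps[1], 1)

  # windows below min_snps are excluded
  set.seed(3)
  g2 <- matrix(rbinom(9 * 6, 2, 0.5), nrow = 9)
  vt2 <- toy_variant_table(g2, pos = seq(100, 900, by = 100),
                           layout = genome_layout(c(chr1 = 50000)))
  sf2 <- site_frequencies(vt2, toy_sample_map())
  ws2 <- window_stats(sf2, make_windows(vt2$layout), min_snps = 10)
  expect_equal(nrow(ws2), 0)

  # all SNPs fixed-different -> window FST exactly 1
  g3 <- matrix(rep(c(2, 2, 2, 0, 0, 0), 15), nrow = 15, byrow = TRUE)
  vt3 <- toy_variant_table(g3, pos = seq(1000, by = 500, length.out = 15),
                           layout = genome_layout(c(chr1 = 50000)))
  sf3 <- site_frequencies(vt3, toy_sample_map())
  ws3 <- window_stats(sf3, make_windows(vt3$layout), min_snps = 10)
  expect_equal(ws3$fst[1], 1)
  expect_true(all(ws3$fst <= 1 + 1e-12, na.rm = TRUE))
})

test_that("windowed FST agrees with a direct transcription on random windows", {
  set.seed(21)
  for (rep in 1:20) {
    ns <- sample(12:40, 1)
    g <- matrix(rbinom(ns * 12, 2, rep(runif(ns, 0.1, 0.9), 12)), nrow = ns)
    vt <- toy_variant_table(g, pos = sort(sample(1:49000, ns)),
                            layout = genome_layout(c(chr1 = 50000)))
    sf <- site_frequencies(vt, toy_sample_map(6, 6))
    ws <- window_stats(sf, data.frame(chrom = "chr1", start = 0, end = 50000,
                                      window_id = 1), min_snps = 1)
    oracle <- sapply(seq_len(ns), function(i) {
      g1 <- g[i, 1:6]; g2 <- g[i, 7:12]
      wc_oracle(c(6, 6), c(mean(g1) / 2, mean(g2) / 2),
                c(mean(g1 == 1), mean(g2 == 1)))
    })
    expect_equal(ws$fst, sum(oracle["a", ]) / sum(colSums(oracle)),
                 tolerance = 1e-10)
  }
})

test_that("LD r2 handles identical, orthogonal and degenerate dosage vectors", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
  set.seed(2)
  for (i in 1:50) {
    a <- rbinom(20, 2, 0.5); b <- rbinom(20, 2, 0.5)
    r2 <- ld_r2(a, b)
    if (!is.na(r2)) expect_true(r2 >= 0 && r2 <= 1 + 1e-12)
  }
})

test_that("LD decay bins pairs by distance and matches per-pair r2", {
  set.seed(4)
  g <- matrix(rbinom(4 * 20, 2, 0.5), nrow = 4)
  vt <- toy_variant_table(g, pos = c(100, 350, 2100, 5000),
                          layout = genome_layout(c(chr1 = 1e5)))
  sm <- toy_sample_map(10, 10)
  tab <- ld_decay(vt, max_dist = 10000, bin = 100)
  # pair (100,350): distance 250 -> bin [200,300)
  expect_equal(tab$n_pairs[tab$bin_start == 200], 1)
  expect_equal(tab$mean_r2[tab$bin_start == 200], ld_r2(g[1, ], g[2, ]),
               tolerance = 1e-10)
  expect_equal(sum(tab$n_pairs), choose(4, 2))
  ## pairwise-complete missing handling matches ld_r2
  g[1, 3] <- NA
  vt2 <- toy_variant_table(g, pos = c(100, 350, 2100, 5000),
                           layout = genome_layout(c(chr1 = 1e5)))
  tab2 <- ld_decay(vt2, max_dist = 10000, bin = 100)
  expect_equal(tab2$mean_r2[tab2$bin_start == 200], ld_r2(g[1, ], g[2, ]),
               tolerance = 1e-10)
})
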