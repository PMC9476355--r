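Package: sweepcis
Title: Selective Sweep Scanning and Cis-Regulatory Variant Prioritization
    from Two-Population Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Windowed scans for selective sweeps from biallelic variant
    calls of two diverged populations (per-site and windowed nucleotide
    diversity, weighted Weir-Cockerham FST, LD decay), quantile-combination
    calling of regions under selection, allele-frequency-differential
    variant prioritization, gene-feature and coding-consequence annotation,
    count-and-length-matched permutation enrichment and depletion tests,
    hypergeometric QTL/GWAS gene-set tests, and integration with
    differential-expression and chromatin-accessibility tables to rank
    candidate cis-regulatory targets of selection.  Includes a seeded
    synthetic-study generator (genome, gene models, repeat mask,
    Balding-Nichols two-population genotypes with planted sweeps, planted
    regulatory enrichment, DEG and ATAC peak tables) with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
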