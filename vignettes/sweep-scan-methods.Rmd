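---
title: "Methods: sweep scanning and cis-regulatory prioritization in sweepcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning and cis-regulatory prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
estimators, the calling rules, the permutation framework, the synthetic
study generator, and the design decisions taken where more than one
reasonable choice existed.

## Estimators

**Per-site diversity.** For a site with `n` called alleles of which `j`
are the alternate allele, the unbiased pairwise diversity is
$\pi_{site} = 2j(n-j)/(n(n-1))$ — the probability that two alleles drawn
without replacement differ. Windowed $\theta_\pi$ sums $\pi_{site}$ over
the SNPs of a window and divides by the *full window span* in bp. That
span normalization (rather than dividing by the number of variant sites)
matches the convention of the standard windowed-diversity tools and makes
windows with few SNPs look invariant-poor rather than artificially
diverse; per-variant normalization is available via
`window_stats(..., normalize = "variant")`.

**F~ST~.** Per site we compute the Weir–Cockerham (1984) variance
components for two populations from the per-population diploid counts
$n_i$, allele frequencies $p_i$ and observed heterozygosities $h_i$:
`a` (between populations), `b` (between individuals within populations)
and `c` (within individuals). The windowed estimator is the weighted
ratio $\sum a / \sum(a+b+c)$ over the computable SNPs of the window —
ratio-of-sums, not mean-of-ratios, so low-information sites cannot
dominate. Per-window values below zero (estimator noise near
$p_1 \approx p_2$) are reported unclamped: the empirical quantile ranks
used downstream are unaffected by any clamping choice. Missing genotypes
simply drop out of $n_i$; a site is uncomputable when a population has no
called genotypes.

**Assumptions.** Diploid, biallelic sites; genotype codes are alternate
allele dosages; populations are predefined by the sample map. Sites are
treated as exchangeable within windows — no LD weighting.

**LD decay.** $r^2$ is the squared Pearson correlation of genotype
dosages over pairwise-complete samples, averaged in fixed 100-bp
distance bins up to 300 kb. Dosage correlation is a deterministic,
phase-free approximation to haplotype $r^2$; it avoids EM phasing and is
the documented choice here. The pair cost is quadratic per chromosome, so
`ld_decay()` exposes `max_sites` for even subsampling.

## Sweep calling

Cutoffs are empirical quantiles over the analyzable windows (those with
at least `min_snps` SNPs), computed genome-wide — a single empirical
distribution, not per chromosome. The rank rule is inclusive: "top
$q$" means value $\geq$ the $\lceil qm \rceil$-th largest, so ties at the
boundary are all included and the flagged fraction can slightly exceed
the nominal mass. With fewer than 20 analyzable windows the quantiles are
meaningless and `compute_cutoffs()` refuses to run.

Two rules are combined, both requiring the window to sit in the top 10 %
of F~ST~:

* **Rule A** — the $\theta_\pi$ ratio (population 1 / population 2) falls
  in a 5 % tail. A *low* ratio means population 1 lost diversity, so the
  window is called swept in population 1; a high ratio calls
  population 2. The orientation is fixed by the sample map (population 1
  is the first label) and printed in the scan stage's provenance header
  to prevent silent swaps.
* **Rule B** — $\theta_\pi$ of population X falls in that population's
  bottom 5 %. This catches fixed sweeps where *both* populations have
  small diversity and the ratio is uninformative. Windows with an
  undefined ratio ($\pi_{pop2} = 0$) are excluded from the ratio
  quantiles but stay eligible under rule B.

A window may carry both rules and both populations; regions are merged
per population (overlapping or book-ended windows, which consecutive
flagged windows always are when step < size) with the rule letters
unioned. Attribution of ambiguous windows to both populations is
recorded with rule provenance rather than guessing a single intent.

Gene assignment uses a 1-bp overlap rule on half-open intervals: a gene
ending exactly where a region starts does not overlap.

## deltaAF and annotation

deltaAF is $|p_1 - p_2|$ over called alleles; "highly differential" is
deltaAF $\geq 0.9$, boundary inclusive. Indels are excluded from
$\pi$/F~ST~/LD (SNP statistics) but retained for deltaAF and annotation.

Each variant receives exactly one category by precedence
CDS > splice site > UTR > promoter > intron > intergenic; a variant in
one gene's CDS and another gene's promoter is assigned to the CDS gene
(ties between genes in the same category break deterministically by gene
id). CDS SNPs are spliced into the coding sequence of the gene's
longest-CDS transcript (strand-aware) and the affected codon translated
under the standard genetic code; indels are frameshift when the REF/ALT
length difference is not divisible by 3, in-frame otherwise. Start-codon
loss is reported as missense rather than a separate class. Splice sites
are the first and last 2 intronic bases of every intron. The promoter is
\[TSS − 2000, TSS + 200) on the coding strand — a declared parameter
(`promoter_up`/`promoter_down`) following common regulatory-genomics
practice, since downstream promoter results are a function of this span.
For indels the affected span starts at the first changed base after
stripping the shared REF/ALT prefix; insertions are represented by the
single base after the insertion point.

## Permutation enrichment framework

The observed statistic is the number of query variants (each counted at
most once) overlapping the target intervals. Each of `n_sim` (default
1000) simulation rounds redraws a target-matched set of random intervals
— matched one-to-one in count and length, placed uniformly over all
positions whose full span avoids the repeat mask — and recounts. Then
fold = Obs / mean(Sim), P~enrich~ = #{Sim ≥ Obs}/n and
P~deplete~ = #{Sim < Obs}/n. Under these strict complementary
definitions P~enrich~ + P~deplete~ = 1 exactly; because an empirical zero
only means "below resolution", pseudocount-corrected values
(x+1)/(n+1) are reported alongside. Sampled intervals are drawn
independently and may overlap one another — independence keeps the null
exchangeable. All `n_sim` sets are drawn in one vectorized pass from a
single seeded generator, which makes results reproducible and
order-fixed by construction.

Before the regulatory tests, regions under selection within 50 kb
(closed flanks) of a highly differential functional coding variant are
removed, so coding selection cannot masquerade as regulatory enrichment.
Both the DEG-promoter fold and an all-promoters baseline fold are
reported; their interpretation (direct comparison vs ratio of folds) is
left to the caller.

QTL/GWAS gene-set tests are exact hypergeometric upper tails
(`stats::phyper`) with Benjamini–Hochberg FDR across traits; QTL genes
are those overlapping the QTL span, GWAS genes those within a 2-Mb
window centered at the tag midpoint.

## Synthetic study generator

The generator emulates the statistical structure of a two-population
resequencing study at desk scale. Defaults, chosen once as the study
conditions: a 20-Mb genome (2 × 10 Mb), 300 genes with exon/intron
structure and translatable CDS (ATG, sense codons, terminal stop), a 20 %
repeat mask avoiding CDS, 20 + 20 diploid samples, 30 000 variant sites,
1 % genotype missingness, 2 % short indels (1–6 bp). Allele frequencies
follow the Balding–Nichols model: ancestral $p \sim U(0.05, 0.95)$ and
per-population frequencies $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with
background $F = 0.15$ — F is then exactly the divergence the weighted
estimator must recover, which is why this model was preferred over a
coalescent simulator (a coalescent backend would be an extension point,
not a dependency). Ten 200-kb sweeps alternate between the populations;
inside a sweep the swept population draws its frequency from
Beta(20, 0.5) (near fixation), producing high F~ST~ and low swept-side
diversity. Highly differential variants are planted in the promoters of
genes overlapping sweeps and in planted differential ATAC peaks with
near-opposite-fixation Betas (Beta(50, 1) vs Beta(1, 50)); sites landing
in CDS are thinned by a factor 0.2 to emulate purifying selection. DEG
labels co-occur with promoter-targeted genes at rate 0.8 in the
enrichment tissue (skeletal muscle analog) and at a background 10 %
elsewhere across the ten tissues.

What the generator does **not** emulate: linkage (genotypes are
independent across sites, so LD decay curves are flat at the $1/n$
noise floor), demographic history (bottlenecks, migration, admixture),
mutation-rate heterogeneity, genotyping error structure, and multi-breed
population structure. Passing recovery tests therefore demonstrates that
the estimators and calling rules behave correctly under the generating
model — not that real data meet that model's assumptions.

Every artifact is a pure function of (config, seed); the fixture
directory carries a MANIFEST with the config digest, and `truth.json`
records sweeps, planted variants, targeted genes and DEG labels for the
recovery tests.

## Numerical and degenerate-input choices

* Quantile ties: inclusive rank rule (documented above); with all values
  equal the tails select everything, which the ≥20-window guard makes a
  conscious, visible outcome rather than a silent one.
* $\Sigma(a+b+c) = 0$ in a window (all sites monomorphic in the pooled
  sample): F~ST~ undefined, window excluded from F~ST~ quantiles.
* $\pi_{pop2} = 0$: ratio undefined, flagged, rule-B-eligible.
* Empirical P of 0 is printed as 0 with the corrected companion.
* Half-called genotypes (e.g. `./1`) are treated as missing — the
  conservative policy; multiallelic rows are split into biallelic records
  with other-alt carriers set to missing (strict rejection available).
* rand = 0 in an enrichment test: fold is NA with a flag, never Inf.
* Coordinates are 0-based half-open everywhere internally; VCF and GFF3
  convert at the I/O boundary, which keeps every overlap rule (1-bp gene
  overlap, book-ended merging, closed 50-kb flanks) exactly testable.

## Problem sizes used by the test suite

The suite exercises the default 20-Mb study for sweep recovery and
pipeline determinism, a 2-Mb/2000-SNP configuration for divergence
recovery (F ∈ {0.05, 0.15, 0.30}, 10 seeds each), 200 replicates of a
1-Mb null for permutation calibration (n_sim = 200 per replicate), and
1000-round permutations for the planted enrichment/depletion checks —
sizes chosen so the whole suite runs comfortably on a laptop while
keeping every statistical check adequately powered.

## Known limitations

* Dosage $r^2$ understates haplotype $r^2$ when phase matters.
* One transcript per gene (longest CDS): consequences on minor isoforms
  are not reported.
* The permutation null matches count and length but not GC content,
  distance-to-gene or chromatin context of the targets.
* Quantile calling makes no multiple-testing claim: "top 10 %" is a
  screening rule, not a significance statement.
* Sweep attribution near the truth boundary inherits window-step
  granularity: called regions can extend up to one window size beyond a
  true sweep.
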