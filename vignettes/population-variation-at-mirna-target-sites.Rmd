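---
title: "Population variation at microRNA target sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population variation at microRNA target sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpopvar)
```

## The problem

MicroRNAs repress transcripts by pairing the seed — nucleotides 2–8 of the
mature sequence — to short complementary motifs in 3'UTRs. Because target
prediction is almost always run on a reference genome sequence, any target
site carried by a non-reference allele is invisible to it. Human populations,
and African populations in particular, segregate many such alleles: a single
SNP can create or destroy a seed-match site, so the set of functional targets
differs between individuals and between populations. `mirpopvar` implements
the analysis chain needed to quantify this: detect seed-match sites, find the
SNPs whose two alleles differ in site status ("target/near-target pairs"),
orient them against ancestral and reference alleles, measure how strongly the
target allele is differentiated between populations, and test two
population-level associations (a latitude cline and an African-vs-European
frequency shift).

## Seed matching

A 7-nt seed defines four canonical site classes on the mRNA sense strand:

* **7mer-m8** — the DNA reverse complement of the full seed (pairs seed
  positions 2–8);
* **6mer** — the 7mer-m8 without its 5'-most base (pairs positions 2–7);
* **7mer-A1** — the 6mer followed by an adenosine opposite mature position 1;
* **8mer** — the 7mer-m8 followed by that adenosine.

The trailing A is matched as a literal A in the UTR, never as the complement
of mature position 1 — the standard convention, reflecting the preference of
Argonaute for an A in that pocket. Matching is exact string matching after
mapping U to T; `N` never matches.

Scanning is anchor-based: every occurrence of the 6mer core is an anchor,
and the bases flanking the core decide the single most-specific class for
that anchor (8mer > 7mer-m8 > 7mer-A1 > 6mer). A locus is therefore never
double-reported as both an 8mer and its contained 7mer; overlapping anchors
are all reported. The default "target" set is {8mer, 7mer-m8, 7mer-A1}; the
weak 6mer class is opt-in (`site_types` arguments throughout), matching
mainstream prediction practice. Mature microRNAs sharing a seed form one
family and are analysed jointly, since they share every site.

"Highly expressed" microRNAs are selected by a configurable expression
threshold. When none is given, the median of the supplied expression table is
used (a top-50% rule); analyses of the synthetic fixtures pass an explicit
threshold of 1 instead, because the simulated tables are bimodal by
construction (expressed miRNAs around 100, decoys near 0) and the median
rule is aimed at realistic, long-tailed expression tables.

## Target/near-target pairs and polarization

For each biallelic SNV inside a UTR, both allele-substituted sequences are
scanned, keeping only sites whose half-open interval contains the SNP
position: the pair concept requires the SNP base itself to toggle the site.
A pair exists iff exactly one allele carries at least one overlapping site
of an allowed type. When both alleles carry one (a substitution that merely
changes the site class), no pair is emitted and the event is logged; the
behaviour of upstream databases on this rare case is not documented anywhere
we know of, so we chose the conservative option. A SNP can form independent
pairs for different seed families.

With a known ancestral allele (1000 Genomes `INFO/AA` dialect; values other
than ref or alt are treated as unknown) each pair falls in one cell of a
2×2 grid — ancestral allele is/is not the target allele × target allele
is/is not in the reference — yielding the four classes
`ancestral_target_lost`, `derived_target_gained`, `ancestral_target_in_ref`
and `derived_nontarget_in_ref`, plus `unpolarized` when the ancestral state
is unknown. Coordinates are 0-based half-open internally; the VCF boundary
(1-based) is converted exactly once, in the parser.

Pairs are filtered to segregating variants with pooled global target-allele
frequency in [0.01, 0.99]; both boundaries are inclusive (the window is
stated as a range without strictness, and inclusive bounds keep a variant
observed at exactly 1% analysable).

## Population differentiation

Target-allele counts are aggregated sample → population → super-population
(AFR, AMR, EAS, EUR, SAS); missing genotypes leave both numerator and
denominator. Global frequency is the pooled count ratio, never a mean of
frequencies. Three Fst estimators are provided:

* **Wright variance ratio** — `var(p) / (p̄(1−p̄))` with equal population
  weights and the population (divisor-k) variance: the textbook definition,
  useful for worked examples on printed frequency vectors;
* **Hudson (1992)** — `1 − Hw/Hb` from allele counts with the finite-sample
  correction; more than two populations are combined as the ratio of
  averaged numerators to averaged denominators over all pairs; the default,
  because it is reproducible from counts alone, nearly unbiased, and
  insensitive to the number of populations;
* **Weir & Cockerham (1984) θ̂** — the a/(a+b+c) variance-component
  estimator for unequal sample sizes. When only allele counts are available
  (the usual situation for frequency-level data), heterozygosity enters at
  its Hardy–Weinberg expectation `2p(1−p)` per population; observed
  heterozygote proportions can be supplied instead.

Multi-locus values use ratio-of-averages (`fst_genomewide()`), not averages
of ratios. Negative single-locus estimates are kept as computed — they carry
information about the estimator — and are clamped to zero only in the
human-readable report tables.

`P_Fst` is an add-one empirical upper-tail percentile,
`(1 + #{null ≥ observed}) / (N + 1)`, against a null distribution that is
either a user-supplied genome-wide Fst file or, by default, simulated under
the Balding–Nichols model with F set to the genome-wide Hudson estimate of
the analysed SNPs themselves. The percentile definition the original
database used is not documented; the add-one percentile is a standard,
conservative stand-in, and is configurable.

The headline differentiation filter is a strict `Fst > 0.7`, with output
ranked by descending Fst; the distribution report counts `Fst ≥ 0.3`
inclusively ("0.3 or more").

## Association analyses

**Latitude model.** Populations are placed at the arithmetic (plate carrée)
centroid of their collection points, and the absolute centroid latitude is
the predictor. Hemisphere-symmetric collection points cancel — a documented
limitation of the planar centroid, irrelevant at the within-population
scales involved. Recently migrated populations (default list CHD, CEU, ASW,
ACB, GIH, STU, ITU) are excluded. The model is ordinary least squares of
target allele frequency on |latitude|, reporting slope, adjusted R², and the
two-sided t-test on the slope. No spatial autocorrelation correction and no
multiple-testing correction are applied, matching the original analysis
scale (two SNPs).

**Paired shift test.** African and European target-allele frequencies per
site are compared with a two-sided Wilcoxon signed-rank test on the paired
differences (EUR − AFR as reported). Zero differences are dropped before
ranking (Wilcoxon's original policy, the common software default) and
counted. The exact null distribution is used for n ≤ 25 without ties
(configurable), otherwise a normal approximation with continuity and tie
correction. The shift estimate is the Hodges–Lehmann pseudomedian — the
median of all Walsh averages of the differences — with a
distribution-inversion confidence interval: the `qsignrank` quantile of the
null picks the order statistics of the sorted Walsh averages (its normal
approximation for large n). For n ≤ 25 this reproduces the standard
`wilcox.test` interval exactly; for large n our estimate is the exact Walsh
median where `wilcox.test` root-finds, so the two agree only approximately.
If every pair has zero difference the test is undefined and an error is
raised rather than a fabricated p of 1.

## The synthetic-data generator

The generator inverts the classifier to produce fixtures with known ground
truth, so every pipeline stage can be tested without downloads.

* **Population structure** is Balding–Nichols: population frequencies are
  independent Beta(p̄(1−F)/F, (1−p̄)(1−F)/F) draws around an ancestral
  frequency p̄, giving expectation p̄ and expected Fst ≈ F. Default F =
  0.15, of the order of continental human differentiation. Ancestral p̄ is
  drawn from a Beta(0.8, 0.8) truncated to [0.05, 0.95] so that planted
  variants populate the 0.01–0.99 analysis window.
* **Layout**: 10 sampled populations, two per super-population, 30 diploids
  each, latitudes drawn from plausible per-continent ranges — small enough
  to keep the full test suite fast, structured enough to exercise every
  aggregation level.
* **Planted SNPs** come in three classes: *disrupting* (reference allele
  completes a planted site, alternate abolishes it), *creating* (the
  reverse) and *neutral*. Every disruption is chosen by search and verified
  with the scanner itself used in reverse: the non-target allele must leave
  no allowed site of any simulated family overlapping the SNP, and neutral
  SNPs must leave site status unchanged for every family on both alleles.
  Placement keeps planted loci at least 8 nt apart so verifications cannot
  interfere.
* **Class-specific frequency profiles** (on by default) emulate the
  out-of-Africa pattern the polarization classes are designed to reveal:
  pairs whose target allele is ancestral get high African / low non-African
  target frequencies (means 0.70 vs 0.15), derived-target pairs the reverse
  (0.20 vs 0.60), with mild within-continent scatter (F = 0.05 around the
  group mean). A configurable subset of pairs instead follows a latitude
  cline, frequency = 0.8 − 0.01·|latitude| + N(0, 0.02) per population.
* **Genotypes** are Hardy–Weinberg binomial draws within populations — the
  simplest model consistent with frequency-level analyses. Ancestral
  alleles equal the target allele with probability 0.5 by default, with an
  optional mislabeling/unknown probability to exercise unpolarized
  handling.

What the generator does **not** emulate: linkage between SNPs, demographic
history (bottlenecks, growth, migration), background selection, sequencing
or imputation error, and realistic UTR base composition. Passing tests on
these fixtures therefore demonstrate correctness of the computation, not
calibration on real 1000 Genomes data; genome-scale runs require real
inputs through the same interfaces.

## Numerical and design choices

* Exact-vs-approximate signed-rank switch at n = 25 (no ties), the add-one
  P_Fst percentile, inclusive frequency-window bounds, strict Fst
  threshold, and descending-Fst/lexicographic-SNP-id table ordering are all
  fixed defaults, each configurable where a different convention is
  plausible.
* Identical subpopulation frequencies give exactly 0 under the Wright
  estimator; the unbiased count-based estimators give slightly negative
  values of order −1/n, approaching 0 in the large-sample limit — the test
  suite checks both facts rather than forcing a clamp.
* Report tables are written with fixed 6-decimal formatting so that
  re-running a pipeline with the same configuration and inputs is
  byte-identical.
* Problem sizes in the test suite (for example 1,000 random scanner
  instances, 2,000 simulated SNPs across 5 populations of 100 diploids for
  estimator recovery, 200-seed regression suites) were chosen as the
  smallest sizes at which the stochastic properties under test are stable.

## Known limitations

* UTR-local coordinates only: no genome liftover, no BED-against-genome
  intersection mode.
* No thermodynamic or context scoring of sites, no 3'-supplementary
  pairing — site presence is a purely combinatorial seed-match notion.
* SNVs only; indels and multi-allelic records are excluded (and counted) at
  the VCF boundary.
* The Weir–Cockerham estimator from allele counts assumes Hardy–Weinberg
  heterozygosity unless observed values are supplied.
* `P_Fst` depends on the chosen null; with the default self-calibrated
  Balding–Nichols null it is a relative outlier measure, not an absolute
  significance claim.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 7)
fx <- simulate_fixtures(cfg, "fixtures")
rc <- run_config(utrs = fx$paths$utrs, mirnas = fx$paths$mirnas,
                 vcf = fx$paths$vcf, panel = fx$paths$panel,
                 expression = fx$paths$expression, expression_threshold = 1,
                 interactions = fx$paths$interactions,
                 latitude = fx$paths$latitude,
                 out_dir = "run", rng_seed = 1)
res <- run_pipeline(rc)
head(res$pairs)
res$fig3_report$fraction
```
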