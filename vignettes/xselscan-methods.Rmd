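---
title: "Sex-aware X-chromosome selection scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-aware X-chromosome selection scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xselscan)
```

`xselscan` implements a complete analysis chain for detecting positive
selection on the X chromosome of structured populations sampled along an
environmental gradient — the motivating case being dog populations at
altitudes from roughly 300 m to 4,400 m, where a candidate haplotype's
frequency rises with altitude. This vignette explains the models, the
numerical choices, and what the package's synthetic studies do and do not
demonstrate.

## Why the X chromosome needs its own bookkeeping

Every statistic in this package is computed over *chromosomes*, not
individuals. A female contributes two X copies and a male one (hemizygosity),
so a population of $F$ females and $M$ males carries $2F + M$ chromosomes.
All allele frequencies, haplotype frequencies, and diversity statistics use
this chromosome count as denominator — the "gender-corrected" frequencies of
the sample sheet. Consequences ripple through the whole pipeline:

* a heterozygous diploid genotype reported for a male is biologically
  impossible on the X (outside pseudo-autosomal regions) and is treated as
  missing for that sample, with a warning — genotyping artifacts should not
  masquerade as data;
* a sample counts as missing at a site when any of its expected allele slots
  is uncalled, and site-level missingness is measured against *all* samples
  in the sheet, not only those with calls;
* males are trivially phased, which makes mixed-sex haplotype panels cheaper
  than autosomal ones.

## Variant filtering

`filter_variants()` applies five post-calling filters in a fixed order, each
counting removals from the set that survived the previous rules: (1) SNPs
within 5 bp of a supplied indel position; (2) sites missing in more than 20%
of all samples; (3) non-bi-allelic sites; (4) site depth outside the
2.5–97.5 depth percentiles; (5) site QUAL not above 40. The depth percentiles
are computed over the sites remaining after rules 1–3, because depth
filtering is meant to trim the tails of the *surviving* coverage
distribution; computing them on the raw set would let indel-adjacent
artifacts shift the bounds. All internal coordinates are 1-based inclusive
(the VCF convention); BED input is shifted on read.

## The two-test scan

Differentiation between a high- and a low-altitude group is measured per SNP
in two ways.

**Hudson's Fst** (ratio of moments), from chromosome counts $n_1, n_2$ and
sample frequencies $\hat p_1, \hat p_2$:

$$\hat F = \frac{(\hat p_1-\hat p_2)^2
  - \frac{\hat p_1(1-\hat p_1)}{n_1-1}
  - \frac{\hat p_2(1-\hat p_2)}{n_2-1}}
  {\hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1)}.$$

Hudson's estimator is the default because it needs nothing beyond allele
counts and is therefore agnostic to the mixed male/female ploidy; the
Weir–Cockerham variance-components estimator assumes a diploid sampling
model, so it is offered only as a comparison option (in its haploid,
allele-observation form). Sites where the denominator vanishes are excluded
from ranking — never imputed as zero, which would dilute the tail the scan
lives in. Negative estimates are retained as computed.

**Fisher's exact test** on the 2×2 table of ref/alt chromosome counts in the
two groups, with the minimum-likelihood two-sided rule: the p-value sums the
probabilities of all tables (margins fixed) whose point probability does not
exceed the observed one, with a relative tolerance of $10^{-12}$ on the
comparison so floating-point near-ties resolve deterministically. A zero
margin returns $p = 1$. P-values are FDR-corrected by Benjamini–Hochberg.

**Outlier calling** takes the top 1% of each statistic by the nearest-rank
rule (with $k = \lceil 0.01\,n\rceil$, the cutoff is the $k$-th most extreme
value) keeping all ties at the cutoff. The package always computes and
reports its cutoff rather than reusing any fixed value; on realistic
synthetic data the Fst cutoff lands around 0.6–0.7. Two guard rails matter in
degenerate settings: when a group is contrasted against itself the Fst cutoff
is non-positive and the q cutoff is 1, and a non-discriminating cutoff yields
zero outliers instead of flagging noise.

**Gene ranking** maps outliers to annotated gene spans (introns included —
regulatory and linked variation inside genes counts), then ranks genes by
outlier density: the union of Fst- and Fisher-outliers inside the span, per
kb of span. Ties break by start coordinate, stably. Candidate genes are the
intersection of the gene sets from independent contrasts.

## The drift test

A region can look differentiated by drift alone, especially on the X with its
reduced effective size. `drift_test()` asks how often a neutral
two-population-split model produces differentiation as strong as observed.

The null model is a standard coalescent: within each extant population,
lineage pairs coalesce at rate $k(k-1)/2$ per $2N_e$ generations; at the
split time (backwards) both lineage sets merge into the ancestral population.
The default demography is the inferred high/low-altitude dog history — split
3,400 years ago, ancestral $N_e$ 37,800, extant sizes 4,058 (high) and
8,681 (low), X-linked mutation rate $2.2\times10^{-9}/1.3 =
1.692\times10^{-9}$ per site per year over a 47,544 bp locus, sampled with
15 + 15 chromosomes. The $N_e$ values are used as printed because the
X correction is already carried by the mutation rate; rescaling both would
double-correct. One parameter the per-year rates cannot do without is a
generation time; the package defaults to 3 years for village dogs, and
exposes it prominently in `demography_params()` since every coalescent time
scales with it.

Mutations follow the infinite-sites model. The default `fixed_s` mode places
exactly $S = 108$ mutations multinomially on branches proportional to branch
length, matching a region with a known SNP count; every mutation has between
1 and $n-1$ descendants, so every site is polymorphic in the pooled sample.
The `theta` mode draws Poisson(total branch length × $\mu$ × $L$) mutations
and exists mainly so the engine can be validated against Watterson's
closed form $E[S] = a_{n-1}\,\theta L$, and against an independent coalescent
simulator in the test suite.

Per replicate the engine computes the per-site Hudson Fst of the simulated
sample and two summaries: the replicate's mean Fst, and a two-sided Welch
t-test of the simulated Fst vector against the observed one. The headline
probability is the mean-Fst exceedance

$$P_{\text{drift}} = \frac{1 + \#\{\bar F_{\text{sim}} \ge
\bar F_{\text{obs}}\}}{n_{\text{reps}} + 1},$$

with the $+1$ small-sample correction so an extreme observation reports a
resolution-limited bound instead of zero. The t-test p distribution is
returned alongside rather than collapsed to a single number, because there is
no canonical way to reduce a million per-replicate tests to one probability;
the exceedance probability is the quantity with a direct null interpretation.

One property of this null deserves emphasis: all sites of a replicate share a
single genealogy, so replicate mean Fst is far more dispersed than site
counts alone suggest (under the default demography the null mean is ≈ 0.06
but roughly 1% of neutral replicates exceed 0.3). Detecting selection against
this null requires genuinely strong differentiation — which is what makes the
test conservative and credible.

The engine is implemented in C++ (as the field's coalescent simulators are):
the drift-test calibration in the test suite runs half a million replicates,
which takes seconds compiled and would take tens of minutes in R. It draws
from R's RNG, so a run is bit-reproducible given `set.seed`; all replicates
consume one seeded stream sequentially, which keeps a single RNG
implementation and still guarantees that identical seed and parameters give
identical output.

## Haplotypes, clines, and LD

`extract_haplotypes()` builds one allele string per chromosome over a SNP
panel from phased input (truth-phased synthetic data, or externally phased
VCF). Chromosomes with any missing panel call are dropped whole — dropping
sites instead would misalign the strings; an unphased heterozygous female
drops both her chromosomes since neither can be reconstructed.

`major_haplotype_frequency()` counts exact matches of a target haplotype per
population over surviving chromosomes. Frequencies are kept at full
precision; a half-up 2-decimal display column matches how such tables are
published (base R's `round()` is banker's rounding, which a frequency table
reader would not expect).

`altitude_correlation()` tests the cline with an unweighted Pearson
correlation and the exact t-test $t = r\sqrt{(n-2)/(1-r^2)}$ on $n$
populations. Pearson unweighted is the default because, on the published
15-population table, it reproduces the reported significance almost exactly;
Spearman and a chromosome-count-weighted variant are provided for
sensitivity analysis. The correlation is computed on population frequencies,
unweighted by sample size, treating each population as one observation of
the cline.

`pairwise_ld()` computes gamete-frequency LD between panel loci:
$D = p_{AB} - p_A p_B$, $r^2 = D^2/(p_Aq_Ap_Bq_B)$, and $D' = D/D_{\max}$
with the sign-dependent $D_{\max}$. Pairs involving monomorphic loci are
flagged `NA` rather than zero.

## The synthetic-study generator

`generate_study()` produces a full study — phased variant table, sample
sheet, gene annotation, and generating truth — with the structure the
analysis assumes:

* **Populations.** By default the 15 populations of the published altitude
  gradient (300–4,380 m) with their published chromosome counts, split into
  females and males at roughly 1/3 females so $2F + M$ matches each count.
  The two scan-contrast populations then carry 15 chromosomes each, exactly
  the sampling depth of the drift-test demography.
* **Neutral background.** One draw of the split coalescent with the
  populations pooled into a high- and a low-altitude deme at the cline
  midpoint, 1,200 SNPs placed uniformly over a 3 Mb chromosome outside the
  selected region. This deliberately small problem size keeps a full study
  under a second to generate and scan while leaving hundreds of defined-Fst
  background SNPs to set the outlier cutoffs.
* **Selected region.** 47,544 bp carrying 108 SNPs. Each chromosome draws
  the distinct major haplotype with probability given by a logistic cline in
  altitude, $f(a) = f_{low} + (f_{high}-f_{low})/(1+e^{-k(a-a_0)})$, else one
  of three random background haplotypes; whole units, no recombination within
  the region, which reproduces the strong single-block LD a recent sweep
  leaves. Logistic is the minimal bounded monotone model for a frequency
  cline; defaults $f_{low} = 0.10$, $f_{high} = 0.95$, midpoint 2,500 m and
  steepness 0.0015/m put the expected frequencies near 0.16 at the lowest
  and 0.90 at the highest sampled altitude, bracketing the published
  low/high frequencies.
* **Annotation.** One gene spanning the selected region plus six 40 kb decoy
  genes over the neutral background.

What the generator does *not* emulate: recombination within the region and
between background SNPs (background sites share one genealogy per deme
rather than being exchangeable loci), sequencing error, depth-driven
missingness, and within-deme substructure among the pooled populations.
Passing tests therefore demonstrate that the statistics recover a planted
signal of realistic effect size under honest sampling noise — not that the
pipeline is robust to the full messiness of real resequencing data.

Because each chromosome draws its region haplotype independently, a
15-chromosome population occasionally draws an unrepresentative frequency
(binomial noise); in about 5% of seeded studies the low-altitude contrast
group draws enough major haplotypes to halve the cline contrast, and the
planted gene then fails to reach the genome-wide top-1% cutoff. The test
suite measures the recovery rate over 40 seeded runs against a 90% floor
rather than demanding every run succeed.

## Problem sizes and determinism

Simulation scales used by the test suite and the acceptance script, chosen
to give stable Monte-Carlo estimates at interactive runtimes: 2,000
replicates for the Watterson check (3-SE band), 500 per split-time point for
the Fst-monotonicity check, 50 calibration trials × 10,000 replicates for
the drift test, 40 (module) / 20 (end-to-end) seeded synthetic studies, and
10 studies × 10,000 replicates in the acceptance script. Every stochastic
step takes an explicit seed, and identical seed + parameters reproduce
byte-identical outputs, including written TSV/JSON files.

## Known limitations

* The coalescent supports exactly two extant populations plus an ancestor;
  multi-deme histories must be approximated by pooling, as the generator
  does.
* Fisher's exact test is applied per SNP to pooled allele counts; linked
  SNPs give correlated tests, which is why outlier calling is by rank, not
  by nominal significance.
* The drift test conditions on a fixed SNP count in its default mode; if the
  observed region's SNP count itself reflects selection (sweeps reduce
  diversity), the test is conservative.
* Phasing quality is taken at face value; statistical phasing errors in real
  data would blur haplotype frequencies toward the mean and weaken, not
  inflate, the altitude correlation.
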