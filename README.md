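# xselscan

Sex-aware selection scans for the X chromosome, with a coalescent
drift-versus-selection test and haplotype–altitude cline analysis.

## The problem

Selection scans routinely skip the X chromosome: males are hemizygous, so
naive diploid allele counting is wrong, the effective population size
differs from the autosomes, and stronger drift makes it easy to mistake
demographic noise for selection. `xselscan` is for population geneticists
who have X-chromosome SNPs (VCF), sample metadata (population, sex, and an
environmental covariate such as altitude), and gene annotations, and who
want to run the full chain: sex-aware allele counting → post-calling
filters → dual outlier tests → gene ranking → an explicit neutral-model
test of whether drift alone explains a candidate region → a
haplotype-frequency cline test across populations.

Every statistic counts *chromosomes*, not individuals: a female contributes
two allele observations per site and a male one, so a population of F
females and M males carries 2F + M chromosomes.

## The statistics at the core

Per-SNP differentiation between a high- and a low-altitude group uses
Hudson's ratio-of-moments estimator from chromosome counts n₁, n₂ and
sample frequencies p̂₁, p̂₂:

    F̂ = [ (p̂₁−p̂₂)² − p̂₁(1−p̂₁)/(n₁−1) − p̂₂(1−p̂₂)/(n₂−1) ]
        / [ p̂₁(1−p̂₂) + p̂₂(1−p̂₁) ]

alongside a per-SNP two-sided Fisher exact test (minimum-likelihood rule)
on ref/alt chromosome counts, FDR-corrected (Benjamini–Hochberg). Each
test's top 1% (nearest rank, ties kept) are outliers; genes are ranked by
outlier-SNP density (union of both outlier sets per kb of gene span).

The drift test simulates a two-population-split coalescent (pair
coalescence rate 1/(2Nₑ) per generation per pair within each population;
lineages merge into the ancestor at the split time) with infinite-sites
mutations — by default exactly S = 108 segregating sites over a 47,544 bp
locus — and reports the exceedance probability

    P_drift = (1 + #{mean simulated Fst ≥ mean observed Fst}) / (n_reps + 1)

plus the distribution of per-replicate Welch t-tests. The default
demography is the inferred high/low-altitude dog history (split 3,400
years ago; Nₑ 37,800 ancestral, 4,058 and 8,681 extant; X mutation rate
2.2e−9/1.3 = 1.692e−9 per site per year; 3-year generations; 15 + 15
chromosomes sampled). The simulator core is compiled (Rcpp), so a
10,000-replicate test runs in well under a second.

The cline test computes gender-corrected major-haplotype frequencies per
population and their Pearson correlation with altitude, with the exact
t-test p on n − 2 degrees of freedom.

## Worked example

A synthetic study emulates the target design: 15 populations from 300 m to
4,380 m with the published chromosome counts, a 47.5 kb selected region
with 108 SNPs whose major haplotype follows a logistic altitude cline, and
a neutral coalescent background.

```r
library(xselscan)

## published 15-population frequency table -> altitude correlation
t1 <- table1_fixture()
altitude_correlation(t1)
#> <altitude_cor> pearson r = 0.7582, two-sided p = 0.00105 (n = 15 populations)

## full synthetic study: scan, gene ranking, cline, drift test
st   <- generate_study(study_config(seed = 11))
scan <- run_scan(st$variants, st$annotation, pop_a = "TM", pop_b = "YJ")
scan
#> <scan_result> 1308 SNPs (949 with defined Fst)
#>   Fst outliers: 33 (cutoff 0.6867); Fisher outliers: 33 (q cutoff 0.00459)
#>   genes with outliers: 1 (Fst), 1 (Fisher)

head(scan$genes, 3)
#> # A tibble: 3 × 7
#>   gene_name span_bp n_fst n_fisher n_outliers n_snps density
#>   <chr>       <int> <int>    <int>      <int>  <int>   <dbl>
#> 1 selgene     47544    33       33         33    108   0.694
#> 2 decoy1      40000     0        0          0     17   0
#> 3 decoy2      40000     0        0          0     15   0

run_altitude_test(st$variants, st$truth$panel_positions,
                  st$truth$major_haplotype)$correlation
#> <altitude_cor> pearson r = 0.9766, two-sided p = 4.66e-10 (n = 15 populations)

run_drift_test(scan, region = c(st$config$region_start, st$config$region_end),
               n_reps = 10000, seed = 12)
#> <drift_test> observed mean Fst 0.3824 vs 10000 neutral replicates
#>   P(drift gives mean Fst >= observed) = 0.0037
#>   per-replicate Welch t-test: 99.2% of p-values < 0.05
```

Reading the output: the scan computes its own top-1% cutoffs from the data
(here Fst ≥ 0.69); the planted selected gene tops the density ranking while
the decoy genes over neutral background collect nothing; the major
haplotype's frequency climbs with altitude (r = 0.98); and drift alone
produces the region's mean differentiation in only ~0.4% of 10,000 neutral
replicates. Result objects have `tidy()`/`glance()` methods and `autoplot()`
Manhattan, cline, and null-distribution plots.

Real data enter through `read_vcf()` (with a `sample_sheet()`),
`read_annotation()` (BED or GFF3), and `filter_variants()` (the five
post-calling filters: indel proximity, missingness, bi-allelic, depth
percentiles, QUAL).

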