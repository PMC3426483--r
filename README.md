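# radscan

Minor-allele-count filtering and FST genome scans for two-population
RAD-seq data.

Genome scans interpret loci of elevated between-population differentiation
as candidates for divergent selection. But FST is sensitive to the allele
frequency distribution as well as to differentiation: a polymorphism whose
minor allele occurs only once or a few times in the pooled sample is
*constrained* to an FST near zero regardless of the drift and hitchhiking
history of its genomic region. Because natural populations carry a large
excess of such rare-allele polymorphisms, keeping them in a data set
deflates the genome-wide FST baseline and flattens sliding-window
differentiation profiles. `radscan` implements the full analysis chain for
demonstrating and correcting this bias, aimed at population genomicists
working with RAD or similar reduced-representation data.

## What it computes

- **Consensus genotyping** of per-individual read stacks: base-quality
  masking (error probability > 0.01 excluded), a diploid consensus when ten
  or more quality-passing reads are available (haploid otherwise), and a
  binomial heterozygote test — a position is heterozygous when the binomial
  point probability of its allele split under a 0.5/0.5 null exceeds 0.01.
- **Per-site FST**, two estimators:
  - Weir–Cockerham's θ = a/(a+b+c) from the among-population, among-
    individual and within-individual variance components of diploid
    genotype counts (unclipped; may be negative);
  - haplotype-diversity FST = (H_T − H_S)/H_T with
    H = n/(n−1)·(1 − Σ p²) on haploid genome counts, valid for pools
    mixing diploid and haploid consensus genotypes (the pipeline default).
  - Multi-SNP RAD sites are collapsed by the maximum clipped per-position
    FST (mean and random-SNP aggregation available); negative values are
    rounded to zero.
- **Marker filtering**: per-site coverage gate (≥ 27 haploid genomes per
  population) and the minor-allele-count threshold *n* — a SNP is kept when
  its pooled minor allele occurs at least *n* times; *n* = 1 is the
  unfiltered analysis.
- **Genome-scan outputs**: the threshold sweep (SNP count and mean FST per
  *n* in 1..10), LOESS sliding-window profiles (2nd-order local polynomial,
  tricube weights, span 0.4), and the sister-RAD-site correlation
  diagnostic (FST agreement between the two tightly linked sites flanking
  the same restriction cut site, per threshold).
- **Synthetic data**: a two-population generator with a rare-allele-skewed
  site-frequency spectrum (calibrated singleton fraction), Balding–Nichols
  drift, exponential-decay hitchhiking displacement around selected
  regions, sister-site pairs with correlated drift, negative-binomial
  coverage and per-base sequencing error.

## Worked example

Two desk checks of θ on 2 × 20 diploids. A balanced polymorphism with
identical counts in both populations, and a nearly monomorphic locus with
a single heterozygote:

```r
library(radscan)
wc_theta(rbind(c(5, 10, 5), c(5, 10, 5)))   # TT/TC/CC in pops A and B
#> [1] -0.02631579
wc_theta(rbind(c(20, 0, 0), c(19, 1, 0)))
#> [1] 0
```

The first locus shows no differentiation (slightly negative, clipping to
zero); the second *cannot* show differentiation — its skewed frequency
distribution forces θ to zero even though a sweep may have shaped the
region.

The bias at genome scale, on synthetic data (27 diploids per population,
drift F = 0.05, ~45% singleton loci):

```r
cfg <- sim_config(seed = 1, n_rad_sites = 20000, drift_F = 0.05,
                  singleton_fraction_target = 0.45, chromosome_length = 2e7)
tab <- add_fst(sim_snp_table(simulate_populations(cfg)), "haplotype")
threshold_sweep(tab, c(1, 2, 4, 10))
#>    n snp_count   mean_fst
#>    1      4426 0.01188893
#>    2      2351 0.02238213
#>    4       897 0.04018862
#>   10       147 0.06075696
```

Excluding singletons (*n* = 2) removes 46.9% of the SNPs and nearly
doubles the genome-wide mean FST; the unfiltered mean (0.012) sits far
below the drift level the data were simulated at, while filtered means
approach it. The `analysis/` directory steps through the whole chain as
numbered scripts — simulation (`01`), read-stack genotyping (`02`),
per-SNP FST (`03`), the threshold sweep (`04`), smoothed profiles over a
simulated hitchhiking region (`05`, peak height 0.43 at *n* = 1 vs 0.52
at *n* = 4), and the sister-site diagnostic (`06`, mean pair correlation
rising from 0.31 at *n* = 1 to 0.40 at *n* = 4):

```sh
Rscript analysis/01_simulate.R 1   # argument = seed
Rscript analysis/02_genotype.R 1
...
```

Each writes its tables under `results/`.

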