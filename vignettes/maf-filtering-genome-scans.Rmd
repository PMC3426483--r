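---
title: "Minor-allele-count filtering in FST genome scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor-allele-count filtering in FST genome scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

Genome scans compare many marker loci between two populations and interpret
loci (or genomic regions) of elevated differentiation as candidates for
divergent selection. FST, however, responds not only to differentiation but
also to the allele-frequency distribution at the marker. A locus that is
nearly monomorphic in the pooled sample — in the extreme, a *singleton*,
whose minor allele occurs exactly once — is arithmetically constrained to an
FST near zero no matter how much drift or hitchhiking the surrounding region
has experienced. Because natural populations carry a large excess of
rare-allele polymorphisms, retaining such "uninformative" markers deflates
the genome-wide FST baseline and flattens sliding-window differentiation
profiles, hiding real selection signals. `radscan` implements the full
analysis chain needed to demonstrate and correct this: consensus genotyping
of RAD read stacks, two per-site FST estimators, a minor-allele-count filter
swept over thresholds, LOESS differentiation profiles, and a sister-RAD-site
reproducibility diagnostic — together with a synthetic-data generator that
reproduces the relevant statistical structure of two-population RAD data.

## Consensus genotyping of read stacks

RAD sequencing yields, per individual and RAD site, a stack of replicate
reads. Genotyping proceeds in three steps:

1. **Base-quality masking** (`filter_bases`): bases whose calling-error
   probability exceeds 0.01 are excluded (strict inequality; a base at
   exactly 0.01 is kept).
2. **Depth rule** (`call_consensus`): with ten or more quality-passing
   reads the consensus is diploid; below ten it is haploid (majority base
   per position). The cutoff reflects the power of the heterozygote test:
   at depth 9 even a 9:0 split cannot be distinguished reliably.
3. **Heterozygote test** (`het_test`): at each position of a diploid stack
   the two most frequent bases enter a binomial test of the null hypothesis
   of heterozygosity (success probability 0.5 for each allele). The
   position is called heterozygous when the binomial *point probability* of
   the observed split exceeds 0.01. At depth 10 this makes a 9/1 stack
   homozygous (10/1024 < 0.01) but an 8/2 stack heterozygous
   (45/1024 > 0.01).

Interpretation choices the source description leaves open, resolved here:
the "likelihood" is the binomial pmf of the observed split, not a tail
probability (it is the likelihood of a single observed outcome); the
depth-10 rule counts quality-passing reads per site (the masking step is
explicitly part of the test's input); at positions with more than two
distinct bases the two most frequent enter the test and the rest are
treated as presumptive errors; ties are broken by the lower summed
error probability, then alphabetically, so calls are deterministic.

## FST estimators

Two per-position estimators are provided.

**Weir–Cockerham theta** (`wc_theta`) for two populations of diploid
genotypes at a biallelic locus, from the variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals), using observed heterozygote frequencies:
$\hat\theta = a/(a+b+c)$, unclipped. Two desk checks pin the
implementation down: populations with identical balanced genotype counts
(5/10/5 vs 5/10/5) give $\hat\theta = -0.026$, and 20/0/0 vs 19/1/0 gives
exactly 0 (the $a$ and $b$ components vanish identically). The test suite
additionally cross-checks against an independent hierarchical-ANOVA
implementation on 1,000 random tables to 1e-12.

**Haplotype-diversity FST** (`haplotype_fst`) operates on haploid genome
counts — a diploid consensus contributes two genomes, a haploid one — which
is why it is the pipeline default for mixed-ploidy consensus pools:
$F_{ST} = (H_T - H_S)/H_T$, with $H = \frac{n}{n-1}(1 - \sum_k p_k^2)$ the
unbiased haplotype diversity (equal to the probability that two genomes
drawn without replacement differ), $H_S$ the average within-population
diversity and $H_T$ the pooled diversity.

**H_S weighting (design choice).** With $H_S$ weighted by genome counts, a
pooled singleton yields $F_{ST} = 0$ exactly for *every* placement: the
within diversity of the population carrying the singleton is $2/m_1$, so
the weighted mean is $2/(m_1+m_2) = H_T$. The unweighted mean instead gives
$(m_1 - m_2)/(2 m_1)$ — up to 0.16 for the coverage-imbalanced pools this
pipeline produces — which would contradict the defining property that
near-monomorphic loci cannot display appreciable differentiation. The
genome-count-weighted form is therefore the default; `hs_weighting =
"unweighted"` and `unbiased = FALSE` remain available as alternative slots
of the diversity partition.

The two estimators agree closely at moderate allele frequencies (within
0.05 for a frequency difference of 0.2 when both frequencies lie in the
central range) but diverge by construction near fixation, where
variance-component estimators run roughly twice the $G_{ST}$-family value;
the cross-estimator sanity test is accordingly confined to the central
band.

**Aggregation.** RAD sites with multiple SNPs are collapsed to one record
(`scan_rad_site`): each variable position is evaluated, each raw value is
clipped at zero, and the maximum is retained (mean and random-SNP
aggregation are available and give similar results). Clipping precedes
aggregation; for the max rule the order is immaterial whenever any position
is non-negative. The record's position is that of the SNP attaining the
maximum, leftmost on ties.

## Marker filtering

A RAD site enters the analysis only if each population contributed at
least 27 haploid consensus genomes (`coverage_gate`) — one genome per
sampled individual on average. A SNP is *informative at threshold n* if
its minor allele, defined on the pooled two-population sample, occurs at
least $n$ times (`minor_allele_gate`); $n = 1$ is the unfiltered analysis.
At an exact 50/50 split either allele counts as minor. The gate applies
per variable position before per-site aggregation, so a site's FST at
threshold $n$ uses only positions passing $n$. Passing sets are nested in
$n$, and raising $n$ from 1 to 2 removes exactly the singleton loci — an
identity the sweep bookkeeping tests exploit.

## Threshold sweep, profiles, sister diagnostic

`threshold_sweep` reports, for each $n$ in 1..10, the surviving SNP count
and the mean clipped FST; the mean is taken over per-site aggregated
values by default (per-SNP averaging is a flag, and with the generator's
one-SNP-per-site default the two coincide).

`loess_profile` smooths per-site FST along a chromosome by local
polynomial regression: 2nd-order polynomial, tricube weights, no
robustness iterations, with the *span* — the fraction of records in each
local neighborhood, 0.4 by default — interpreted in the R convention of
that smoother. Exact (direct-surface) fitting is used rather than
interpolation so the tests can compare against an independently coded
local-regression oracle to 1e-6. Profiles are evaluated at every record
position plus a uniform 1-kb grid, never across chromosome boundaries;
when fewer than degree + 2 records exist the degree falls back with a
warning, and the span is widened as needed so each neighborhood holds
enough points for the fit.

`sister_correlation` implements the filtering guideline: the two RAD sites
flanking the same restriction cut site are tightly physically linked, so
if a marker's FST reliably measures the consequences of drift and
selection in its region, its sister should show a similar value. The
Pearson correlation of per-site FST across sister pairs, tracked as $n$
rises, indicates how stringent filtering must be before marker FST becomes
reproducible; it is reported per threshold with the pair count, and
requires at least 10 complete pairs (and substantial differentiation) to
be meaningful.

## The synthetic-data generator

`simulate_populations` generates the statistical structure the argument
needs, not a full coalescent:

- **Site-frequency spectrum**: ancestral frequencies follow a discretized
  neutral spectrum (derived count $i$ out of the pooled genome number with
  probability $\propto 1/i$), optionally mixed with a near-fixed point
  mass (ancestral frequency $0.5/G$). When `singleton_fraction_target` is
  set, the mixing weight is calibrated by Monte Carlo from a dedicated RNG
  substream so the realized fraction of polymorphic loci that are
  singletons hits the target (±0.02 at 20,000 sites). The default target
  in the analysis scripts, 0.45, matches the singleton excess typical of
  population samples of this size.
- **Drift**: population frequencies are Balding–Nichols beta draws around
  the ancestral frequency with parameter `drift_F` (0.05 in the baseline
  analyses — a plausible drainage-scale baseline). Sampling goes through
  the inverse CDF so that sister sites can share correlated Gaussian-copula
  quantiles (`sister_cor`, default 0.9; 0.95 in the diagnostic analyses) —
  the "shared locus effect plus site-level noise" that makes linked markers
  informative about each other.
- **Hitchhiking**: inside a selected region the two population frequencies
  are displaced additively in opposite directions by
  $\text{max\_effect} \cdot e^{-\text{decay} \cdot d}$ at distance $d$ from
  the center (0.8 and 2e-5 per bp in the scan analyses, a ~50-kb-scale
  sweep footprint). Displacements that leave [0, 1] are clamped with a
  warning, or fail under `strict = TRUE`.
- **Genotypes and reads**: individuals are binomial draws from their
  population frequency (27 diploids per population by default). Read
  depth per individual and site is negative-binomial (means 27 and 31 per
  population, dispersion 5 — the overdispersion typical of RAD libraries);
  reads copy one of the two haplotypes uniformly; each base is miscalled
  with its per-base error probability to a uniformly chosen other base.
  Error probabilities are a two-point mixture (a typical rate, default
  0.001, plus a small fraction of low-quality bases at 0.1) so the
  quality-masking step has something real to remove; the attached
  error-probability matrices are exactly the ones the miscall process
  used.
- **Reproducibility**: one root seed; each stage (population simulation,
  read simulation, calibration, random aggregation) draws from its own
  derived substream, so stages are individually reproducible and
  byte-identical under a fixed seed.

What the generator does *not* emulate: linkage disequilibrium beyond the
sister-pair copula and the deterministic sweep displacement, recombination
maps, demographic history, PCR duplicates, alignment error, and
reference-genome artifacts. Passing tests therefore show that the
analysis chain behaves correctly on data with the assumed spectrum, drift
and coverage structure — not that real data meet those assumptions.

`hitchhiking_scenario` encodes the three canonical marker/QTL linkage
cases: (A) rare marker allele unlinked to the favored QTL allele — the
sweep is invisible at the marker and FST stays near zero before and after
selection; (B) rare marker allele linked to the favored allele — it
hitchhikes to high frequency and the marker differentiates strongly;
(C) balanced marker — identical counts before selection (FST clips to
zero) and clear differentiation after. Exact frequencies are configurable;
the cases are qualitative orderings, not printed values.

## Numerical choices and degenerate inputs

- Negative raw FST clips to zero (`clip_fst`) before aggregation and
  averaging, as is conventional.
- Monomorphic pools make both estimators undefined: `wc_theta` and
  `haplotype_fst` raise errors, and the site emits no record.
- Theta on mixed-ploidy pools uses diploid individuals only (it requires
  heterozygote counts); the haplotype estimator is the default for such
  pools.
- Internal coordinates are 1-based inclusive; BEDGRAPH-style exports are
  0-based half-open, with the conversion unit-tested.
- Missing data are explicit (`NA`/absent), never a sentinel allele.

## Problem sizes in the tests and analyses

The analysis scripts and test suite use 20,000 RAD sites for spectrum and
sweep work, 1,000 sites per replicate (100 replicates) for the profile
comparisons, 2,000 sites (1,000 sister pairs, 50 replicates) for the
diagnostic, and ~1,000–2,000 site-individuals for read-stack genotyping
checks; these sizes give stable Monte Carlo estimates for every property
tested while keeping each script in the seconds-to-minutes range.

## Known limitations

- Only two populations; the multi-population generalization of theta is
  out of scope.
- The simulator's hitchhiking model displaces frequencies
  deterministically; it reproduces the *shape* of a sweep footprint but
  not the stochastic variance of real hitchhiking.
- The sister diagnostic needs substantial baseline differentiation;
  at low `drift_F` the correlation stays weak at every threshold, as it
  does in real data.
- No formal outlier tests (Bayesian FST outlier methods, coalescent
  baselines) are included; the package produces the filtered inputs such
  methods would consume.
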