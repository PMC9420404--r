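---
title: "Methods: pooled-MAF / F_ST genome scans with poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-MAF / F_ST genome scans with poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scan in one paragraph

`poolsweep` looks for genomic regions where natural selection has shaped
variation in a focal population that was sequenced as a pool, using a set of
individually genotyped congener species as the comparative background. Two
window statistics carry the signal: the mean pooled minor allele frequency
(MAF), which measures polymorphism within the focal pool, and the windowed
Weir–Cockerham fixation index F\_ST with each species treated as one
population, which measures differentiation among species. Consecutive
windows that sit jointly in the low-MAF/high-F\_ST corner of the
two-dimensional distribution are candidate selective sweeps; consecutive
windows in the opposite corner (high polymorphism, low differentiation) are
candidates for balancing or frequency-dependent selection.

## Pooled MAF from read counts

For a pool, allele frequencies are estimated directly from per-site read
counts rather than called genotypes. At each site the major allele is the
one with the most reads and the MAF is the summed frequency of all
non-major alleles, so multiallelic sites are handled by the same rule. Two
filters guard the estimator:

* `min_depth = 15` reads — below this the binomial sampling noise of
  pool-seq dominates any real frequency signal;
* `min_variant_reads = 2` — a site whose non-major alleles are supported by
  a single read is indistinguishable from a sequencing error and is
  discarded (status `singleton_variant`) rather than averaged in.

Sites with adequate depth and zero variant reads get status `monomorphic`.
Whether such sites should enter the window average is genuinely ambiguous
when the MAF is computed "without regard to whether a site was called a
variant": including them as MAF 0 shrinks every window mean toward zero by
an amount that depends on local SNP density. The package supports both
conventions via `include_monomorphic`; the default (`FALSE`) averages over
polymorphic sites only, which keeps the window mean interpretable as the
typical frequency of a segregating site. Because both MAF and its outlier
thresholds are computed under the same convention, the ranking of windows —
which is all the empirical scan uses — is very similar either way.

When two alleles tie for the major count the lexicographically smallest is
taken as major. The choice never affects the MAF value; it only makes the
reported major allele deterministic.

## Variant retention

Genotype-based statistics use only biallelic SNPs at the caller's maximum
quality (`max_qual = 999`, the programmatic ceiling of common callers; the
filter compares against a configurable maximum rather than a hard-coded
number). Indels are never used, and SNPs within 3 bp of a called indel are
removed because alignment in indel neighborhoods is unreliable. The
proximity rule is interpreted as |SNP pos − indel anchor pos| ≤ 3, the
simplest reading, and is applied against every called indel including
low-quality ones — a called indel marks the local alignment as suspect
regardless of its own quality score. This keeps the filter idempotent.

## Weir–Cockerham F\_ST

Per site, the package computes the three variance components of the
Weir & Cockerham (1984) diploid estimator — `a` among populations, `b`
among individuals within populations, `c` within individuals (the observed
heterozygosity term) — from sample sizes, allele frequencies and observed
heterozygote frequencies per population. The per-site estimate
θ̂ = a/(a+b+c) is kept unclamped: negative per-site values are estimator
noise and must be retained so that window sums stay unbiased.

The windowed statistic is the ratio of sums Σa / Σ(a+b+c) over the window's
polymorphic sites ("weighted" F\_ST, the headline output of the usual
command-line tools), with `min_fst_sites = 100` variant sites required per
window; the mean of per-site ratios is available by `fst_method = "mean"`
for comparison. Windows below the site minimum are reported as undefined
and are excluded from the joint outlier analysis, which uses only windows
with both statistics defined.

The focal pool enters the species-level F\_ST as a single pseudodiploid
sample forming its own population: segregating pool sites (both alleles at
`min_variant_reads` or more reads) are coded heterozygous, others
homozygous for the majority allele. Sites where fewer than two populations
are called, or where the mean per-population sample size does not exceed
one, are skipped.

## Windows

Windows are 50 kb with a 25-kb step by default, addressed by their start
coordinate, 0-based half-open internally (VCF positions are converted on
read). Averaging over large windows is what makes the noisy per-site pooled
MAF usable: stochastic sampling error averages out while sweep-scale
signals, which span many kb, remain. A site falling in two overlapping
windows contributes to both. The tiling emits windows at 0, step, 2·step, …
and stops at the first window truncated by the scaffold end: later starts
would lie wholly inside sequence that window already covers. A scaffold
shorter than one window therefore yields a single truncated window, and a
non-overlapping tiling (step = size) covers every bp exactly once.

## The joint outlier procedure

Identifying "visual outliers in a two-dimensional plot" is operationalized
with two thresholds so that no human inspection is needed:

1. **run membership** — a window is flagged for a mode if both statistics
   lie beyond their `run_tail = 5%` empirical quantiles in the mode's
   directions (sweep: MAF low *and* F\_ST high; balancing: MAF high *and*
   F\_ST low);
2. **runs** — at least `min_run = 2` consecutive flagged windows of one
   mode form a candidate region (the weakest reading of a
   consecutive-window requirement; configurable). Consecutiveness is over
   the ordered tiling, so a window with no estimate (typically a
   repeat-masked stretch) breaks a run;
3. **confirmation** — a region is reported only if at least one member
   window lies beyond the `extreme_tail = 1%` quantiles of both
   distributions.

Quantiles are empirical with linear interpolation (type 7), computed
genome-wide over all analyzed windows — the tails of a single pooled
distribution, not per-scaffold tails. Comparisons against a threshold are
strict, so a degenerate constant distribution flags nothing. Region spans
are the union of member-window intervals; gene overlap is any shared bp
under half-open coordinates, so a gene starting exactly at a region end
does not overlap.

Because both statistics are empirical ranks, the procedure controls the
*fraction* of the genome reported, not an error rate; the consecutive-run
and 1%-confirmation requirements are what push the background expectation
far below one region per thousand windows. It is worth stating the measured
background behavior at the default conditions (40-Mb genome, ~1,580
analyzed windows): about 10% of null replicates emit one minimal
two-window false region (≈ 0.06 false regions per 1,000 background
windows). Two correlations inflate the joint tail beyond the naive
independence product: 50%-overlapping neighbor windows share half their
sites, so a single noisy 25-kb stretch can flag two consecutive windows at
once; and the window MAF and F\_ST are computed from the same pool reads,
so a downward fluctuation in pool variant reads simultaneously lowers MAF
and raises F\_ST (the pool is more often coded homozygous), enriching
specifically the sweep-direction corner. Both correlations are intrinsic
to the design — the real study's statistics share the same pool library —
so reported two-window regions with a single marginal extreme member
deserve skepticism, while the planted-signal regions in the same
conditions span 6–7 windows with several extreme members.

## IBS phylogeny

The sample-relatedness check uses identity by state over called SNP
dosages: per comparable site IBS = (2 − |d_i − d_j|)/2, distance = 1 − mean
IBS, with pairwise-complete site sets (how missing genotypes entered such
published IBS computations is typically unstated; pairwise-complete is the
convention here and each pair's comparable-site count is reported).
Neighbor joining uses the Studier–Keppler formulation (via `ape::nj`) with
negative branch estimates clamped to zero at output. Node support comes
from resampling sites with replacement, recomputing distance and tree, and
counting each reference bipartition among replicate trees as unrooted
splits. Pools enter as pseudodiploids, which exaggerates their terminal
branch lengths (every segregating site looks heterozygous) but leaves the
topology informative.

## The synthetic-data generator

The generator emulates the statistical structure the scan assumes, not the
sequencing process. Its defaults are the study conditions used throughout
the package's tests:

| parameter | default | meaning |
|---|---|---|
| `n_scaffolds` × `scaffold_length` | 20 × 2 Mb | genome size (40 Mb) |
| `n_species`, `individuals_per_species` | 4, 2 | congener design |
| `pool_chromosomes` | 48 | 24 diploids in the focal pool |
| `species_divergence` | 0.1 | per-branch drift variance |
| `pool_branch_scale` | 0.1 | pool branch, fraction of a species branch |
| `snp_density` | 0.005/bp | ~250 SNPs per 50-kb window |
| `mean_depth`, `depth_dispersion` | 40, 0.2 | pool depth model |
| `sweep_maf_ceiling` | 0.02 | focal folded MAF inside sweeps |
| `sweep_fst_floor` | 0.6 | focal-vs-congener separation inside sweeps |
| `balancing_shrink` | 0.15 | pull toward 0.5 inside balancing regions |

Ancestral frequencies are uniform on (0.05, 0.95); each branch of the fixed
balanced tree ((A,B),(C,D)) adds truncated-Gaussian drift (exact
inverse-CDF sampling, so frequencies stay in [0,1] without boundary
atoms), and the focal pool branches off species A with a short branch.
Pool depth is negative-binomial (the overdispersion typical of real
coverage; Poisson in the zero-dispersion limit), the realized pool
frequency is a binomial draw of `pool_chromosomes` chromosomes, and
variant reads are binomial in the realized frequency. Individuals are
Hardy–Weinberg draws of their species frequency.

Planted sweeps set the focal lineage to a folded frequency at most
`sweep_maf_ceiling` and push every other species at least `sweep_fst_floor`
away; planted balancing regions pull all lineages toward 0.5. The defaults
are strong, desk-scale analogues of a hard sweep and of long-term balancing
selection.

What the generator does **not** model: linkage structure within regions
(sites are independent given the planted pattern), read-level errors and
mapping bias, indels, demographic history of the focal population
(bottlenecks, admixture), or unequal scaffold lengths. Passing tests
therefore demonstrate that the estimators and the outlier logic are
correct and well calibrated under the assumed sampling model — not that
the scan is robust to demography or linked selection in real data, where
the empirical-quantile design is precisely what absorbs (but cannot
remove) such genome-wide confounds.

## Numerical and design choices

* All randomness in a pipeline run flows from one `seed`; stage-specific
  seeds are derived deterministically, and outputs are written with fixed
  number formatting, so a run is byte-identical under a fixed seed.
* Statistics at the window level are plain doubles; the acceptance between
  implementation and the mean-squares oracle is at 1e-12, far below any
  biological signal.
* Undefined statistics propagate as `NA` and are never silently zeroed.
* The interface is R functions (`run_config()` + `run_scan()`) rather than
  a shell executable: every artifact the pipeline writes is a plain-text
  table that downstream shell tools can consume, and the R surface
  composes better with simulation studies, which is the package's main
  use.
* Test problem sizes: unit tests run on 0.4-Mb scaffolds (thousands of
  sites); the end-to-end calibration and recovery checks run the full
  default conditions (20 × 2 Mb, ~200,000 sites per replicate, 10 planted
  and 20 null replicates) — chosen as the smallest scale at which the
  windowed statistics operate exactly as at genome scale.

## Worked example

```{r, eval = FALSE}
library(poolsweep)
cfg <- run_config(
  sim = sim_config(
    sweep_regions = data.frame(scaffold = c(1, 3), start = 5e5, end = 6.5e5),
    balancing_regions = data.frame(scaffold = 2, start = 1e6, end = 1.15e6)),
  out_dir = "scan_out", seed = 42)
res <- run_scan(cfg)
res$regions[, c("scaffold", "start", "end", "type", "n_windows", "genes")]
res$summary
```

## Limitations

The scan is empirical: it reports the most extreme joint tails of one
genome's window distribution and cannot attach a false-positive rate or an
effect size to a region. Regions of low recombination, segmental
duplication or residual assembly error produce the same joint signatures
as selection and must be excluded by the coverage diagnostics
(`relative_window_depth`) and by inspection. The pseudodiploid coding makes
the pool's branch length on the IBS tree incomparable to individual
branches. The simulator's independence of sites means power estimates on
synthetic data are optimistic relative to linked real genomes.
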