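---
title: "Haplotype allelic classes and the Svd sweep test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype allelic classes and the Svd sweep test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacsweep)
```

## The statistic

An ongoing (incomplete) selective sweep drags the haplotype that carries the
selected allele to high frequency faster than mutation and recombination can
diversify it. `hacsweep` detects this signature through *haplotype allelic
classes* (HAC): over a window of `S` SNPs, each haplotype is assigned the
Hamming distance between itself and the window-local *major-allele reference
haplotype* (MARH), the artificial haplotype carrying the majority allele at
every SNP. Haplotypes riding a sweep are structurally close to the MARH, so
their HAC values cluster near zero.

At an evaluated SNP `k` the sample of `n` haplotypes splits into `R_k`, the
carriers of the major allele (the allele on the MARH at `k`), and `r_k`, the
carriers of the minor allele. With `V̂(·)` the sample variance of the HAC
values in a sub-sample,

    vd_k  = V̂(r_k) − V̂(R_k)
    Svd_k = f_d,k × vd_k / S

where `f_d,k` is the derived allele frequency of SNP `k` in the analyzed
sample. Under a sweep the selected (major, derived) allele sits on
near-identical haplotypes, `V̂(R_k)` collapses, and `Svd` is large and
positive; under neutrality `vd_k` is near zero, or negative when `R_k` is
much the larger class. The division by `S` makes values comparable across
window sizes because the HAC variance grows at most linearly in `S` (the
package tests verify this empirically on simulated windows); the weight
`f_d,k` focuses the test on *derived* alleles driven to high frequency, the
configuration of interest, and downweights high-frequency ancestral alleles.

The test rejects neutrality when `Svd` exceeds a critical value `c` with
`Pr(Svd ≥ c | null) = p` (`p = 0.05` throughout), calibrated on simulations
of the matched null model. Power is the proportion of sweep simulations with
`Svd > c` (strictly greater, mirroring the two defining inequalities, which
deliberately differ).

### Numerical conventions

* **Variance denominator.** The estimator uses the conventional unbiased
  sample variance (denominator `n − 1`); a denominator-`n` variant is
  available through the `denominator` argument since both are consistent and
  asymptotically normal. All variance computation is in double precision;
  package tests compare against a brute-force two-pass oracle at 1e-12
  relative tolerance.
* **Undefined statistics.** When either sub-sample holds fewer than two
  haplotypes the variance, and hence `Svd`, is undefined. Such sites are
  flagged (`defined = FALSE`) and *excluded* from null and alternative
  distributions, scans, and p-value computations — never silently zeroed,
  which would bias the calibration.
* **MARH ties.** At sites with both alleles exactly at frequency 0.5 the
  reference takes the ancestral allele. Any deterministic rule works; this
  one favours the derived-major configuration the weighting already targets
  and keeps runs reproducible. Tie sites are recorded on the `marh` object.
* **Evaluated site's own column.** The evaluated SNP is part of the
  `S`-SNP haplotype and contributes to the HAC by default
  (`include_evaluated = TRUE`). Exclusion is available for sensitivity
  analysis, e.g. to mimic a per-SNP analysis "in the context of the
  remaining SNPs".
* **Window edges.** Scans skip SNPs that lack a full centred window rather
  than truncating the window, so the `/S` normalization stays comparable
  along a track. For even `S` the centre is 0-based index `floor(S/2)`.

## The simulator

All power numbers in this package are Monte Carlo estimates over coalescent
simulations, generated by an internal Hudson-style ancestral recombination
graph engine (ancestral material tracked as per-lineage segment lists with
sample-set bitmasks; mutations dropped on each lineage when it dies). Time
is scaled in units of `2 Ne` generations; `theta` and `rho` are the
population-scaled rates `4 Ne mu` and `4 Ne r` for the whole locus.

The default study conditions are those used throughout the package's
validation: samples of `n = 50` haplotypes at `theta = 223` (about 1,000
SNPs per replicate, matching Watterson's expectation — verified by the test
suite), constant population size with `Ne = 1000`, no recombination, and an
ongoing sweep that has brought the selected allele to frequency `f = 0.75`
under selection coefficient `s = 0.15`. `Ne = 1000` is the scale implied by
the companion small/large population variants (500 and 2,000); the locus is
50 kb by default, chosen so that a hotspot placed 2 kb downstream of the
evaluated site remains interior with room for the window.

### Sweeps

Selection scenarios use a two-background structured coalescent driven by the
population frequency trajectory of the selected allele, at one-generation
resolution. Within the derived (selected) background of current frequency
`X(t)`, pairs coalesce at rate `1/X(t)`; within the ancestral background at
rate `1/(1 − X(t))`. Recombination moves the piece of a lineage that does
not contain the selected position into a background drawn from `X(t)`; for
this purpose a lineage's recombination span is extended to cover the
selected position, so escape between the focal site and the ancestral
material is modelled. When the trajectory reaches a single copy, remaining
derived lineages coalesce into the mutation's origin, which then joins the
ancestral background; the neutral phase continues under the configured
demography.

Trajectories are stochastic by default: exact Wright–Fisher forward
simulations from one copy in `2 Ne` chromosomes, with additive fitnesses
`1, 1 + s/2, 1 + s`, restarted until the allele reaches `f` (first
passage), then reversed. Whether the original study's sweep engine used
stochastic or deterministic trajectories is not stated; we default to
stochastic as the fuller model and provide the deterministic logistic decay
as an option (`trajectory = "deterministic"`). The number of derived
carriers in the sample is Binomial(`n`, `f`), i.e. the conditioning is on
the *population* frequency.

### The matched null

Critical values are calibrated on simulations "identical in every parameter
except the selection coefficient, set to zero". With a frequency-conditioned
sweep simulator this means the null *keeps the conditioning*: `s = 0` with
`f` set yields a neutral allele currently at frequency `f`, its backward
trajectory following the neutral diffusion conditioned on loss (drift
`−x/2Ne` per generation). This matters a great deal. The evaluated site then
carries a derived allele at the same frequency under null and alternative,
so the calibration absorbs what is merely "a high-frequency derived allele
exists here" and the test measures the sweep's *haplotype* signature. An
unconditioned neutral calibration (random central SNP) yields a far lower
critical value and a test that is nearly always significant at a true sweep
— but one whose null no longer matches the alternative's ascertainment of
the evaluated site. `match_null()` therefore returns the scenario with
`selection$s = 0` and `f` retained, and `power_estimate()` structurally
refuses null/alternative pairs that differ in anything beyond `s` and the
seed.

### Demography and recombination

Bottleneck and expansion demographies are piecewise-constant size histories
(a 95% reduction lasting 80 generations that ended 260 generations ago; an
ancestral size of 500 growing to 1,000 over the last 300 generations,
modelled as a step). Recombination maps are piecewise constant over the
locus; hotspots are intervals of width 2 kb (configurable) at a multiple of
the background rate, placed by their offset downstream of the evaluated
site. Infinite-sites positions are uniform on the locus; coincident draws
are separated by 1e-9 jitter.

### Problem sizes and reproducibility

The package's own validation uses the full published protocol: 1,000
matched-null plus 1,000 sweep replicates per scenario (500 + 500 for the
strong-hotspot scenario, whose ancestral graphs are several times more
expensive; the acceptance tolerance is widened accordingly). At these sizes
a power estimate carries a binomial standard error of about 0.013 plus
comparable Monte Carlo noise from the calibrated critical value, so
repeated runs under different seeds scatter by a few percentage points.
Every replicate derives its own seed from the scenario's master seed and is
individually regenerable; replicates with too few SNPs on a flank for the
requested window are regenerated from a fresh derived seed and counted.

## Ascertainment emulation

Three ascertainment schemes, applied per replicate before window
extraction, emulate how genotyping data are collected. They only drop
sites; allele codes at retained sites are never altered, and the evaluated
site is never removed (it is the tested site; a warning, or an error in
strict mode, reports when it would have failed).

* `filter_by_maf(w, 3)` removes sites with minor-allele count below 3 —
  with `n = 50` exactly the singletons and doubletons (MAF < 0.05) that
  genotyping chips typically exclude. Removing them *raises* detection
  power: rare variants contribute HAC noise but little information, so the
  effective window widens.
* `panel_ascertain(w, m)` rediscoveries SNPs in a panel of `m` chromosomes
  drawn without replacement, then genotypes all `n`; at `m = n` there is no
  bias. A singleton survives with probability `m/n`.
* `spectrum_rejection_sample(w, target)` performs rejection sampling of
  sites so the derived-allele-frequency spectrum converges to a target
  histogram (25 equal-width bins by default; the binning is our choice, as
  is matching on the derived rather than the minor allele frequency, the
  natural unfolded reading). Used to match simulated replicates to the
  spectrum observed in real data before computing simulation-based
  p-values.
* `diploidize(w)` collapses the haplotypes into unphased diploid genotypes
  (recorded pairing, exact round trip) for export to external statistical
  phasing tools via a minimal VCF; statistical phasing itself is out of
  scope, and re-import goes through `read_phased()`.

## What the simulations do and do not establish

The generator reproduces the study conditions: equilibrium or simply
perturbed demographies, a single biallelic selected site, infinite-sites
mutation, known ancestral states, and phased haplotypes. Real data differ
in ways the tests deliberately do not cover: ancestral-allele
misassignment, genotyping error, statistical-phasing artefacts (which
narrow HAC distributions and are known to cost power), population
structure, and background selection. Passing the simulation-based checks
therefore validates the statistic's operating characteristics under its
own model, not its error rates on arbitrary real data; the scan's empirical
p-values (chromosome-wide ranks) and the candidate machinery's
simulation-matched p-values are the intended routes to inference on data.

## Comparison statistics

Tajima's `D` (1989 constants), the normalized Fay & Wu's `H` (unfolded
spectrum, `theta_H = Σ 2 S_i i² / (n(n−1))`, standardized with the Zeng
et al. 2006 variance using Watterson's `theta` and
`theta² = S(S−1)/(a1² + a2)`), and the *unstandardized* iHS
(`ln(iHH_A/iHH_D)`, EHH integrated by the trapezoid rule out to the window
edge or an EHH of 0.05, the Voight et al. convention — the truncation level
and integration rule are our choices, as the source does not restate them).
Sweeps on derived alleles push the unstandardized iHS negative; power
comparisons should use `|iHS|` or the appropriate one-sided tail, exposed
as a parameter since the tail convention used for the published power
comparison is not stated.

## Scanning and candidate loci

`sliding_scan()` moves the `S`-SNP window one SNP at a time, rebuilding the
MARH per window (the reference is always window-local). Empirical p-values
are upper-tail ranks against all defined `Svd` values of the track, ties
sharing the more conservative value; the top 1% of positive values are
flagged, and flagged SNPs within 20 indices (configurable — a reporting
convention, not an inference rule) merge into BED intervals.
`candidate_pvalues()` trims matched simulated replicates so the selected
SNP sits at the locus's putative target index and reports, per locus SNP,
the exceedance proportion of the simulated `Svd` distribution at the
corresponding index; spectrum matching, when wanted, is applied upstream.

## Known limitations

* The sweep engine models hard sweeps from a single new mutation; selection
  on standing variation, soft sweeps and forward-time simulation are out of
  scope.
* `Svd` targets *derived* alleles at major frequency; sweeps still below
  frequency 0.5 are largely invisible to it by construction.
* Sample-size limits: the bitmask engine supports any `n`, but power
  calibration assumes the null and alternative share `n`, `theta` and the
  map exactly — enforced, not checked statistically.
* Critical values from 1,000 replicates carry visible Monte Carlo noise in
  the heavy null upper tail; power estimates inherit it. Increase the
  replicate count for tighter operating points.
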