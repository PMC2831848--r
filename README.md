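# hacsweep

Detecting **ongoing (incomplete) selective sweeps** in phased haplotype data
with **haplotype allelic classes (HAC)** and the per-SNP **Svd** statistic.

When positive selection drives a new allele toward fixation, the haplotype
carrying it hitchhikes to high frequency largely intact. Over a window of
*S* SNPs, assign every haplotype its HAC: the Hamming distance to the
window-local *major-allele reference haplotype* (MARH), the artificial
haplotype composed of the majority allele at every SNP. At an evaluated SNP
*k* the sample splits into *R<sub>k</sub>* (carriers of the major allele,
the one on the MARH) and *r<sub>k</sub>* (the rest), and

> *vd<sub>k</sub>* = V̂(*r<sub>k</sub>*) − V̂(*R<sub>k</sub>*),
> **Svd** = *f<sub>d,k</sub>* · *vd<sub>k</sub>* / *S*

with V̂ the sample variance of the HAC values and *f<sub>d,k</sub>* the
derived allele frequency of SNP *k*. A sweep collapses V̂(*R<sub>k</sub>*)
and pushes Svd to large positive values; neutrality keeps it near zero or
negative. Significance comes from a critical value calibrated on matched
neutral simulations, or from chromosome-wide empirical ranks in a sliding
scan. The package is aimed at population geneticists who want a
haplotype-based sweep statistic that stays informative when recombination
has already broken the long-range haplotype that LD-based tests rely on.

The package provides, as first-class tested code:

* the HAC/MARH/Svd machinery (`haplotype_window`, `build_marh`,
  `svd_at_site`, ...);
* a coalescent simulator for the validation scenarios: constant size,
  bottleneck, expansion, uniform recombination and hotspot maps, and
  structured-coalescent sweeps conditioned on the current selected-allele
  frequency (`scenario_config`, `simulate_neutral`, `simulate_sweep`);
* SNP ascertainment emulation: MAF filtering, sequencing-panel discovery,
  spectrum-matching rejection sampling, diploidization
  (`filter_by_maf`, `panel_ascertain`, `spectrum_rejection_sample`,
  `diploidize`);
* comparison statistics: Tajima's D, normalized Fay & Wu's H,
  unstandardized iHS;
* calibration and power machinery with a structurally enforced matched-null
  rule (`critical_value`, `detection_power`, `power_estimate`,
  `power_fdr_curve`);
* a sliding-window genome scanner with empirical p-values, top-percentile
  clusters (BED output) and simulation-matched candidate-locus p-values
  (`sliding_scan`, `empirical_pvalues`, `candidate_pvalues`);
* ms-format and phased-VCF I/O plus a command-line front end
  (`inst/cli/hacsweep.R`).

## Worked example

Calibrate the test on a matched null and estimate its power under the
default ongoing-sweep scenario (50 haplotypes, Θ = 223, selected allele at
frequency 0.75 with s = 0.15; 200 replicates here for speed):

```r
library(hacsweep)
cfg <- scenario_config(n = 50, theta = 223,
                       selection = list(s = 0.15, f = 0.75), seed = 42)
alt <- simulate_sweep(cfg, 200)
nul <- simulate_sweep(match_null(cfg), 200)   # same scenario, s = 0
pe  <- power_estimate(nul, alt, S = 51)
pe$null
#> Null calibration of svd on 200 defined values ( 0 undefined dropped )
#>   c = 0.21347 at nominal p = 0.05 ; achieved Pr(>= c) = 0.05
pe$power
#> Detection power: 0.94 +/- 0.017 ( n = 200 , c = 0.21347 )
```

The null calibration reports the critical value `c` such that 5% of
frequency-conditioned neutral replicates reach it; the power is the
proportion of sweep replicates whose Svd exceeds `c` (at the full
1,000+1,000 protocol the estimate settles around 0.8). Per-replicate
anatomy of the statistic:

```r
w  <- alt$replicates[[1]]
ww <- extract_window(w, 51)    # 51 SNPs centred on the selected site
svd_at_site(ww)
#> Svd at site 26 : 0.6175  (vd = 41.44 , |R_k| = 38 , |r_k| = 12 )
```

38 haplotypes carry the selected (major) allele with a tight HAC
distribution, the 12 others are diverse: vd = 41.4, weighted and normalized
to Svd = 0.62, far above `c`. The comparison statistics on the same window
(`tajima_d(ww)` gives D = −1.12, `ihs_unstandardized(ww)` gives −1.31,
negative as expected for a derived-allele sweep) are available through the
same window objects, and `sliding_scan()` applies Svd along a chromosome.

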