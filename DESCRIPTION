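Package: hacsweep
Title: Haplotype Allelic Classes and the Svd Test for Ongoing Selective Sweeps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ongoing (incomplete) selective sweeps in phased haplotype
    data using haplotype allelic classes (HAC): the mutational distance of each
    haplotype from a window-local major-allele reference haplotype (MARH). The
    per-SNP Svd statistic contrasts the HAC variance of haplotypes carrying the
    minor allele with that of the major-allele carriers, weighted by the derived
    allele frequency and normalized by window size. Includes a coalescent
    simulator (constant size, bottleneck, expansion, uniform and hotspot
    recombination, and structured-coalescent sweeps conditioned on the current
    selected-allele frequency), SNP ascertainment emulation (MAF filtering,
    sequencing-panel discovery, spectrum-matching rejection sampling,
    diploidization), comparison statistics (Tajima's D, normalized Fay and Wu's
    H, unstandardized iHS), critical-value calibration and power estimation on
    matched neutral simulations, and a sliding-window genome scanner with
    empirical and simulation-based p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    rlang
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
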