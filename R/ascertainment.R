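# SNP ascertainment emulation: MAF filtering, sequencing-panel discovery,
# spectrum-matching rejection sampling and diploidization. These
# operations only drop or re-weight sites; allele codes at retained sites
# are never altered.

subset_sites <- function(window, keep) {
  keep <- sort(unique(keep))
  ev <- window$evaluated_index
  new_ev <- if (is.na(ev)) NA_integer_ else match(ev, keep)
  haplotype_window(window$alleles[, keep, drop = FALSE],
                   positions = window$sites$position[keep],
                   site_ids = window$sites$site_id[keep],
                   ancestral_allele = window$sites$ancestral_allele[keep],
                   derived_allele = window$sites$derived_allele[keep],
                   evaluated_index = new_ev,
                   require_segregating = FALSE)
}

#' Remove sites below a minor-allele count threshold
#'
#' Emulates MAF-based ascertainment: sites whose minor-allele count falls
#' below `min_minor_count` are dropped. With `n = 50`, removing singletons
#' and doubletons (`min_minor_count = 3`) removes exactly the sites with
#' MAF below 0.05. The evaluated site is never removed -- it is the tested
#' site -- but a warning (or an error in strict mode) is raised if it
#' fails the filter.
#'
#' @param window A [haplotype_window()].
#' @param min_minor_count Minimum minor-allele count to retain a site;
#'   `0` is the identity.
#' @param strict Error (rather than warn) when the evaluated site itself
#'   fails the filter.
#' @return A filtered [haplotype_window()] with `evaluated_index`
#'   remapped.
#' @export
filter_by_maf <- function(window, min_minor_count = 3L, strict = FALSE) {
  stopifnot(inherits(window, "hap_window"))
  if (min_minor_count < 0L) stop("min_minor_count must be non-negative")
  cnt <- colSums(window$alleles)
  minor <- pmin(cnt, window$n - cnt)
  keep <- which(minor >= min_minor_count)
  ev <- window$evaluated_index
  if (!is.na(ev) && !(ev %in% keep)) {
    msg <- paste0("evaluated site ", window$sites$site_id[ev],
                  " has minor-allele count ", minor[ev],
                  " below the filter threshold")
    if (strict) stop(msg)
    warning(msg, "; keeping it anyway")
    keep <- c(keep, ev)
  }
  if (!length(keep)) stop("no sites survive the MAF filter")
  subset_sites(window, keep)
}

#' Sequencing-panel SNP ascertainment
#'
#' Draws a discovery panel of `m` haplotypes without replacement and
#' retains only the sites segregating within the panel, returning all `n`
#' haplotypes restricted to the discovered sites. At `m = n` there is no
#' ascertainment bias. The panel is resampled independently per call, so
#' applying this to each replicate of a set uses a fresh panel each time.
#'
#' @inheritParams filter_by_maf
#' @param m Panel size, `2 <= m <= n`.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return An ascertained [haplotype_window()].
#' @export
panel_ascertain <- function(window, m, seed = NULL, strict = FALSE) {
  stopifnot(inherits(window, "hap_window"))
  if (m > window$n) stop("panel size m exceeds sample size n")
  if (m < 2L) stop("panel needs at least 2 chromosomes")
  if (!is.null(seed)) set.seed(seed)
  panel <- sample.int(window$n, m)
  cnt <- colSums(window$alleles[panel, , drop = FALSE])
  keep <- which(cnt > 0L & cnt < m)
  ev <- window$evaluated_index
  if (!is.na(ev) && !(ev %in% keep)) {
    msg <- paste0("evaluated site ", window$sites$site_id[ev],
                  " is monomorphic within the discovery panel")
    if (strict) stop(msg)
    warning(msg, "; keeping it anyway")
    keep <- c(keep, ev)
  }
  if (!length(keep)) stop("no sites segregate within the panel")
  subset_sites(window, keep)
}

#' Derived-allele frequency spectrum of a window
#'
#' @inheritParams filter_by_maf
#' @param n_bins Number of equal-width bins over (0, 1).
#' @return Numeric vector of bin proportions (sums to 1).
#' @export
frequency_spectrum <- function(window, n_bins = 25L) {
  stopifnot(inherits(window, "hap_window"))
  b <- seq(0, 1, length.out = n_bins + 1L)
  h <- findInterval(window$sites$derived_freq, b, rightmost.closed = TRUE,
                    all.inside = TRUE)
  tabulate(h, nbins = n_bins) / window$S
}

#' Spectrum-matching rejection sampling of sites
#'
#' Accepts each site with probability proportional to the ratio of the
#' target to the source derived-allele-frequency bin density, rescaled so
#' the largest acceptance probability is 1. As the number of sites grows,
#' the accepted spectrum converges to the target. Bins requested empty by
#' the target get acceptance 0. The evaluated site, when set, is always
#' retained.
#'
#' @inheritParams panel_ascertain
#' @param target_spectrum Numeric vector of bin masses over (0, 1) (equal
#'   width, any normalization).
#' @return A [haplotype_window()] containing the accepted sites.
#' @export
spectrum_rejection_sample <- function(window, target_spectrum, seed = NULL) {
  stopifnot(inherits(window, "hap_window"))
  if (!is.null(seed)) set.seed(seed)
  n_bins <- length(target_spectrum)
  if (n_bins < 2L) stop("target spectrum needs at least 2 bins")
  if (any(target_spectrum < 0)) stop("negative target bin mass")
  tgt <- target_spectrum / sum(target_spectrum)
  src <- frequency_spectrum(window, n_bins)
  ratio <- ifelse(src > 0, tgt / src, 0)
  if (all(ratio == 0)) stop("no source sites fall in any requested bin")
  ratio <- ratio / max(ratio)
  b <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(window$sites$derived_freq, b, rightmost.closed = TRUE,
                      all.inside = TRUE)
  acc <- stats::runif(window$S) < ratio[bin]
  ev <- window$evaluated_index
  if (!is.na(ev)) acc[ev] <- TRUE
  if (!any(acc)) stop("rejection sampling removed every site")
  subset_sites(window, which(acc))
}

#' Collapse haplotypes into unphased diploid genotypes
#'
#' Randomly pairs the `n` haplotypes (without replacement) into `n/2`
#' individuals and sums the derived-allele codes, emulating the loss of
#' phase before statistical phasing. The pairing is recorded in the
#' `pairing` attribute so the genotypes can be reconstructed exactly.
#'
#' @inheritParams panel_ascertain
#' @return Integer matrix (`n/2` individuals by `S` sites) with codes
#'   0/1/2 and attributes `pairing` (2-column matrix of haplotype row
#'   indices) and `positions`.
#' @export
diploidize <- function(window, seed = NULL) {
  stopifnot(inherits(window, "hap_window"))
  if (window$n %% 2L != 0L) stop("diploidize needs an even number of haplotypes")
  if (!is.null(seed)) set.seed(seed)
  pairing <- matrix(sample.int(window$n), ncol = 2L)
  G <- window$alleles[pairing[, 1L], , drop = FALSE] +
    window$alleles[pairing[, 2L], , drop = FALSE]
  storage.mode(G) <- "integer"
  rownames(G) <- paste0("ind", seq_len(nrow(G)))
  colnames(G) <- window$sites$site_id
  attr(G, "pairing") <- pairing
  attr(G, "positions") <- window$sites$position
  G
}
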