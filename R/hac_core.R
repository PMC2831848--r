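# Core HAC machinery: haplotype windows, the major-allele reference
# haplotype, HAC distances/distributions, and the per-SNP Svd statistic.

#' Construct a haplotype window
#'
#' A haplotype window is an `n x S` matrix of phased alleles coded
#' 0 = ancestral / 1 = derived, together with per-site annotations and an
#' optional index of the evaluated SNP. It is the substrate every statistic
#' in the package operates on.
#'
#' @param alleles Integer matrix (`n` haplotypes by `S` sites) of 0/1 codes.
#' @param positions Numeric vector of length `S`, strictly increasing
#'   physical (bp) or relative coordinates.
#' @param site_ids Optional character vector of site labels.
#' @param ancestral_allele,derived_allele Optional character vectors of
#'   allele symbols per site (defaults `"A"`/`"G"` placeholders for
#'   simulated data).
#' @param evaluated_index Optional 1-based index of the evaluated SNP.
#' @param require_segregating If `TRUE` (default), every site must carry
#'   both alleles. Subsetting operations may legitimately produce
#'   monomorphic sites and set this to `FALSE`.
#' @return An object of class `hap_window` with elements `alleles`, `sites`
#'   (data frame with `site_id`, `position`, `ancestral_allele`,
#'   `derived_allele`, `derived_freq`, `minor_allele_freq`), `n`, `S`,
#'   `evaluated_index`.
#' @export
haplotype_window <- function(alleles, positions = seq_len(ncol(alleles)),
                             site_ids = NULL, ancestral_allele = NULL,
                             derived_allele = NULL, evaluated_index = NA_integer_,
                             require_segregating = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles); S <- ncol(alleles)
  if (S < 1L || n < 1L) stop("haplotype window must be non-empty")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be coded 0/1")
  if (length(positions) != S) stop("positions length must equal number of sites")
  if (S > 1L && any(diff(positions) <= 0)) {
    stop("site positions must be strictly increasing")
  }
  if (is.null(site_ids)) site_ids <- paste0("s", seq_len(S))
  if (is.null(ancestral_allele)) ancestral_allele <- rep("A", S)
  if (is.null(derived_allele)) derived_allele <- rep("G", S)
  dcount <- colSums(alleles)
  dfreq <- dcount / n
  if (require_segregating && any(dcount == 0L | dcount == n)) {
    bad <- site_ids[dcount == 0L | dcount == n][1L]
    stop("site ", bad, " is not segregating in this window")
  }
  if (!is.na(evaluated_index) &&
      (evaluated_index < 1L || evaluated_index > S)) {
    stop("evaluated_index out of range")
  }
  sites <- data.frame(
    site_id = as.character(site_ids),
    position = as.numeric(positions),
    ancestral_allele = as.character(ancestral_allele),
    derived_allele = as.character(derived_allele),
    derived_freq = dfreq,
    minor_allele_freq = pmin(dfreq, 1 - dfreq),
    stringsAsFactors = FALSE
  )
  structure(list(alleles = alleles, sites = sites, n = n, S = S,
                 evaluated_index = as.integer(evaluated_index)),
            class = "hap_window")
}

#' @export
print.hap_window <- function(x, ...) {
  cat("Haplotype window:", x$n, "haplotypes x", x$S, "sites\n")
  if (!is.na(x$evaluated_index)) {
    cat("Evaluated SNP:", x$sites$site_id[x$evaluated_index],
        "(index", x$evaluated_index, ", derived freq",
        signif(x$sites$derived_freq[x$evaluated_index], 3), ")\n")
  }
  invisible(x)
}

#' Recode a raw allele matrix into a 0/1 haplotype window
#'
#' Maps allele symbols onto ancestral (0) / derived (1) codes using per-site
#' ancestral annotations, recomputes derived allele frequencies from the
#' matrix, and rejects sites whose observed symbols do not match the
#' annotation.
#'
#' @param raw_alleles Character matrix (`n x S`) of allele symbols.
#' @param annotations Data frame with columns `site_id`, `position`,
#'   `ancestral_allele` and optionally `derived_allele`.
#' @inheritParams haplotype_window
#' @return A [haplotype_window()].
#' @export
encode_window <- function(raw_alleles, annotations, evaluated_index = NA_integer_) {
  raw_alleles <- as.matrix(raw_alleles)
  S <- ncol(raw_alleles)
  if (nrow(annotations) != S) stop("one annotation row per site required")
  coded <- matrix(0L, nrow(raw_alleles), S)
  derived <- character(S)
  for (j in seq_len(S)) {
    anc <- annotations$ancestral_allele[j]
    obs <- unique(raw_alleles[, j])
    if (!anc %in% obs) {
      stop("site ", annotations$site_id[j],
           ": ancestral allele ", anc, " not observed")
    }
    other <- setdiff(obs, anc)
    if (length(other) > 1L) {
      stop("site ", annotations$site_id[j], " is not biallelic")
    }
    if (length(other) == 0L) {
      stop("site ", annotations$site_id[j],
           " is not segregating (all haplotypes ancestral)")
    }
    if (!is.null(annotations$derived_allele) &&
        !is.na(annotations$derived_allele[j]) &&
        annotations$derived_allele[j] != other) {
      stop("site ", annotations$site_id[j], ": observed derived allele ",
           other, " does not match annotation")
    }
    derived[j] <- other
    coded[, j] <- as.integer(raw_alleles[, j] == other)
  }
  haplotype_window(coded, positions = annotations$position,
                   site_ids = annotations$site_id,
                   ancestral_allele = annotations$ancestral_allele,
                   derived_allele = derived,
                   evaluated_index = evaluated_index)
}

#' Build the major-allele reference haplotype (MARH)
#'
#' The MARH carries, at every site of the window, the allele with sample
#' frequency above 0.5. At ties (frequency exactly 0.5) the ancestral allele
#' is chosen and the site is recorded in `tie_sites`; a deterministic tie
#' rule keeps runs reproducible.
#'
#' @param window A [haplotype_window()].
#' @return Object of class `marh`: list with `alleles` (0/1 vector of
#'   length `S`) and `tie_sites` (integer indices).
#' @export
build_marh <- function(window) {
  stopifnot(inherits(window, "hap_window"))
  f <- window$sites$derived_freq
  ref <- as.integer(f > 0.5)
  ties <- which(f == 0.5)
  structure(list(alleles = ref, tie_sites = ties), class = "marh")
}

#' @export
print.marh <- function(x, ...) {
  cat("MARH over", length(x$alleles), "sites;",
      sum(x$alleles), "derived-major,", length(x$tie_sites), "tie site(s)\n")
  invisible(x)
}

ref_alleles <- function(reference) {
  if (inherits(reference, "marh")) reference$alleles else as.integer(reference)
}

#' HAC distance of one haplotype from a reference
#'
#' The haplotype allelic class (HAC) is the count of allelic differences
#' (Hamming distance) between a haplotype and the reference.
#'
#' @param haplotype Integer 0/1 vector of length `S`.
#' @param reference A `marh` object or 0/1 vector of the same length.
#' @return Integer in `[0, S]`.
#' @export
hac_distance <- function(haplotype, reference) {
  ref <- ref_alleles(reference)
  if (length(haplotype) != length(ref)) {
    stop("haplotype and reference lengths differ")
  }
  sum(as.integer(haplotype) != ref)
}

#' HAC distances for every row of a haplotype matrix
#'
#' @param haplotypes Integer 0/1 matrix (rows are haplotypes) or a
#'   `hap_window`.
#' @inheritParams hac_distance
#' @return Integer vector of per-haplotype HAC values.
#' @export
hac_distances <- function(haplotypes, reference) {
  if (inherits(haplotypes, "hap_window")) haplotypes <- haplotypes$alleles
  ref <- ref_alleles(reference)
  if (ncol(haplotypes) != length(ref)) {
    stop("haplotype and reference lengths differ")
  }
  as.integer(rowSums(haplotypes != matrix(ref, nrow(haplotypes),
                                          length(ref), byrow = TRUE)))
}

#' Sample estimator of the HAC variance
#'
#' Dispersion of the HAC values about their empirical mean. The default
#' denominator is `n - 1` (the conventional unbiased sample variance); a
#' denominator of `n` is available as an option since both estimators are
#' consistent and asymptotically normal.
#'
#' @param hac_values Integer vector of HAC values, length at least 2.
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Non-negative scalar.
#' @export
hac_variance <- function(hac_values, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- length(hac_values)
  if (m < 2L) stop("HAC variance is undefined for fewer than 2 haplotypes")
  v <- stats::var(hac_values)
  if (denominator == "n") v <- v * (m - 1) / m
  v
}

#' HAC distribution of a set of haplotypes
#'
#' Counts of haplotypes in each allelic class `0..S`, with the empirical
#' mean and (when at least two haplotypes are present) the variance
#' estimator.
#'
#' @param haplotypes 0/1 matrix of haplotype rows (or a `hap_window`).
#' @inheritParams hac_distance
#' @inheritParams hac_variance
#' @return Object of class `hac_distribution`: list with `counts` (length
#'   `S + 1`, class `c` at `counts[c + 1]`), `size`, `mean`, `variance`
#'   (`NA` when `size < 2`).
#' @export
hac_distribution <- function(haplotypes, reference,
                             denominator = c("n-1", "n")) {
  if (inherits(haplotypes, "hap_window")) haplotypes <- haplotypes$alleles
  if (is.null(dim(haplotypes))) haplotypes <- matrix(haplotypes, nrow = 1L)
  if (nrow(haplotypes) < 1L) stop("empty haplotype set")
  S <- length(ref_alleles(reference))
  h <- hac_distances(haplotypes, reference)
  counts <- tabulate(h + 1L, nbins = S + 1L)
  structure(list(counts = counts, size = length(h), mean = mean(h),
                 variance = if (length(h) >= 2L)
                   hac_variance(h, denominator) else NA_real_,
                 hac = h),
            class = "hac_distribution")
}

#' @export
print.hac_distribution <- function(x, ...) {
  cat("HAC distribution over", x$size, "haplotypes; mean", signif(x$mean, 4),
      if (!is.na(x$variance)) paste0("variance ", signif(x$variance, 4)) else
        "variance undefined (size < 2)", "\n")
  invisible(x)
}

#' Split window rows by the allele carried at a site
#'
#' Partitions the haplotypes into the sub-sample `R_k` carrying the
#' reference (MARH) allele at SNP `k` and the sub-sample `r_k` carrying the
#' other allele.
#'
#' @param window A [haplotype_window()].
#' @param k 1-based site index.
#' @param reference A `marh` (defaults to [build_marh()] of the window).
#' @return List with integer row indices `major` (`R_k`) and `minor`
#'   (`r_k`).
#' @export
split_by_allele <- function(window, k, reference = build_marh(window)) {
  stopifnot(inherits(window, "hap_window"))
  if (k < 1L || k > window$S) stop("site index out of range")
  refa <- ref_alleles(reference)[k]
  inR <- window$alleles[, k] == refa
  list(major = which(inR), minor = which(!inR))
}

#' HAC variance difference at an evaluated SNP
#'
#' `vd_k` is the HAC variance of the minor-allele carriers (`r_k`) minus
#' that of the major-allele carriers (`R_k`), both measured against the
#' window reference. Under an ongoing sweep the major (selected) allele
#' rides on near-identical haplotypes, the `R_k` variance collapses and
#' `vd_k` turns positive; under neutrality it is near zero or negative.
#' When either sub-sample has fewer than two haplotypes the statistic is
#' flagged undefined (never silently zeroed).
#'
#' @inheritParams split_by_allele
#' @param include_evaluated Should the evaluated SNP's own column
#'   contribute to the HAC distances? Default `TRUE` (it is part of the
#'   window haplotype); `FALSE` is provided for sensitivity analysis.
#' @inheritParams hac_variance
#' @return Object of class `site_svd`: list with `k`, `n_major`, `n_minor`,
#'   `var_major`, `var_minor`, `vd`, `svd` (`NA` here; see
#'   [svd_at_site()]), `defined`.
#' @export
vd_at_site <- function(window, k = window$evaluated_index,
                       reference = build_marh(window),
                       include_evaluated = TRUE,
                       denominator = c("n-1", "n")) {
  stopifnot(inherits(window, "hap_window"))
  if (is.na(k)) stop("no evaluated site: supply k or set evaluated_index")
  if (k < 1L || k > window$S) stop("site index out of range")
  denominator <- match.arg(denominator)
  parts <- split_by_allele(window, k, reference)
  use <- if (include_evaluated) seq_len(window$S) else setdiff(seq_len(window$S), k)
  refa <- ref_alleles(reference)[use]
  h <- hac_distances(window$alleles[, use, drop = FALSE], refa)
  out <- list(k = as.integer(k),
              n_major = length(parts$major), n_minor = length(parts$minor),
              var_major = NA_real_, var_minor = NA_real_,
              vd = NA_real_, svd = NA_real_,
              S_contrib = length(use), defined = FALSE)
  if (length(parts$major) >= 2L && length(parts$minor) >= 2L) {
    out$var_major <- hac_variance(h[parts$major], denominator)
    out$var_minor <- hac_variance(h[parts$minor], denominator)
    out$vd <- out$var_minor - out$var_major
    out$defined <- TRUE
  }
  structure(out, class = "site_svd")
}

#' The Svd statistic at an evaluated SNP
#'
#' `Svd = f_d,k * vd_k / S`: the HAC variance difference normalized by the
#' number of contributing SNPs `S` (the HAC variance grows at most linearly
#' with `S`, so the division makes values comparable across window sizes)
#' and weighted by the derived allele frequency `f_d,k` of the evaluated
#' SNP, so that only alleles driven to high frequency -- the sweep
#' signature of interest -- score highly.
#'
#' @inheritParams vd_at_site
#' @return A `site_svd` with the `svd` field filled (or `defined = FALSE`).
#' @export
svd_at_site <- function(window, k = window$evaluated_index,
                        reference = build_marh(window),
                        include_evaluated = TRUE,
                        denominator = c("n-1", "n")) {
  out <- vd_at_site(window, k, reference, include_evaluated, denominator)
  if (out$defined) {
    fd <- window$sites$derived_freq[out$k]
    out$svd <- fd * out$vd / out$S_contrib
  }
  out
}

#' @export
print.site_svd <- function(x, ...) {
  if (!x$defined) {
    cat("Svd at site", x$k, ": undefined (sub-sample below 2 haplotypes)\n")
  } else {
    cat("Svd at site", x$k, ":", signif(x$svd, 4),
        " (vd =", signif(x$vd, 4), ", |R_k| =", x$n_major,
        ", |r_k| =", x$n_minor, ")\n")
  }
  invisible(x)
}

#' Svd of a window at its evaluated SNP
#'
#' Convenience wrapper: builds the window-local MARH and returns the `svd`
#' value at the window's evaluated site (`NA` when undefined).
#'
#' @inheritParams vd_at_site
#' @return Numeric scalar (`NA_real_` when the statistic is undefined).
#' @export
svd_stat <- function(window, k = window$evaluated_index,
                     include_evaluated = TRUE,
                     denominator = c("n-1", "n")) {
  res <- svd_at_site(window, k, build_marh(window), include_evaluated,
                     denominator)
  if (res$defined) res$svd else NA_real_
}
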