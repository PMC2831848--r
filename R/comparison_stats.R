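# Comparison statistics evaluated alongside Svd: Tajima's D, the
# normalized Fay & Wu's H (Zeng et al. 2006 normalization) and the
# unstandardized iHS of Voight et al.

stat_result <- function(name, value, defined = is.finite(value)) {
  structure(list(name = name, value = if (defined) value else NA_real_,
                 defined = defined),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$name, ":", if (x$defined) signif(x$value, 5) else "undefined", "\n")
  invisible(x)
}

seg_counts <- function(window) {
  cnt <- colSums(window$alleles)
  cnt[cnt > 0L & cnt < window$n]
}

#' Tajima's D
#'
#' Compares the mean pairwise difference estimate of theta with
#' Watterson's estimate, standardized with Tajima's (1989) variance
#' constants computed from `n` and the number of segregating sites.
#'
#' @param window A [haplotype_window()].
#' @return A `stat_result` (undefined with no segregating sites).
#' @export
tajima_d <- function(window) {
  stopifnot(inherits(window, "hap_window"))
  n <- window$n
  d <- seg_counts(window)
  S <- length(d)
  if (S < 1L) return(stat_result("D", NA_real_, FALSE))
  ii <- seq_len(n - 1L)
  a1 <- sum(1 / ii); a2 <- sum(1 / ii^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pw <- sum(2 * d * (n - d)) / (n * (n - 1))
  sd_d <- sqrt(e1 * S + e2 * S * (S - 1))
  if (sd_d == 0) return(stat_result("D", NA_real_, FALSE))
  stat_result("D", (pw - S / a1) / sd_d)
}

#' Normalized Fay and Wu's H
#'
#' Uses the unfolded site frequency spectrum: `theta_H = sum(2 S_i i^2) /
#' (n (n-1))` over derived counts `i`. The difference `pi - theta_H`
#' equals `2 (theta_pi - theta_L)` and is standardized with the variance
#' of Zeng et al. (2006), estimating `theta` by Watterson and `theta^2`
#' by `S(S-1)/(a1^2 + a2)`.
#'
#' @inheritParams tajima_d
#' @return A `stat_result` (undefined for monomorphic windows).
#' @export
fay_wu_h <- function(window) {
  stopifnot(inherits(window, "hap_window"))
  n <- window$n
  d <- seg_counts(window)
  S <- length(d)
  if (S < 1L) return(stat_result("H", NA_real_, FALSE))
  ii <- seq_len(n - 1L)
  a1 <- sum(1 / ii); a2 <- sum(1 / ii^2)
  a2n1 <- a2 + 1 / n^2                      # sum of 1/i^2 up to n
  pw <- sum(2 * d * (n - d)) / (n * (n - 1))
  th_h <- sum(2 * d^2) / (n * (n - 1))
  th_w <- S / a1
  th_sq <- S * (S - 1) / (a1^2 + a2)
  var_pl <- th_w * (n - 2) / (6 * (n - 1)) +
    th_sq * (18 * n^2 * (3 * n + 2) * a2n1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  if (var_pl <= 0) return(stat_result("H", NA_real_, FALSE))
  # pi - theta_H = 2 (theta_pi - theta_L), hence the factor 4 in the variance
  stat_result("H", (pw - th_h) / sqrt(4 * var_pl))
}

# EHH decay away from the core site for one allele class, plus the
# integrated haplotype homozygosity (trapezoid rule over physical
# positions, truncated where EHH falls below `cutoff`)
ihh_one_side <- function(alleles, positions, rows, k, step, cutoff) {
  nc <- length(rows)
  denom <- nc * (nc - 1) / 2
  grp <- rep(1L, nc)
  ehh_prev <- 1
  pos_prev <- positions[k]
  ihh <- 0
  j <- k + step
  while (j >= 1L && j <= ncol(alleles)) {
    grp <- as.integer(factor(paste(grp, alleles[rows, j])))
    cnts <- tabulate(grp)
    ehh <- sum(cnts * (cnts - 1) / 2) / denom
    ihh <- ihh + (ehh_prev + ehh) / 2 * abs(positions[j] - pos_prev)
    if (ehh < cutoff) break
    ehh_prev <- ehh
    pos_prev <- positions[j]
    j <- j + step
  }
  ihh
}

#' Unstandardized iHS
#'
#' `ln(iHH_A / iHH_D)`: the log ratio of the integrated extended haplotype
#' homozygosity (EHH) around the core SNP for the ancestral-core and
#' derived-core haplotype sets. EHH is integrated by the trapezoid rule
#' out to the window edges or until it drops below `cutoff` (0.05, the
#' Voight et al. convention). Sweeps on derived alleles keep derived-core
#' haplotypes homozygous over long ranges, making `iHH_D` large and the
#' statistic negative. No genome-wide frequency-bin standardization is
#' applied.
#'
#' @inheritParams tajima_d
#' @param k 1-based core site index (defaults to the evaluated site).
#' @param cutoff EHH truncation level.
#' @return A `stat_result`; undefined when either allele class has fewer
#'   than 2 haplotypes, the window has a single SNP, or either integral is
#'   zero.
#' @export
ihs_unstandardized <- function(window, k = window$evaluated_index,
                               cutoff = 0.05) {
  stopifnot(inherits(window, "hap_window"))
  if (is.na(k)) stop("no core site: supply k or set evaluated_index")
  if (window$S < 2L) return(stat_result("iHS", NA_real_, FALSE))
  a <- window$alleles[, k]
  rows_d <- which(a == 1L)
  rows_a <- which(a == 0L)
  if (length(rows_d) < 2L || length(rows_a) < 2L) {
    return(stat_result("iHS", NA_real_, FALSE))
  }
  pos <- window$sites$position
  ihh <- function(rows) {
    ihh_one_side(window$alleles, pos, rows, k, -1L, cutoff) +
      ihh_one_side(window$alleles, pos, rows, k, +1L, cutoff)
  }
  ia <- ihh(rows_a)
  id <- ihh(rows_d)
  if (ia <= 0 || id <= 0) return(stat_result("iHS", NA_real_, FALSE))
  stat_result("iHS", log(ia / id))
}
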