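# Critical-value calibration on matched neutral simulations and
# detection-power estimation.

#' Critical value of a test at a nominal level
#'
#' `c` is the smallest observed null value such that the proportion of
#' null values greater than or equal to `c` is at most `p`; the achieved
#' proportion is reported alongside. Undefined (`NA`) values are excluded
#' and counted, never treated as zero.
#'
#' @param null_values Numeric vector of the statistic under the null
#'   (`NA` = undefined replicate).
#' @param p Nominal level in (0, 1).
#' @param name Statistic label.
#' @return Object of class `null_distribution`: list with `statistic`,
#'   `values`, `p`, `c`, `achieved` (realized `Pr(value >= c)`),
#'   `n_defined`, `n_undefined`, `degenerate`.
#' @export
critical_value <- function(null_values, p = 0.05, name = "Svd") {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  vals <- null_values[!is.na(null_values)]
  n_na <- sum(is.na(null_values))
  if (length(vals) < 20L) {
    stop("need at least 20 defined null values to calibrate")
  }
  N <- length(vals)
  sv <- sort(unique(vals), decreasing = TRUE)
  prop <- vapply(sv, function(v) mean(vals >= v), 0)
  ok <- which(prop <= p)
  degenerate <- length(sv) == 1L
  if (degenerate) {
    cv <- sv[1L]; achieved <- 1
  } else if (length(ok)) {
    i <- max(ok)                     # smallest value still within level p
    cv <- sv[i]; achieved <- prop[i]
  } else {
    cv <- sv[1L]; achieved <- prop[1L]
  }
  structure(list(statistic = name, values = vals, p = p, c = cv,
                 achieved = achieved, n_defined = N, n_undefined = n_na,
                 degenerate = degenerate),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null calibration of", x$statistic, "on", x$n_defined,
      "defined values (", x$n_undefined, "undefined dropped )\n")
  cat("  c =", signif(x$c, 5), "at nominal p =", x$p,
      "; achieved Pr(>= c) =", signif(x$achieved, 4),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Detection power against a critical value
#'
#' The proportion of alternative-scenario values strictly greater than
#' `c` (the sensitivity of the test), with its binomial standard error.
#'
#' @param alt_values Numeric vector of the statistic under the
#'   alternative (`NA` = undefined, dropped and counted).
#' @param c Critical value (a scalar or a `null_distribution`).
#' @param scenario Optional scenario descriptor carried into the result.
#' @return Object of class `power_result`: list with `power`, `n_alt`,
#'   `se`, `n_undefined`, `c`, `scenario`.
#' @export
detection_power <- function(alt_values, c, scenario = NULL) {
  if (inherits(c, "null_distribution")) c <- c$c
  vals <- alt_values[!is.na(alt_values)]
  if (length(vals) < 20L) {
    stop("need at least 20 defined alternative values")
  }
  pw <- mean(vals > c)
  structure(list(power = pw, n_alt = length(vals),
                 se = sqrt(pw * (1 - pw) / length(vals)),
                 n_undefined = sum(is.na(alt_values)), c = c,
                 scenario = scenario),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Detection power:", signif(x$power, 3), "+/-", signif(x$se, 2),
      "( n =", x$n_alt, ", c =", signif(x$c, 5), ")\n")
  if (!is.null(x$scenario)) cat("  scenario:", format(x$scenario), "\n")
  invisible(x)
}

#' Power versus false discovery rate
#'
#' Sweeps the decision threshold over the pooled null and alternative
#' values; at each achievable threshold reports the FDR (proportion of
#' exceedances that are null) and the power (proportion of alternative
#' values exceeding the threshold). Exceedance is `>= threshold` so every
#' observed value is an operating point.
#'
#' @inheritParams critical_value
#' @inheritParams detection_power
#' @return Data frame with columns `threshold`, `fdr`, `power`.
#' @export
power_fdr_curve <- function(null_values, alt_values) {
  nv <- null_values[!is.na(null_values)]
  av <- alt_values[!is.na(alt_values)]
  if (!length(nv) || !length(av)) stop("both value sets must be non-empty")
  thr <- sort(unique(c(nv, av)), decreasing = TRUE)
  nn <- vapply(thr, function(t) sum(nv >= t), 0L)
  na <- vapply(thr, function(t) sum(av >= t), 0L)
  keep <- nn + na > 0L
  data.frame(threshold = thr[keep],
             fdr = nn[keep] / (nn[keep] + na[keep]),
             power = na[keep] / length(av))
}

#' Power at a target false discovery rate
#'
#' The largest power achievable on the [power_fdr_curve()] at an FDR not
#' exceeding `fdr`.
#'
#' @inheritParams power_fdr_curve
#' @param fdr Target FDR operating point.
#' @return Numeric scalar (0 when no threshold attains the target).
#' @export
power_at_fdr <- function(null_values, alt_values, fdr = 0.1) {
  curve <- power_fdr_curve(null_values, alt_values)
  ok <- curve$fdr <= fdr
  if (!any(ok)) return(0)
  max(curve$power[ok])
}

# scenarios must agree in everything except the selection coefficient
# (null s = 0), seed and label; the frequency conditioning must match
assert_matched <- function(null_cfg, alt_cfg) {
  if (is.null(null_cfg$selection) || null_cfg$selection$s != 0) {
    stop("the matched null must be the selection scenario with s = 0 ",
         "(frequency-conditioned neutral); see match_null()")
  }
  if (is.null(alt_cfg$selection)) {
    stop("the alternative scenario carries no selection parameters")
  }
  if (!identical(null_cfg$selection$f, alt_cfg$selection$f)) {
    stop("null and alternative condition on different current frequencies")
  }
  strip <- function(cfg) cfg[setdiff(names(cfg), c("selection", "seed", "label"))]
  if (!identical(strip(null_cfg), strip(alt_cfg))) {
    stop("null and alternative scenarios differ in more than the ",
         "selection coefficient and seed: calibration would be invalid")
  }
  invisible(TRUE)
}

#' Per-replicate statistic values at the evaluated site
#'
#' Runs the full evaluation pipeline on every replicate of a set:
#' optional ascertainment of the whole replicate, extraction of the
#' `S`-SNP window centred on the evaluated site, then the statistic.
#' Replicates where the statistic is undefined, or that lack a full
#' window after ascertainment, yield `NA` (reported as missing, never as
#' zero).
#'
#' @param reps A `replicate_set` (or plain list of [haplotype_window()]).
#' @param S Window size in SNPs.
#' @param statistic One of `"svd"`, `"tajima_d"`, `"fay_wu_h"`, `"ihs"`.
#' @param ascertainment Optional function applied to each full replicate
#'   before window extraction, e.g.
#'   `function(w) filter_by_maf(w, 3)`.
#' @param include_evaluated,denominator Passed to [svd_at_site()].
#' @return Numeric vector (one value per replicate) with attribute
#'   `n_unwindowed` counting replicates without a full window.
#' @export
replicate_statistics <- function(reps, S,
                                 statistic = c("svd", "tajima_d",
                                               "fay_wu_h", "ihs"),
                                 ascertainment = NULL,
                                 include_evaluated = TRUE,
                                 denominator = c("n-1", "n")) {
  statistic <- match.arg(statistic)
  denominator <- match.arg(denominator)
  wins <- if (inherits(reps, "replicate_set")) reps$replicates else reps
  out <- rep(NA_real_, length(wins))
  unwin <- 0L
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    if (!is.null(ascertainment)) w <- ascertainment(w)
    ww <- tryCatch(extract_window(w, S), error = function(e) NULL)
    if (is.null(ww)) { unwin <- unwin + 1L; next }
    out[i] <- switch(statistic,
      svd = svd_stat(ww, include_evaluated = include_evaluated,
                     denominator = denominator),
      tajima_d = { r <- tajima_d(ww); if (r$defined) r$value else NA_real_ },
      fay_wu_h = { r <- fay_wu_h(ww); if (r$defined) r$value else NA_real_ },
      ihs = { r <- ihs_unstandardized(ww); if (r$defined) r$value else NA_real_ })
  }
  attr(out, "n_unwindowed") <- unwin
  out
}

#' Calibrated power of a statistic under a selection scenario
#'
#' Enforces the matched-null rule (identical scenarios except for the
#' selection coefficient and seed), calibrates the critical value at
#' level `p` on the null replicates, and estimates the detection power on
#' the alternative replicates, applying the same ascertainment and
#' windowing to both.
#'
#' @param null_set,alt_set `replicate_set`s simulated under the matched
#'   null and the selection scenario.
#' @inheritParams replicate_statistics
#' @param p Nominal level of the test.
#' @return List with `power` (a `power_result`), `null` (a
#'   `null_distribution`), `null_values`, `alt_values`.
#' @export
power_estimate <- function(null_set, alt_set, S, p = 0.05,
                           statistic = "svd", ascertainment = NULL,
                           include_evaluated = TRUE,
                           denominator = c("n-1", "n")) {
  stopifnot(inherits(null_set, "replicate_set"),
            inherits(alt_set, "replicate_set"))
  assert_matched(null_set$scenario, alt_set$scenario)
  nv <- replicate_statistics(null_set, S, statistic, ascertainment,
                             include_evaluated, denominator)
  av <- replicate_statistics(alt_set, S, statistic, ascertainment,
                             include_evaluated, denominator)
  nd <- critical_value(nv, p, name = statistic)
  pw <- detection_power(av, nd, scenario = alt_set$scenario$label)
  list(power = pw, null = nd, null_values = nv, alt_values = av)
}

#' Power surface over a grid of selection scenarios
#'
#' Simulates, for every scenario of the grid, matched null and
#' alternative replicate sets, and estimates power per scenario.
#'
#' @param grid List of selection [scenario_config()]s (see
#'   [scenario_grid()]).
#' @param n_reps Replicates per set.
#' @inheritParams power_estimate
#' @return Data frame: one row per scenario with `label`, `s`, `f`, `S`,
#'   `power`, `se`, `c`.
#' @export
power_surface <- function(grid, n_reps, S, p = 0.05, statistic = "svd",
                          ascertainment = NULL) {
  rows <- lapply(grid, function(cfg) {
    alt <- simulate_sweep(cfg, n_reps)
    nul <- simulate_sweep(match_null(cfg), n_reps)
    pe <- power_estimate(nul, alt, S, p, statistic, ascertainment)
    data.frame(label = if (is.null(cfg$label)) NA_character_ else cfg$label,
               s = cfg$selection$s, f = cfg$selection$f, S = S,
               power = pe$power$power, se = pe$power$se, c = pe$null$c)
  })
  do.call(rbind, rows)
}
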