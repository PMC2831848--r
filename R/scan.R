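# Sliding-window Svd scan along a chromosome, empirical p-values, top
# percentile flagging, cluster reporting, and simulation-matched p-values
# for a candidate locus.

#' Sliding-window Svd scan
#'
#' Slides a window of fixed length `S` one SNP at a time along the
#' chromosome; at every evaluable SNP the window centred on it is
#' extracted, its own MARH is built (the reference is always
#' window-local, never chromosome-global) and `Svd` is computed. SNPs too
#' close to either chromosome end for a full centred window are reported
#' as not evaluated: windows are never truncated, so the `/S`
#' normalization stays comparable along the track.
#'
#' @param chromosome A [haplotype_window()] spanning all SNPs of the
#'   region, with ancestral annotation.
#' @param S Window size in SNPs.
#' @param include_evaluated,denominator Passed to [svd_at_site()].
#' @return Object of class `scan_track`: data frame with one row per SNP
#'   (`site_id`, `position`, `S`, `evaluated`, `svd`, `defined`,
#'   `n_major`, `n_minor`).
#' @export
sliding_scan <- function(chromosome, S, include_evaluated = TRUE,
                         denominator = c("n-1", "n")) {
  stopifnot(inherits(chromosome, "hap_window"))
  denominator <- match.arg(denominator)
  C <- chromosome$S
  if (S > C) stop("window size S exceeds the number of SNPs")
  lo_margin <- floor(S / 2)
  hi_margin <- S - lo_margin - 1L
  track <- data.frame(site_id = chromosome$sites$site_id,
                      position = chromosome$sites$position,
                      S = S, evaluated = FALSE, svd = NA_real_,
                      defined = FALSE, n_major = NA_integer_,
                      n_minor = NA_integer_,
                      stringsAsFactors = FALSE)
  for (k in seq_len(C)) {
    if (k <= lo_margin || k > C - hi_margin) next
    win <- extract_window(chromosome, S, center = k)
    res <- svd_at_site(win, include_evaluated = include_evaluated,
                       denominator = denominator)
    track$evaluated[k] <- TRUE
    track$defined[k] <- res$defined
    track$n_major[k] <- res$n_major
    track$n_minor[k] <- res$n_minor
    if (res$defined) track$svd[k] <- res$svd
  }
  class(track) <- c("scan_track", "data.frame")
  track
}

#' Empirical p-values along a scan track
#'
#' Assigns each defined SNP the upper-tail empirical p-value against the
#' distribution of all defined `Svd` values on the track (ties share the
#' more conservative, larger p). SNPs in the top percentile of positive
#' `Svd` values are flagged (`top_percentile_flag`), matching the
#' convention of plotting only the 99th percentile of positive values.
#'
#' @param track A `scan_track` from [sliding_scan()].
#' @param top_quantile Quantile of positive values to flag (default
#'   0.99).
#' @return The track with columns `empirical_p` and
#'   `top_percentile_flag` added.
#' @export
empirical_pvalues <- function(track, top_quantile = 0.99) {
  stopifnot(inherits(track, "scan_track"))
  vals <- track$svd[track$defined]
  if (length(vals) < 100L) {
    stop("need at least 100 defined Svd values for empirical p-values")
  }
  track$empirical_p <- NA_real_
  idx <- which(track$defined)
  track$empirical_p[idx] <- vapply(track$svd[idx],
                                   function(v) mean(vals >= v), 0)
  track$top_percentile_flag <- FALSE
  pos <- vals[vals > 0]
  if (length(pos)) {
    thr <- stats::quantile(pos, top_quantile, names = FALSE, type = 1)
    track$top_percentile_flag[idx] <- track$defined[idx] &
      !is.na(track$svd[idx]) & track$svd[idx] > 0 & track$svd[idx] >= thr
  }
  track
}

#' Merge flagged SNPs into candidate intervals
#'
#' Consecutive top-percentile SNPs closer than `gap` SNP indices merge
#' into one reported interval (cluster reporting is an artifact
#' convention; the underlying evidence is the per-SNP track).
#'
#' @inheritParams empirical_pvalues
#' @param gap Maximum index gap between flagged SNPs in one cluster.
#' @return Data frame with `start_index`, `end_index`, `start_pos`,
#'   `end_pos`, `n_flagged`.
#' @export
scan_clusters <- function(track, gap = 20L) {
  stopifnot(inherits(track, "scan_track"))
  if (is.null(track$top_percentile_flag)) {
    stop("run empirical_pvalues() first")
  }
  idx <- which(track$top_percentile_flag)
  if (!length(idx)) {
    return(data.frame(start_index = integer(), end_index = integer(),
                      start_pos = numeric(), end_pos = numeric(),
                      n_flagged = integer()))
  }
  brk <- c(0L, which(diff(idx) > gap), length(idx))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    mem <- idx[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start_index = mem[1L], end_index = mem[length(mem)],
               start_pos = track$position[mem[1L]],
               end_pos = track$position[mem[length(mem)]],
               n_flagged = length(mem))
  })
  do.call(rbind, out)
}

#' Simulation-matched p-values for a candidate locus
#'
#' For a locus of `S_locus` SNPs with a putative selection target at
#' `target_index`, trims each matched simulated replicate so its selected
#' SNP sits at `target_index` within an `S_locus`-SNP haplotype, computes
#' `Svd` at every index of every trimmed replicate, and reports, for each
#' locus SNP, the exceedance proportion of the simulated `Svd`
#' distribution at the corresponding index.
#'
#' @param locus A [haplotype_window()] of the candidate locus.
#' @param matched A `replicate_set` simulated to match the locus (sample
#'   size, mutation rate, selection parameters, ascertainment applied
#'   upstream), each replicate's `evaluated_index` at its selected site.
#' @param target_index 1-based index of the putative selected SNP within
#'   the locus.
#' @param include_evaluated,denominator Passed to [svd_at_site()].
#' @return Object of class `candidate_report`: data frame (`site_id`,
#'   `index`, `svd_observed`, `p_sim`) with the matching metadata in
#'   attributes `n_sim_used` and `scenario`.
#' @export
candidate_pvalues <- function(locus, matched, target_index,
                              include_evaluated = TRUE,
                              denominator = c("n-1", "n")) {
  stopifnot(inherits(locus, "hap_window"))
  denominator <- match.arg(denominator)
  S_l <- locus$S
  if (target_index < 1L || target_index > S_l) {
    stop("target_index outside the locus")
  }
  wins <- if (inherits(matched, "replicate_set")) matched$replicates else matched
  sim_vals <- matrix(NA_real_, length(wins), S_l)
  used <- 0L
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    ev <- w$evaluated_index
    lo <- ev - (target_index - 1L)
    hi <- ev + (S_l - target_index)
    if (is.na(ev) || lo < 1L || hi > w$S) next
    if (w$n != locus$n) {
      stop("replicate sample size (", w$n, ") does not match the locus (",
           locus$n, ")")
    }
    tw <- subset_sites(w, lo:hi)
    used <- used + 1L
    for (j in seq_len(S_l)) {
      sim_vals[i, j] <- svd_stat(tw, k = j,
                                 include_evaluated = include_evaluated,
                                 denominator = denominator)
    }
  }
  if (used < 1L) stop("no matched replicate could be trimmed to the locus")
  obs <- vapply(seq_len(S_l), function(j)
    svd_stat(locus, k = j, include_evaluated = include_evaluated,
             denominator = denominator), 0)
  p_sim <- vapply(seq_len(S_l), function(j) {
    sims <- sim_vals[!is.na(sim_vals[, j]), j]
    if (!length(sims) || is.na(obs[j])) return(NA_real_)
    mean(sims >= obs[j])
  }, 0)
  rep <- data.frame(site_id = locus$sites$site_id,
                    index = seq_len(S_l),
                    svd_observed = obs, p_sim = p_sim,
                    stringsAsFactors = FALSE)
  attr(rep, "n_sim_used") <- used
  attr(rep, "scenario") <- if (inherits(matched, "replicate_set"))
    matched$scenario else NULL
  class(rep) <- c("candidate_report", "data.frame")
  rep
}
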