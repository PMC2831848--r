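test_that("a chromosome of exactly S SNPs yields one evaluated SNP", {
  w <- random_window(20, 21, seed = 70)
  track <- sliding_scan(w, 21)
  expect_equal(sum(track$evaluated), 1L)
  expect_equal(which(track$evaluated), 11L)
  expect_error(sliding_scan(w, 22), "exceeds")
})

test_that("the scan track is invariant to haplotype row order", {
  w <- random_window(18, 40, seed = 71)
  set.seed(3)
  wp <- haplotype_window(w$alleles[sample(18), ],
                         positions = w$sites$position,
                         require_segregating = FALSE)
  expect_equal(sliding_scan(wp, 15)$svd, sliding_scan(w, 15)$svd)
})

test_that("the maximum Svd localizes a planted sweep", {
  # recombination is what makes the signal decay away from the selected
  # site; under complete linkage the Svd plateau has no positional
  # information, so the localization property is probed with rho > 0
  hits <- 0L
  for (seed in 1:9) {
    cfg <- scenario_config(n = 30, theta = 150, rho = 75,
                           selection = list(s = 0.5, f = 0.8), seed = seed)
    w <- simulate_replicate(cfg, min_flank = 40L)
    lo <- w$evaluated_index - 40L
    hi <- w$evaluated_index + 40L
    chrom <- hacsweep:::subset_sites(w, lo:hi)
    track <- sliding_scan(chrom, 31)
    # under tight linkage the maximum forms a plateau of identical values;
    # the sweep is localized when the plateau reaches the true site
    vals <- ifelse(track$defined, track$svd, -Inf)
    peaks <- which(vals >= max(vals) - 1e-12)
    if (min(abs(peaks - chrom$evaluated_index)) <= 10) hits <- hits + 1L
  }
  expect_gt(hits, 4L)
})

test_that("empirical p-values and the top-percentile flag behave", {
  w <- random_window(30, 160, seed = 77)
  track <- empirical_pvalues(sliding_scan(w, 11))
  def <- which(track$defined)
  expect_true(all(track$empirical_p[def] > 0 & track$empirical_p[def] <= 1))
  # the maximum gets 1/N_defined
  mx <- def[which.max(track$svd[def])]
  expect_equal(track$empirical_p[mx], 1 / length(def))
  # about 1% of the positive values are flagged (up to ties)
  npos <- sum(track$svd[def] > 0)
  expect_lte(sum(track$top_percentile_flag), max(1, ceiling(0.02 * npos)))
  # tied tracks give everyone p = 1
  tr2 <- track
  tr2$svd[def] <- 1
  tr2 <- empirical_pvalues(tr2)
  expect_true(all(tr2$empirical_p[def] == 1))
  # too few defined values is an error
  expect_error(empirical_pvalues(sliding_scan(random_window(10, 30, seed = 1),
                                              25)), "100")
})

test_that("flagged SNPs merge into clusters and export as BED", {
  w <- random_window(20, 150, seed = 80)
  track <- empirical_pvalues(sliding_scan(w, 11))
  track$top_percentile_flag <- FALSE
  track$top_percentile_flag[c(20, 22, 30, 90, 95)] <- TRUE
  cl <- scan_clusters(track, gap = 10)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start_index, c(20L, 90L))
  expect_equal(cl$n_flagged, c(3L, 2L))
  bed <- tempfile(fileext = ".bed")
  write_bed(cl, bed)
  tab <- read.table(bed, sep = "\t")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$V3 > tab$V2))   # half-open, end exclusive
  # no flags, no clusters
  track$top_percentile_flag <- FALSE
  expect_equal(nrow(scan_clusters(track)), 0L)
})

test_that("neutral scans flag about one percent without clustering", {
  cfg <- scenario_config(n = 20, theta = 150, seed = 90)
  w <- simulate_neutral(cfg, 1)$replicates[[1]]
  track <- empirical_pvalues(sliding_scan(w, 21))
  def <- which(track$defined)
  npos <- sum(track$svd[def] > 0)
  frac <- sum(track$top_percentile_flag) / max(npos, 1)
  expect_lte(frac, 0.05)
})

test_that("candidate p-values localize a planted strong sweep", {
  # locus: strong ongoing sweep, 26 SNPs, target at index 8;
  # matched replicates: same scenario with s = 0
  cfg <- scenario_config(n = 40, theta = 223,
                         selection = list(s = 0.5, f = 0.9), seed = 991)
  locus_full <- simulate_replicate(cfg, min_flank = 20L)
  ev <- locus_full$evaluated_index
  locus <- hacsweep:::subset_sites(locus_full, (ev - 7L):(ev + 18L))
  expect_equal(locus$S, 26L)
  matched <- simulate_sweep(match_null(cfg), 120, min_flank = 20L)
  rep <- candidate_pvalues(locus, matched, target_index = 8L)
  expect_equal(nrow(rep), 26L)
  expect_lt(rep$p_sim[8], 0.1)
  # self-consistency: a locus drawn from the matched distribution itself
  # gets its own rank-based exceedance
  self <- matched$replicates[[1]]
  ev1 <- self$evaluated_index
  locus_self <- hacsweep:::subset_sites(self, (ev1 - 7L):(ev1 + 18L))
  rep_self <- candidate_pvalues(locus_self, matched, target_index = 8L)
  expect_gte(rep_self$p_sim[8], 1 / 120)
  # sample-size mismatch is an error
  bad <- simulate_sweep(scenario_config(n = 20, theta = 223,
                                        selection = list(s = 0, f = 0.9),
                                        seed = 7), 5, min_flank = 20L)
  expect_error(candidate_pvalues(locus, bad, 8L), "sample size")
})
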