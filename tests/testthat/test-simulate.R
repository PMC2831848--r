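test_that("replicate sets are exactly regenerable from their seeds", {
  cfg <- scenario_config(n = 12, theta = 15, seed = 404)
  a <- simulate_neutral(cfg, 3)
  b <- simulate_neutral(cfg, 3)
  expect_identical(a$replicates, b$replicates)
  # a single replicate regenerated from its recorded seed
  w <- simulate_replicate(cfg, a$rep_seeds[2])
  attr(w, "attempts") <- NULL
  w2 <- a$replicates[[2]]
  attr(w2, "attempts") <- NULL
  expect_identical(w, w2)

  cfgs <- scenario_config(n = 12, theta = 15,
                          selection = list(s = 0.3, f = 0.7), seed = 405)
  expect_identical(simulate_sweep(cfgs, 2)$replicates,
                   simulate_sweep(cfgs, 2)$replicates)
})

test_that("neutral segregating sites match Watterson's expectation", {
  cfg <- scenario_config(n = 50, theta = 223, seed = 1912)
  reps <- simulate_neutral(cfg, 150)
  ss <- sapply(reps$replicates, function(w) w$S)
  expected <- 223 * sum(1 / (1:49))
  se <- sd(ss) / sqrt(length(ss))
  expect_lt(abs(mean(ss) - expected), 3 * se)
})

test_that("without recombination every site pair passes four gametes", {
  cfg <- scenario_config(n = 20, theta = 40, seed = 77)
  reps <- simulate_neutral(cfg, 5)
  set.seed(1)
  for (w in reps$replicates) {
    pairs <- cbind(sample(w$S, 150, replace = TRUE),
                   sample(w$S, 150, replace = TRUE))
    for (r in seq_len(nrow(pairs))) {
      j1 <- pairs[r, 1]; j2 <- pairs[r, 2]
      if (j1 == j2) next
      gametes <- unique(paste(w$alleles[, j1], w$alleles[, j2]))
      expect_lte(length(gametes), 3)
    }
  }
})

test_that("a bottleneck reduces pairwise diversity below constant size", {
  n_reps <- 120
  const <- simulate_neutral(scenario_config(n = 20, theta = 60, seed = 51),
                            n_reps)
  bott <- simulate_neutral(
    scenario_config(n = 20, theta = 60, seed = 52,
                    demography = list(kind = "bottleneck", t_start = 260,
                                      duration = 80, reduction = 0.05)),
    n_reps)
  pi_of <- function(set) sapply(set$replicates, function(w) {
    cnt <- colSums(w$alleles)
    sum(2 * cnt * (w$n - cnt)) / (w$n * (w$n - 1))
  })
  expect_lt(mean(pi_of(bott)), mean(pi_of(const)))
})

test_that("sweep replicates are conditioned on the selected frequency", {
  cfg <- scenario_config(n = 50, theta = 80,
                         selection = list(s = 0.5, f = 0.9), seed = 61)
  reps <- simulate_sweep(cfg, 60)
  f_obs <- sapply(reps$replicates, function(w)
    w$sites$derived_freq[w$evaluated_index])
  # sample frequency is Binomial(n, f) around f
  expect_lt(abs(mean(f_obs) - 0.9), 3 * sqrt(0.9 * 0.1 / 50) / sqrt(60) + 0.01)
  # the selected site sits at the locus midpoint
  pos <- sapply(reps$replicates, function(w)
    w$sites$position[w$evaluated_index])
  expect_true(all(abs(pos - 25000) < 1))
  # hitchhiking: the selected-allele class is the tight one
  vv <- t(sapply(reps$replicates, function(w) {
    r <- svd_at_site(extract_window(w, 31))
    c(r$var_major, r$var_minor)
  }))
  expect_lt(mean(vv[, 1], na.rm = TRUE), mean(vv[, 2], na.rm = TRUE))
})

test_that("selection strength and frequency shift the Svd distribution", {
  strong <- simulate_sweep(scenario_config(
    n = 40, theta = 120, selection = list(s = 0.5, f = 0.9), seed = 71), 60)
  weak <- simulate_sweep(scenario_config(
    n = 40, theta = 120, selection = list(s = 0.05, f = 0.6), seed = 72), 60)
  vs <- replicate_statistics(strong, 31)
  vw <- replicate_statistics(weak, 31)
  expect_gt(median(vs, na.rm = TRUE), median(vw, na.rm = TRUE))
})

test_that("scenario_grid builds a full grid with distinct seeds", {
  base <- scenario_config(n = 50, theta = 223, seed = 9)
  grid <- scenario_grid(base, f_values = c(0.6, 0.7, 0.75, 0.8, 0.9),
                        s_values = c(0.05, 0.15, 0.5))
  expect_length(grid, 15)
  seeds <- sapply(grid, function(g) g$seed)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_length(scenario_grid(base, c(0.6), numeric(0)), 0)
})

test_that("window extraction is centred and validates flanks", {
  w <- random_window(10, 30, seed = 8)
  w$evaluated_index <- 15L
  ww <- extract_window(w, 11)
  expect_equal(ww$S, 11L)
  expect_equal(ww$evaluated_index, 6L)
  expect_equal(ww$sites$site_id[6], w$sites$site_id[15])
  # even S: centre at 0-based floor(S/2)
  we <- extract_window(w, 10)
  expect_equal(we$S, 10L)
  expect_equal(we$evaluated_index, 6L)
  expect_error(extract_window(w, 31), "window")
  w$evaluated_index <- 2L
  expect_error(extract_window(w, 11), "flank")
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario_config(theta = -1), "theta")
  expect_error(scenario_config(selection = list(s = 0.1, f = 1.2)), "f")
  expect_error(scenario_config(selection = list(s = 0.1, f = 0.5),
                               demography = list(kind = "bottleneck")),
               "constant")
  expect_error(scenario_config(rho = 0,
                               hotspots = list(list(offset = 2000, mult = 10))),
               "background")
  expect_error(scenario_config(rho = 10,
                               hotspots = list(list(offset = 0, mult = 0.5))),
               "multipliers")
  expect_error(simulate_neutral(scenario_config(
    selection = list(s = 0.1, f = 0.5)), 1), "simulate_sweep")
  expect_error(simulate_sweep(scenario_config(), 1), "no selection")
})

test_that("the recombination map integrates hotspots correctly", {
  cfg <- scenario_config(n = 10, theta = 50, rho = 100,
                         hotspots = list(list(offset = 2000, mult = 10)),
                         hotspot_width = 2000, locus_length = 50000)
  map <- hacsweep:::scenario_recomb_map(cfg)
  # total map mass: background everywhere plus 9x extra over 4% of the locus
  expect_equal(max(map$cum), 100 * (1 + 9 * 0.04))
  # hotspot interval starts 2 kb downstream of the midpoint
  expect_true(any(abs(map$breaks - 0.54) < 1e-12))
  expect_true(any(abs(map$breaks - 0.58) < 1e-12))
})
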