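# Scenario configuration and the coalescent simulation harness.
#
# Time bookkeeping: the C-level engine works in units of 2*Ne generations
# with population sizes relative to the present size. Scenario parameters
# are given in generations and converted here.

#' Describe one simulation scenario
#'
#' @param n Sample size (haplotypes).
#' @param theta Population mutation rate for the whole locus
#'   (`4 Ne mu`); 223 gives on average about 1,000 SNPs in samples of 50.
#' @param rho Background population recombination rate for the whole locus
#'   (`4 Ne r`); 0 for no recombination.
#' @param hotspots Optional list of recombination hotspots, each
#'   `list(offset = <bp downstream of the evaluated site>, mult =
#'   <intensity multiplier over the background rate>)`. Multipliers must be
#'   at least 1.
#' @param hotspot_width Physical width of each hotspot in bp (default
#'   2000).
#' @param Ne Diploid effective population size used for time scaling and
#'   for the granularity/noise of selected-allele frequency trajectories.
#' @param demography `list(kind = "constant")` (default),
#'   `list(kind = "bottleneck", t_start =, duration =, reduction =)`
#'   (times in generations before present, `reduction` the relative size
#'   during the bottleneck), or
#'   `list(kind = "expansion", ne_from =, duration =)` (the population grew
#'   from `ne_from` to `Ne` over the last `duration` generations).
#' @param selection Optional `list(s = <selection coefficient>, f =
#'   <current population frequency of the selected allele>)`. The selected
#'   site sits at the centre of the locus.
#' @param locus_length Physical length of the locus in bp (default 50000);
#'   used to place hotspots and to report positions.
#' @param trajectory `"stochastic"` (default; exact Wright-Fisher forward
#'   trajectories conditioned on currently segregating at `f`) or
#'   `"deterministic"` (logistic decay backward from `f`).
#' @param seed Integer master seed; every replicate derives its own seed
#'   from it so any single replicate is exactly regenerable.
#' @param label Optional scenario label carried through result tables.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n = 50L, theta = 223, rho = 0,
                            hotspots = list(), hotspot_width = 2000,
                            Ne = 1000, demography = list(kind = "constant"),
                            selection = NULL, locus_length = 50000,
                            trajectory = c("stochastic", "deterministic"),
                            seed = 1L, label = NULL) {
  trajectory <- match.arg(trajectory)
  if (n < 2L) stop("sample size must be at least 2")
  if (theta <= 0) stop("theta must be positive")
  if (rho < 0) stop("rho must be non-negative")
  if (Ne < 2) stop("Ne must be at least 2")
  if (!is.list(demography) || is.null(demography$kind) ||
      !demography$kind %in% c("constant", "bottleneck", "expansion")) {
    stop("demography must be a list with kind constant/bottleneck/expansion")
  }
  if (demography$kind == "bottleneck") {
    if (is.null(demography$t_start)) demography$t_start <- 260
    if (is.null(demography$duration)) demography$duration <- 80
    if (is.null(demography$reduction)) demography$reduction <- 0.05
    if (demography$reduction <= 0 || demography$duration <= 0) {
      stop("invalid bottleneck parameters")
    }
  }
  if (demography$kind == "expansion") {
    if (is.null(demography$ne_from)) demography$ne_from <- 500
    if (is.null(demography$duration)) demography$duration <- 300
    if (demography$ne_from <= 0 || demography$duration <= 0) {
      stop("invalid expansion parameters")
    }
  }
  if (!is.null(selection)) {
    if (is.null(selection$s) || is.null(selection$f)) {
      stop("selection needs both s and f")
    }
    if (selection$s < 0) stop("selection coefficient must be non-negative")
    if (selection$f <= 0 || selection$f >= 1) stop("f must lie in (0, 1)")
    if (demography$kind != "constant") {
      stop("selection scenarios assume constant population size")
    }
  }
  for (h in hotspots) {
    if (is.null(h$offset) || is.null(h$mult)) {
      stop("each hotspot needs offset and mult")
    }
    if (h$mult < 1) stop("hotspot multipliers must be at least 1")
    if (rho <= 0) stop("hotspots need a positive background rate")
  }
  structure(list(n = as.integer(n), theta = theta, rho = rho,
                 hotspots = hotspots, hotspot_width = hotspot_width,
                 Ne = Ne, demography = demography, selection = selection,
                 locus_length = locus_length, trajectory = trajectory,
                 seed = as.integer(seed), label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", if (!is.null(x$label)) x$label else "(unlabelled)", "\n")
  cat("  n =", x$n, ", theta =", x$theta, ", rho =", x$rho,
      ", Ne =", x$Ne, ", demography =", x$demography$kind, "\n")
  if (!is.null(x$selection)) {
    cat("  selection: s =", x$selection$s, ", f =", x$selection$f,
        "(", x$trajectory, "trajectory )\n")
  }
  if (length(x$hotspots)) {
    cat(" ", length(x$hotspots), "recombination hotspot(s)\n")
  }
  invisible(x)
}

# piecewise-constant sizes, backward in time, in 2*Ne units
scenario_epochs <- function(cfg) {
  g2 <- 2 * cfg$Ne
  d <- cfg$demography
  if (d$kind == "constant") {
    list(start = 0, size = 1)
  } else if (d$kind == "bottleneck") {
    list(start = c(0, d$t_start, d$t_start + d$duration) / g2,
         size = c(1, d$reduction, 1))
  } else {
    list(start = c(0, d$duration) / g2,
         size = c(1, d$ne_from / cfg$Ne))
  }
}

# recombination map as (breaks on [0,1], cumulative rho at the breaks)
scenario_recomb_map <- function(cfg) {
  if (cfg$rho <= 0) return(list(breaks = c(0, 1), cum = c(0, 0)))
  L <- cfg$locus_length
  ivals <- list()
  for (h in cfg$hotspots) {
    a <- 0.5 + h$offset / L
    b <- a + cfg$hotspot_width / L
    a <- max(0, min(1, a)); b <- max(0, min(1, b))
    if (b > a) ivals[[length(ivals) + 1L]] <- c(a, b, h$mult)
  }
  if (length(ivals) > 1L) {
    o <- order(vapply(ivals, `[`, 0, 1L))
    ivals <- ivals[o]
    for (i in seq_len(length(ivals) - 1L)) {
      if (ivals[[i]][2] > ivals[[i + 1L]][1]) stop("overlapping hotspots")
    }
  }
  breaks <- 0
  dens <- numeric(0)
  cur <- 0
  for (iv in ivals) {
    if (iv[1] > cur) { breaks <- c(breaks, iv[1]); dens <- c(dens, 1) }
    breaks <- c(breaks, iv[2]); dens <- c(dens, iv[3])
    cur <- iv[2]
  }
  if (cur < 1) { breaks <- c(breaks, 1); dens <- c(dens, 1) }
  cum <- c(0, cumsum(cfg$rho * dens * diff(breaks)))
  list(breaks = breaks, cum = cum)
}

#' Simulate a selected-allele frequency trajectory
#'
#' Backward-in-time population frequency path of the evaluated allele,
#' at one-generation resolution, starting from the current frequency `f`
#' and ending at a single copy. With `s > 0` and a stochastic trajectory
#' the path is an exact Wright-Fisher forward simulation (additive
#' fitnesses 1, 1 + s/2, 1 + s) started from one copy and conditioned on
#' reaching `f`, then reversed. With `s = 0` the path follows the neutral
#' diffusion conditioned on backward loss (drift `-x / 2Ne` per
#' generation). The deterministic option is the logistic decay.
#'
#' @param s Selection coefficient (`>= 0`).
#' @param f Current population frequency in (0, 1).
#' @param Ne Diploid effective population size.
#' @param method `"stochastic"` or `"deterministic"`.
#' @return Numeric vector of frequencies, element 1 the present.
#' @export
sim_trajectory <- function(s, f, Ne, method = c("stochastic", "deterministic")) {
  method <- match.arg(method)
  N2 <- round(2 * Ne)
  x0 <- 1 / N2
  if (method == "deterministic") {
    if (s <= 0) stop("deterministic trajectories need s > 0")
    g <- 0:ceiling((2 / (s / 2)) * log((1 - x0) * f / (x0 * (1 - f))) + 10)
    x <- f / (f + (1 - f) * exp((s / 2) * g))
    return(x[x >= x0])
  }
  if (s > 0) {
    repeat {
      x <- x0
      path <- numeric(65536L)
      i <- 0L
      while (x > 0 && x < f) {
        xs <- x * (1 + s / 2 + s * x / 2) / (1 + s * x)
        x <- stats::rbinom(1L, N2, xs) / N2
        i <- i + 1L
        if (i > length(path)) path <- c(path, numeric(length(path)))
        path[i] <- x
      }
      if (x >= f) {
        path[i] <- f
        return(rev(path[seq_len(i)]))
      }
    }
  }
  # s = 0 with f set: neutral frequency path conditioned on backward loss
  repeat {
    x <- f
    path <- numeric(65536L)
    i <- 0L
    ok <- TRUE
    while (x >= x0) {
      x <- x - x / N2 + stats::rnorm(1L, 0, sqrt(x * (1 - x) / N2))
      if (x >= 1) { ok <- FALSE; break }
      i <- i + 1L
      if (i > length(path)) path <- c(path, numeric(length(path)))
      path[i] <- max(x, 0)
    }
    if (ok) return(c(f, path[seq_len(max(i - 1L, 0L))]))
  }
}

# one replicate under the configured scenario; assumes the RNG state is set
simulate_replicate_raw <- function(cfg) {
  ep <- scenario_epochs(cfg)
  map <- scenario_recomb_map(cfg)
  sel <- !is.null(cfg$selection)
  nd <- -1L
  traj <- numeric(0)
  if (sel) {
    repeat {
      nd <- stats::rbinom(1L, cfg$n, cfg$selection$f)
      if (nd >= 2L && nd <= cfg$n - 2L) break
    }
    traj <- sim_trajectory(cfg$selection$s, cfg$selection$f, cfg$Ne,
                           cfg$trajectory)
  }
  res <- .sim_locus_cpp(cfg$n, cfg$theta, map$breaks, map$cum,
                        ep$start, ep$size, nd, traj, 1 / (2 * cfg$Ne), 0.5)
  pos <- res$positions
  alle <- res$alleles
  sel_col <- NULL
  if (sel) {
    sel_col <- c(rep(1L, nd), rep(0L, cfg$n - nd))
    alle <- cbind(alle, sel_col)
    pos <- c(pos, 0.5)
  }
  o <- order(pos)
  pos <- pos[o]
  alle <- alle[, o, drop = FALSE]
  # infinite-sites positions: resolve coincident draws by minimal jitter
  for (j in seq_along(pos)[-1]) {
    if (pos[j] <= pos[j - 1]) pos[j] <- pos[j - 1] + 1e-9
  }
  ev <- if (sel) which(o == length(o)) else which.min(abs(pos - 0.5))
  # haplotype order is exchangeable; shuffle rows so derived carriers are
  # not block-ordered
  perm <- sample.int(cfg$n)
  alle <- alle[perm, , drop = FALSE]
  win <- haplotype_window(alle, positions = pos * cfg$locus_length,
                          evaluated_index = ev)
  attr(win, "t_mrca") <- res$t_mrca
  attr(win, "n_rec") <- res$n_rec
  win
}

#' Simulate one replicate of a scenario
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed for this replicate.
#' @param min_flank Minimum number of SNPs required on each side of the
#'   evaluated site; replicates falling short are regenerated with a fresh
#'   derived seed (the attempt count is recorded in the `attempts`
#'   attribute).
#' @return A [haplotype_window()] with `evaluated_index` at the selected
#'   site (selection scenarios) or the SNP nearest the locus midpoint.
#' @export
simulate_replicate <- function(cfg, seed = cfg$seed, min_flank = 0L) {
  for (attempt in 0:49) {
    set.seed((as.numeric(seed) + 7919 * attempt) %% 2147483647)
    win <- simulate_replicate_raw(cfg)
    ok <- win$evaluated_index > min_flank &&
      win$S - win$evaluated_index >= min_flank
    if (ok) {
      attr(win, "attempts") <- attempt + 1L
      return(win)
    }
  }
  stop("failed to obtain a replicate with ", min_flank,
       " SNPs on each flank after 50 attempts")
}

new_replicate_set <- function(replicates, cfg, rep_seeds, n_regen) {
  structure(list(replicates = replicates, scenario = cfg,
                 n_reps = length(replicates), rep_seeds = rep_seeds,
                 n_regenerated = n_regen),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("Replicate set:", x$n_reps, "replicates of n =", x$scenario$n,
      "haplotypes\n")
  print(x$scenario)
  invisible(x)
}

simulate_set <- function(cfg, n_reps, min_flank) {
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  reps <- vector("list", n_reps)
  regen <- 0L
  for (i in seq_len(n_reps)) {
    reps[[i]] <- simulate_replicate(cfg, rep_seeds[i], min_flank)
    regen <- regen + attr(reps[[i]], "attempts") - 1L
  }
  new_replicate_set(reps, cfg, rep_seeds, regen)
}

#' Simulate neutral replicates
#'
#' Coalescent samples with infinite-sites mutation at rate `theta`,
#' recombination and demography per the scenario. The scenario must not
#' request selection.
#'
#' @inheritParams simulate_replicate
#' @param n_reps Number of replicates.
#' @return Object of class `replicate_set`.
#' @export
simulate_neutral <- function(cfg, n_reps, min_flank = 0L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$selection)) {
    stop("scenario requests selection; use simulate_sweep()")
  }
  simulate_set(cfg, n_reps, min_flank)
}

#' Simulate replicates under an ongoing selective sweep
#'
#' Structured-coalescent samples conditioned on the selected allele
#' currently segregating at population frequency `f` under additive
#' selection `s`, with neutral mutations at rate `theta` dropped on the
#' resulting genealogies and any configured recombination map honoured.
#' With `s = 0` (and `f` set) this falls back to a frequency-conditioned
#' neutral simulation; this is documented behaviour, not an error.
#'
#' @inheritParams simulate_neutral
#' @return Object of class `replicate_set`; each replicate's
#'   `evaluated_index` marks the selected site.
#' @export
simulate_sweep <- function(cfg, n_reps, min_flank = 0L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(cfg$selection)) stop("scenario has no selection parameters")
  simulate_set(cfg, n_reps, min_flank)
}

#' Cartesian grid of selection scenarios
#'
#' @param base A [scenario_config()] providing all shared parameters.
#' @param f_values Current selected-allele frequencies.
#' @param s_values Selection coefficients.
#' @return List of `scenario_config` objects with distinct derived seeds.
#' @export
scenario_grid <- function(base, f_values, s_values) {
  stopifnot(inherits(base, "scenario_config"))
  if (any(f_values <= 0 | f_values >= 1)) stop("f values must lie in (0,1)")
  if (any(s_values < 0)) stop("s values must be non-negative")
  out <- list()
  i <- 0L
  for (s in s_values) for (f in f_values) {
    i <- i + 1L
    cfg <- base
    cfg$selection <- list(s = s, f = f)
    cfg$seed <- as.integer((as.numeric(base$seed) + 104729 * i) %% 2147483647)
    cfg$label <- sprintf("s=%g,f=%g", s, f)
    out[[i]] <- cfg
  }
  out
}

#' Matched neutral configuration for a selection scenario
#'
#' Returns the scenario with the selection coefficient set to zero and
#' every other parameter identical -- including the conditioning on the
#' current frequency `f` of the evaluated allele, which under `s = 0`
#' becomes a frequency-conditioned neutral simulation. Calibrating the
#' critical value on this matched null (rather than on an unconditioned
#' neutral sample) is essential: the evaluated site then carries a
#' derived allele at the same frequency in both null and alternative, so
#' the test measures the sweep signature and not merely the presence of a
#' high-frequency derived allele. The seed is re-derived so null and
#' alternative use independent streams.
#'
#' @param cfg A selection [scenario_config()].
#' @return A `scenario_config` with `selection$s = 0`.
#' @export
match_null <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(cfg$selection)) stop("scenario has no selection parameters")
  cfg$selection$s <- 0
  cfg$seed <- as.integer((as.numeric(cfg$seed) + 1299709) %% 2147483647)
  cfg$label <- if (is.null(cfg$label)) "matched null" else
    paste(cfg$label, "(matched null)")
  cfg
}

#' Extract a fixed-size window centred on a site
#'
#' Takes the `S` SNPs centred on `center` (for even `S` the centre sits at
#' 0-based index `floor(S/2)` within the window, i.e. with `floor(S/2)`
#' SNPs to its left).
#'
#' @param window A [haplotype_window()] spanning at least `S` sites.
#' @param S Window size in SNPs.
#' @param center 1-based index of the focal site (defaults to the
#'   evaluated site).
#' @return A [haplotype_window()] of exactly `S` sites with
#'   `evaluated_index` at the focal site.
#' @export
extract_window <- function(window, S, center = window$evaluated_index) {
  stopifnot(inherits(window, "hap_window"))
  if (is.na(center)) stop("no focal site available")
  lo <- center - floor(S / 2)
  hi <- lo + S - 1L
  if (lo < 1L || hi > window$S) {
    stop("not enough SNPs on a flank for a window of size ", S)
  }
  idx <- lo:hi
  haplotype_window(window$alleles[, idx, drop = FALSE],
                   positions = window$sites$position[idx],
                   site_ids = window$sites$site_id[idx],
                   ancestral_allele = window$sites$ancestral_allele[idx],
                   derived_allele = window$sites$derived_allele[idx],
                   evaluated_index = center - lo + 1L,
                   require_segregating = FALSE)
}
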