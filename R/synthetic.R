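# Synthetic cohort generator: d_x curves with a known three-component
# structure (infant spike, premature-mortality hump, old-age peak) and known
# cluster labels, for testing smoothing, FPCA and clustering end to end.

#' Define a synthetic cohort scenario
#'
#' A scenario fixes the mixture that generates one d_x curve: a steep
#' exponential infant component over ages 0-2, an optional bounded unimodal
#' premature-mortality hump (roughly ages 20-65), and an old-age peak whose
#' location (`mode_age`, the adult modal age at death) and spread (`mode_sd`)
#' encode shifting and compression. Component masses are exact targets on the
#' discretized grid; multiplicative log-normal noise (then renormalization to
#' the radix) makes smoothing non-trivial while keeping curves non-negative
#' and mass-conserving.
#'
#' @param infant_mass Fraction of deaths at ages 0-2 (e.g. 0.04 vs 0.02).
#' @param hump_mass Fraction of deaths in the premature component.
#' @param hump_loc,hump_scale Location and spread (years) of the premature
#'   hump.
#' @param mode_age Adult modal age at death (years), in (40, 110).
#' @param mode_sd Spread of the old-age peak (years).
#' @param noise_cv Coefficient of variation of the multiplicative observation
#'   noise (0 = noiseless).
#' @param infant_scale Decay scale (years) of the infant exponential.
#' @return A `cohort_scenario` object (a validated list).
#' @export
cohort_scenario <- function(infant_mass = 0.02, hump_mass = 0,
                            hump_loc = 45, hump_scale = 10,
                            mode_age = 80, mode_sd = 7,
                            noise_cv = 0, infant_scale = 0.4) {
  if (infant_mass < 0 || hump_mass < 0 || infant_mass + hump_mass >= 1) {
    stop("component masses must be >= 0 with infant_mass + hump_mass < 1")
  }
  if (mode_age <= 40 || mode_age >= 110) stop("mode_age must lie in (40, 110)")
  if (mode_sd <= 0 || hump_scale <= 0 || infant_scale <= 0) {
    stop("all scale parameters must be > 0")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(
    list(infant_mass = infant_mass, hump_mass = hump_mass,
         hump_loc = hump_loc, hump_scale = hump_scale,
         mode_age = mode_age, mode_sd = mode_sd,
         noise_cv = noise_cv, infant_scale = infant_scale),
    class = "cohort_scenario"
  )
}

# Mass of a kernel on age bins [x - 0.5, x + 0.5] for x = 0..110, truncated to
# the bin system and renormalized so the component carries its mass exactly.
bin_edges <- function(ages) c(ages[1] - 0.5, ages + 0.5)

component_bins <- function(cdf, ages) {
  e <- bin_edges(ages)
  m <- diff(cdf(e))
  m[m < 0] <- 0
  s <- sum(m)
  if (s <= 0) stop("degenerate component: no mass on the age grid")
  m / s
}

#' Generate one synthetic d_x curve
#'
#' Discretizes the scenario's three-component mixture on the age grid (bins
#' centred on integer ages), applies multiplicative log-normal noise with unit
#' mean and coefficient of variation `noise_cv`, and renormalizes so the curve
#' sums exactly to the radix. Deterministic given `seed`.
#'
#' @param scenario A [cohort_scenario()].
#' @param ages Integer age grid (default 0:110).
#' @param radix Total deaths (default 100000).
#' @param seed Integer seed for the noise draw (ignored when `noise_cv = 0`).
#' @return Numeric vector of d_x values over `ages`, summing to `radix`.
#' @export
generate_dx <- function(scenario, ages = 0:110, radix = 100000, seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  s <- scenario
  w <- numeric(length(ages))
  if (s$infant_mass > 0) {
    # truncated exponential supported on [0, 2.5): all mass within ages 0-2
    inf_cdf <- function(x) {
      x <- pmin(pmax(x, 0), 2.5)
      stats::pexp(x, rate = 1 / s$infant_scale)
    }
    w <- w + s$infant_mass * component_bins(inf_cdf, ages)
  }
  if (s$hump_mass > 0) {
    hump_cdf <- function(x) stats::pnorm(x, s$hump_loc, s$hump_scale)
    w <- w + s$hump_mass * component_bins(hump_cdf, ages)
  }
  old_mass <- 1 - s$infant_mass - s$hump_mass
  old_cdf <- function(x) stats::pnorm(x, s$mode_age, s$mode_sd)
  w <- w + old_mass * component_bins(old_cdf, ages)

  if (s$noise_cv > 0) {
    sdlog <- sqrt(log(1 + s$noise_cv^2))
    noise <- withr::with_seed(as.integer(seed), {
      stats::rlnorm(length(ages), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    w <- w * noise
  }
  radix * w / sum(w)
}

#' Generate a labelled panel of synthetic cohorts
#'
#' Draws `n_per_cluster` curves from each scenario, with optional Gaussian
#' jitter on scenario parameters (within-cluster heterogeneity) and per-curve
#' observation noise. Returns the curve set together with the true labels so
#' cluster-recovery experiments can score themselves.
#'
#' @param scenarios_by_cluster Named list of [cohort_scenario()]s, one per
#'   cluster (at least 2 for recovery experiments; 1 is allowed).
#' @param n_per_cluster Curves per cluster (>= 1).
#' @param jitter Named list of standard deviations for parameter jitter, e.g.
#'   `list(mode_age = 0.8, infant_mass = 0.003)`; names must be scenario
#'   fields. Jittered values are clamped to their valid ranges.
#' @param seed Integer seed controlling jitter and noise.
#' @param ages Age grid.
#' @return A list with `curves` (a [curve_set()]), `labels` (integer vector),
#'   and `cluster_names`.
#' @export
generate_panel <- function(scenarios_by_cluster, n_per_cluster = 20,
                           jitter = list(), seed = 1L, ages = 0:110) {
  stopifnot(length(scenarios_by_cluster) >= 1)
  if (n_per_cluster < 1) stop("n_per_cluster must be >= 1")
  for (s in scenarios_by_cluster) stopifnot(inherits(s, "cohort_scenario"))
  K <- length(scenarios_by_cluster)
  cl_names <- names(scenarios_by_cluster)
  if (is.null(cl_names)) cl_names <- paste0("cluster", seq_len(K))

  n <- K * n_per_cluster
  curves <- matrix(NA_real_, n, length(ages))
  labels <- rep(seq_len(K), each = n_per_cluster)

  withr::with_seed(as.integer(seed), {
    curve_seeds <- sample.int(.Machine$integer.max - 1L, n)
    for (i in seq_len(n)) {
      base <- scenarios_by_cluster[[labels[i]]]
      pars <- unclass(base)
      for (nm in names(jitter)) {
        if (!nm %in% names(pars)) stop("unknown jitter parameter: ", nm)
        pars[[nm]] <- pars[[nm]] + stats::rnorm(1, 0, jitter[[nm]])
      }
      # clamp back into the scenario's valid domain
      pars$infant_mass <- min(max(pars$infant_mass, 0), 0.5)
      pars$hump_mass <- min(max(pars$hump_mass, 0), 0.5)
      pars$mode_age <- min(max(pars$mode_age, 40.5), 109.5)
      for (nm in c("mode_sd", "hump_scale", "infant_scale")) {
        pars[[nm]] <- max(pars[[nm]], 0.1)
      }
      sc <- do.call(cohort_scenario, pars)
      curves[i, ] <- generate_dx(sc, ages = ages, seed = curve_seeds[i])
    }
  })

  idx <- tibble::tibble(country = paste0(cl_names[labels], "_",
                                         stats::ave(labels, labels,
                                                    FUN = seq_along)),
                        year = seq_len(n), sex = "synthetic")
  list(curves = curve_set(curves, ages = ages, index = idx, radix_tol = 1e-6),
       labels = labels, cluster_names = cl_names)
}

#' Reference scenarios emulating the three observed mortality regimes
#'
#' Three scenarios mirroring the qualitative regimes seen across developed
#' countries 1960-2018: `infant` (high infant mortality, early mode),
#' `premature` (pronounced premature-mortality hump, depressed adult mode) and
#' `shifted` (low infant mortality, late and compressed old-age peak). Used as
#' the package's standard cluster-recovery panel.
#'
#' @param noise_cv Observation noise level shared by all three (default 0.05).
#' @return Named list of three [cohort_scenario()]s.
#' @export
regime_scenarios <- function(noise_cv = 0.05) {
  list(
    infant = cohort_scenario(infant_mass = 0.04, hump_mass = 0.03,
                             hump_loc = 45, hump_scale = 12,
                             mode_age = 76, mode_sd = 8, noise_cv = noise_cv),
    premature = cohort_scenario(infant_mass = 0.02, hump_mass = 0.12,
                                hump_loc = 50, hump_scale = 12,
                                mode_age = 74, mode_sd = 9,
                                noise_cv = noise_cv),
    shifted = cohort_scenario(infant_mass = 0.005, hump_mass = 0.02,
                              hump_loc = 55, hump_scale = 10,
                              mode_age = 87, mode_sd = 5.5,
                              noise_cv = noise_cv)
  )
}

#' Standard jitter for the regime panel
#' @return Named list of jitter standard deviations.
#' @export
regime_jitter <- function() {
  list(mode_age = 0.8, mode_sd = 0.3, infant_mass = 0.003, hump_mass = 0.008)
}
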