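# Synthetic cohorts of paired arterial/venous ICP prediction samples.
#
# The generator emulates the distributional structure of the reference
# cohort: hold-out-like cases carry right-skewed predictive distributions
# (lognormal / gamma / logistic) whose medians sit close to the measured
# ICP, while cautionary cases carry an arterial distribution that has
# degenerated toward uniform over a wide support, with its median far from
# the measured value. Defaults (sample sizes 248-3617 per vessel, sd 5-9 cm
# water for hold-out-like cases, uniform widths 45-55 cm water) span the
# per-case ranges of the reference cohort table.

SYNTH_FAMILIES <- c("lognormal", "gamma", "beta_scaled", "logistic",
                    "uniform", "normal")

#' Solve family parameters from a target median and sd
#'
#' Closed forms where available: lognormal `mu = log(median)` with
#' `sigma^2 = log((1 + sqrt(1 + 4 sd^2/median^2)) / 2)`; uniform centred on
#' the median with width `sd * sqrt(12)`; logistic location = median,
#' scale = `sd * sqrt(3) / pi`; normal mean = median. The gamma shape is
#' solved numerically (median has no closed form); `beta_scaled` maps a
#' Beta(alpha, beta) onto the interval `[median - 2.5 sd, median + 5 sd]`
#' (asymmetric, so the family is right-skewed like the predictive
#' distributions it emulates) with alpha, beta solved from the target
#' mean/sd on the unit interval.
#'
#' @param family One of `r paste(SYNTH_FAMILIES, collapse = ", ")`.
#' @param median Target median, cm water (> 0 for positive-support families).
#' @param sd Target standard deviation, cm water (> 0).
#' @return Named list of family parameters.
#' @export
params_from_median_sd <- function(family, median, sd) {
  family <- match.arg(family, SYNTH_FAMILIES)
  if (!is.finite(sd) || sd <= 0)
    stop_icpdx("feasibility_error", "`sd` must be positive.")
  if (family %in% c("lognormal", "gamma") && median <= 0)
    stop_icpdx("feasibility_error",
               sprintf("%s needs a positive median.", family))
  switch(family,
    lognormal = {
      ew <- (1 + sqrt(1 + 4 * sd^2 / median^2)) / 2
      list(meanlog = log(median), sdlog = sqrt(log(ew)))
    },
    gamma = {
      f <- function(logk) {
        k <- exp(logk)
        stats::qgamma(0.5, shape = k, scale = sd / sqrt(k)) - median
      }
      root <- stats::uniroot(f, c(log(1e-3), log(1e8)), tol = 1e-10)
      k <- exp(root$root)
      list(shape = k, scale = sd / sqrt(k))
    },
    beta_scaled = {
      lo <- median - 2.5 * sd; hi <- median + 5 * sd
      m01 <- (median - lo) / (hi - lo)
      s01 <- sd / (hi - lo)
      if (s01^2 >= m01 * (1 - m01))
        stop_icpdx("feasibility_error",
                   "target sd too large for the scaled beta support.")
      nu <- m01 * (1 - m01) / s01^2 - 1
      list(alpha = m01 * nu, beta = (1 - m01) * nu, lo = lo, hi = hi)
    },
    logistic = list(location = median, scale = sd * sqrt(3) / pi),
    uniform = list(min = median - sd * sqrt(3), max = median + sd * sqrt(3)),
    normal = list(mean = median, sd = sd)
  )
}

draw_family <- function(family, params, n) {
  switch(family,
    lognormal = stats::rlnorm(n, params$meanlog, params$sdlog),
    gamma = stats::rgamma(n, shape = params$shape, scale = params$scale),
    beta_scaled = params$lo +
      (params$hi - params$lo) * stats::rbeta(n, params$alpha, params$beta),
    logistic = stats::rlogis(n, params$location, params$scale),
    uniform = stats::runif(n, params$min, params$max),
    normal = stats::rnorm(n, params$mean, params$sd),
    stop_icpdx("name_error", sprintf("unknown family: %s", family))
  )
}

#' Draw reproducible samples from a parameterized family
#'
#' Identical `(family, params, n, seed)` yield identical draws; the
#' caller's RNG state is untouched.
#'
#' @param family One of `r paste(SYNTH_FAMILIES, collapse = ", ")`.
#' @param params Parameters from [params_from_median_sd()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(family, params, n, seed = 1234L) {
  if (!family %in% SYNTH_FAMILIES)
    stop_icpdx("name_error", sprintf("unknown family: %s", family))
  if (!is.numeric(n) || n < 1)
    stop_icpdx("validation_error", "`n` must be >= 1.")
  withr::with_seed(seed, draw_family(family, params, n))
}

#' Generate a synthetic cohort of prediction records
#'
#' @param regime `"holdout_like"` (right-skewed, well-centred predictive
#'   distributions for both vessels), `"cautionary"` (arterial distribution
#'   uniform over a 45-55 cm water support with median displaced >= 15 cm
#'   water from the measured ICP; venous moderately displaced), or
#'   `"mixed"` (alternating, with per-case subset labels).
#' @param n_cases Number of cases (>= 1).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of `(regime, n_cases, seed)`.
#' @return List of [case_record()]s (two per case) with metadata attached.
#' @export
make_synthetic_cohort <- function(regime = c("holdout_like", "cautionary", "mixed"),
                                  n_cases = 1L, seed = 1234L) {
  if (is.character(regime) && length(regime) == 1L &&
      !regime %in% c("holdout_like", "cautionary", "mixed"))
    stop_icpdx("name_error", sprintf("unknown regime: %s", regime))
  regime <- match.arg(regime)
  if (n_cases < 1L) stop_icpdx("validation_error", "`n_cases` must be >= 1.")
  withr::with_seed(seed, {
    purrr::map(seq_len(n_cases), function(i) {
      kind <- switch(regime, mixed = if (i %% 2L == 1L) "holdout_like" else "cautionary",
                     regime)
      if (kind == "holdout_like") {
        measured <- stats::runif(1, 17, 32)
        meta <- case_metadata(
          case_id = sprintf("synth_%03d", i), measured_icp = measured,
          laterality = sample(c(2L, 2L, 2L, 1L), 1), # bilateral-dominant, as observed
          n_iop_levels = sample(7:15, 1), subset = "hold_out")
        recs <- purrr::map(VESSELS, function(v) {
          fam <- sample(c("lognormal", "gamma", "logistic"), 1)
          md <- measured + stats::runif(1, -3, 3)
          par <- params_from_median_sd(fam, md, stats::runif(1, 5, 9))
          case_record(meta$case_id, v,
                      draw_family(fam, par, sample(248:3617, 1)), meta)
        })
      } else {
        measured <- stats::runif(1, 8, 12)
        meta <- case_metadata(
          case_id = sprintf("synth_%03d", i), measured_icp = measured,
          laterality = 1L, n_iop_levels = sample(7:15, 1),
          subset = "cautionary")
        width <- stats::runif(1, 45, 55)
        art_par <- params_from_median_sd(
          "uniform", measured + stats::runif(1, 15, 37), width / sqrt(12))
        ven_fam <- sample(c("logistic", "gamma", "beta_scaled"), 1)
        ven_par <- params_from_median_sd(
          ven_fam, measured + stats::runif(1, 10, 25), stats::runif(1, 4, 11))
        recs <- list(
          case_record(meta$case_id, "arterial",
                      draw_family("uniform", art_par, sample(248:3617, 1)), meta),
          case_record(meta$case_id, "venous",
                      draw_family(ven_fam, ven_par, sample(248:3617, 1)), meta))
      }
      recs
    }) |> purrr::flatten()
  })
}

# Generating parameters for harmonic samples, keyed by vessel and group;
# scales follow the observed ordering (vein amplitude above artery,
# cautionary below hold-out; first-harmonic dispersion above second;
# negative-shifted first-harmonic sine coefficient).
harmonic_params <- function(vessel, group) {
  amp_median <- if (vessel == "vein") {
    if (group == "hold_out") 7.0 else 6.1
  } else {
    if (group == "hold_out") 6.2 else 4.1
  }
  list(
    amp_shape = 2,                           # gamma shape 2: skew sqrt(2) > 1
    amp_scale = amp_median / stats::qgamma(0.5, shape = 2),
    a1_mean = if (vessel == "vein") 1.5 else -0.5, a1_sd = 2.4,
    b1_mean = -2.1, b1_sd = 2.0,
    a2_mean = if (vessel == "vein") -0.2 else 0.3, a2_sd = 0.9,
    b2_mean = 0.1, b2_sd = 0.85
  )
}

#' Generate synthetic harmonic-regression samples
#'
#' Draws the harmonic regression wave amplitude `hrw_a` from a right-skewed
#' gamma family (vein scale above artery scale) and the first/second
#' harmonic Fourier coefficients from normal families whose signs and
#' dispersions match the observed summaries (`b_n1` negative-shifted;
#' second-harmonic dispersions smaller than first).
#'
#' @param vessel `"artery"` or `"vein"`.
#' @param group `"hold_out"` or `"cautionary"`.
#' @param n Number of samples (>= 3).
#' @param seed Integer seed.
#' @return Tibble: `vessel`, `group`, `hrw_a`, `a_n1`, `b_n1`, `a_n2`,
#'   `b_n2`.
#' @export
make_harmonic_samples <- function(vessel = c("artery", "vein"),
                                  group = c("hold_out", "cautionary"),
                                  n = 100L, seed = 1234L) {
  vessel <- match.arg(vessel); group <- match.arg(group)
  if (n < 3L) stop_icpdx("validation_error", "`n` must be >= 3.")
  p <- harmonic_params(vessel, group)
  withr::with_seed(seed, tibble::tibble(
    vessel = vessel, group = group,
    hrw_a = stats::rgamma(n, shape = p$amp_shape, scale = p$amp_scale),
    a_n1 = stats::rnorm(n, p$a1_mean, p$a1_sd),
    b_n1 = stats::rnorm(n, p$b1_mean, p$b1_sd),
    a_n2 = stats::rnorm(n, p$a2_mean, p$a2_sd),
    b_n2 = stats::rnorm(n, p$b2_mean, p$b2_sd)
  ))
}
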