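# Shared fixtures and independent oracles for the test suite.

gaussian_sample <- function(n, mean = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, rnorm(n, mean, sd))
}

# Closed-form expectation of the DI statistic for a Gaussian kernel density
# estimate of Gaussian data: the KDE expectation is N(mu, sigma^2 + h^2),
# so the mass within +/- w of the centre is 2 Phi(w / sqrt(sigma^2 + h^2)) - 1.
gaussian_kde_di_oracle <- function(sigma, h, w = 1) {
  100 * (2 * pnorm(w / sqrt(sigma^2 + h^2)) - 1)
}

# Brute-force two-sample KS oracle: maximal ECDF gap evaluated on a fine
# grid covering the pooled range plus every pooled point.
brute_force_ks <- function(s1, s2) {
  xs <- sort(unique(c(s1, s2, seq(min(s1, s2) - 1, max(s1, s2) + 1,
                                  length.out = 2000))))
  f1 <- vapply(xs, function(x) mean(s1 <= x), numeric(1))
  f2 <- vapply(xs, function(x) mean(s2 <= x), numeric(1))
  max(abs(f1 - f2))
}

# Point sets representing each Cullen-Frey locus (the beta entry is the
# region boundary, including the s2 = 0.05 guard edge), used to measure
# minimum distances between family loci.
cf_locus_points <- function(family) {
  s2 <- seq(0, 20, length.out = 2001)
  switch(family,
    normal = cbind(0, 3),
    uniform = cbind(0, 1.8),
    logistic = cbind(0, 4.2),
    exponential = cbind(4, 9),
    gamma = cbind(s2, 3 + 1.5 * s2),
    lognormal = {
      w <- seq(1e-4, 3, length.out = 2001)
      ew <- exp(w)
      cbind((ew + 2)^2 * (ew - 1), ew^4 + 2 * ew^3 + 3 * ew^2 - 3)
    },
    beta = {
      s2b <- seq(0.05, 20, length.out = 2001)
      rbind(cbind(s2b, 1 + s2b), cbind(s2b, 3 + 1.5 * s2b),
            cbind(0.05, seq(1.05, 3.075, length.out = 200)))
    },
    stop("unknown family: ", family)
  )
}

cf_locus_distance <- function(f1, f2) {
  p1 <- cf_locus_points(f1); p2 <- cf_locus_points(f2)
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  sqrt(min(d2))
}

# Generators used in the distribution-classification self-consistency
# simulations.
cf_generators <- list(
  normal = function(n) rnorm(n, 25, 5),
  uniform = function(n) runif(n, 0, 50),
  logistic = function(n) rlogis(n, 25, 3),
  exponential = function(n) rexp(n, 0.1),
  gamma = function(n) rgamma(n, shape = 4, scale = 2),
  lognormal = function(n) rlnorm(n, log(25), 0.5)
)

# Classification success: the generating family itself, or a family whose
# locus passes within 0.25 of the generating family's locus (families whose
# loci touch -- gamma/beta boundary, exponential on the gamma line, the
# lognormal curve near the origin -- are visually indistinguishable on the
# skewness-kurtosis plane).
cf_success_rate <- function(family, n = 5000, seeds = 1:50) {
  labels <- vapply(seeds, function(s) {
    withr::with_seed(s, classify_sample(cf_generators[[family]](n)))
  }, character(1))
  ok <- vapply(labels, function(lab) {
    lab == family || cf_locus_distance(lab, family) <= 0.25
  }, logical(1))
  mean(ok)
}

write_temp_predictions <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "predictions.csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}

write_temp_metadata <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "metadata.csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}

small_metadata_df <- function(ids = c("a", "b")) {
  tibble::tibble(case_id = ids, measured_icp = 20 + seq_along(ids),
                 laterality = rep_len(c(2L, 1L), length(ids)),
                 n_iop_levels = rep_len(c(12L, 9L), length(ids)),
                 subset = rep_len(c("hold_out", "cautionary"), length(ids)))
}
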