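# Cullen-Frey classification: identify a candidate distribution family from
# the position of a sample in the (squared skewness, kurtosis) plane.
#
# Loci on the plane (non-excess kurtosis):
#   normal       point (0, 3)
#   uniform      point (0, 9/5)
#   logistic     point (0, 4.2)
#   exponential  point (4, 9)
#   gamma        line  k = 3 + 1.5 * s2       (shape swept over (0, Inf))
#   lognormal    curve (s(w)^2, k(w)), w = sigma^2:
#                  s(w) = (e^w + 2) sqrt(e^w - 1)
#                  k(w) = e^{4w} + 2 e^{3w} + 3 e^{2w} - 3
#   beta         the AREA between the impossibility boundary k = 1 + s2 and
#                the gamma line (exclusive), not a locus.
#
# A graph reader labels a point "beta" when it falls inside the beta area,
# otherwise by the nearest locus. The deterministic rule below formalizes
# that: beta-region membership first (with an s2 > 0.05 guard so that
# near-symmetric samples such as uniform ones, whose locus lies inside the
# region, are not absorbed), then nearest feature by Euclidean distance.

CF_POINTS <- list(normal = c(0, 3), uniform = c(0, 1.8),
                  logistic = c(0, 4.2), exponential = c(4, 9))

cf_lognormal_curve <- function(w) {
  ew <- exp(w)
  c((ew + 2)^2 * (ew - 1),                      # s(w)^2
    ew^4 + 2 * ew^3 + 3 * ew^2 - 3)             # k(w)
}

# distance from (s2, k) to the gamma ray {(t, 3 + 1.5 t), t >= 0}
cf_gamma_distance <- function(s2, k) {
  t <- (s2 + 1.5 * (k - 3)) / (1 + 1.5^2)      # perpendicular foot
  t <- max(t, 0)
  sqrt((s2 - t)^2 + (k - 3 - 1.5 * t)^2)
}

cf_lognormal_distance <- function(s2, k) {
  obj <- function(w) {
    p <- cf_lognormal_curve(w)
    (s2 - p[1])^2 + (k - p[2])^2
  }
  opt <- stats::optimize(obj, interval = c(1e-4, 3))
  sqrt(min(opt$objective, obj(1e-4), obj(3)))
}

cf_in_beta_region <- function(s2, k) {
  s2 > 0.05 && k >= 1 + s2 && k < 3 + 1.5 * s2
}

#' Cullen-Frey coordinates of a sample
#'
#' @param samples Numeric vector, n >= 3, nonzero variance.
#' @return Named numeric vector `c(s2, k)`: squared skewness and non-excess
#'   kurtosis from [sample_moments()].
#' @export
cullen_frey_coordinates <- function(samples) {
  m <- sample_moments(samples)
  if (is.na(m$skew))
    stop_icpdx("degenerate_error", "zero-variance sample has no Cullen-Frey position.")
  c(s2 = m$skew^2, k = m$kurtosis)
}

#' Classify a distribution family from Cullen-Frey coordinates
#'
#' Beta-region membership is checked first (beta is an area, not a locus);
#' otherwise the nearest feature by Euclidean distance in the
#' (squared-skewness, kurtosis) plane wins, with deterministic tie-break
#' priority normal > uniform > logistic > exponential > gamma > lognormal.
#'
#' @param s2 Squared skewness (>= 0), or a sample's coordinates via
#'   [cullen_frey_coordinates()].
#' @param k Non-excess kurtosis (> 0).
#' @return A list of class `icpdx_cullen_frey`: `s2`, `k`, `family`
#'   (character), `distances` (named vector; the beta entry is 0 inside the
#'   region and `Inf` outside).
#' @examples
#' classify_distribution(0, 3)$family           # "normal"
#' classify_distribution((-0.11)^2, 1.83)$family # "uniform"
#' @export
classify_distribution <- function(s2, k) {
  if (!is.finite(s2) || !is.finite(k) || s2 < 0 || k <= 0)
    stop_icpdx("validation_error", "need finite s2 >= 0 and k > 0.")
  d <- c(
    normal      = sqrt(s2^2 + (k - 3)^2),
    uniform     = sqrt(s2^2 + (k - 1.8)^2),
    logistic    = sqrt(s2^2 + (k - 4.2)^2),
    exponential = sqrt((s2 - 4)^2 + (k - 9)^2),
    gamma       = cf_gamma_distance(s2, k),
    lognormal   = cf_lognormal_distance(s2, k),
    beta        = if (cf_in_beta_region(s2, k)) 0 else Inf
  )
  family <- if (cf_in_beta_region(s2, k)) "beta"
            else names(d)[which.min(d[1:6])]   # which.min: first minimum = priority order
  structure(list(s2 = s2, k = k, family = family, distances = d),
            class = "icpdx_cullen_frey")
}

#' @export
print.icpdx_cullen_frey <- function(x, ...) {
  cat(sprintf("<icpdx_cullen_frey> (s2 = %.3f, k = %.3f) -> %s\n",
              x$s2, x$k, x$family))
  invisible(x)
}

#' Classify a sample's distribution family
#'
#' Convenience composition of [cullen_frey_coordinates()] and
#' [classify_distribution()].
#'
#' @param samples Numeric vector, n >= 3.
#' @return The classified family label (character scalar).
#' @export
classify_sample <- function(samples) {
  xy <- cullen_frey_coordinates(samples)
  classify_distribution(xy[["s2"]], xy[["k"]])$family
}
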