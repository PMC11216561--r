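# Cohort-level surface: the per-case diagnostics table, group summaries,
# univariate-F associations with the prediction error, correlation
# analyses, rank-sum comparisons of the harmonic-regression parameters and
# the 2-sd outlier rule.

#' Build the per-case diagnostics table
#'
#' Runs the full per-case pipeline over a cohort of prediction records:
#' density estimation and `DI_ICP`, distribution moments, Lilliefors KS and
#' Anderson-Darling normality statistics, Shannon entropy, Cullen-Frey
#' family classification and the prediction error `Diff_ICPmd`. One row per
#' case x vessel.
#'
#' @param records List of [case_record()]s with metadata attached (see
#'   [attach_metadata()]).
#' @param config An [analysis_config()].
#' @return Tibble in the canonical diagnostics column order.
#' @export
build_diagnostics_table <- function(records, config = analysis_config()) {
  rows <- purrr::map(records, function(rec) {
    if (is.null(rec$meta))
      stop_icpdx("join_error",
                 sprintf("case %s has no metadata; use attach_metadata().", rec$case_id))
    s <- rec$samples
    m <- sample_moments(s)
    pdf <- estimate_pdf(s, grid_size = config$grid_size, cut = config$cut)
    tibble::tibble(
      case_id = rec$case_id, vessel = rec$vessel,
      icp_measured = rec$meta$measured_icp, n = rec$n,
      n_iop_levels = rec$meta$n_iop_levels, laterality = rec$meta$laterality,
      mean = m$mean, median = m$median, mode = peak_density(pdf),
      sd = m$sd, skew = m$skew, kurtosis = m$kurtosis,
      di_icp = 100 * definite_integral(pdf, m$median - config$di_halfwidth,
                                       m$median + config$di_halfwidth),
      ads = anderson_darling(s), ks = lilliefors_ks(s),
      dist_type = classify_distribution(m$skew^2, m$kurtosis)$family,
      diff_icp_md = diff_icp_md(rec$meta$measured_icp, m$median),
      sent = shannon_entropy(s, n_bins = config$entropy_bins)$sent,
      subset = rec$meta$subset
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_cohort_table(out)
  out[DIAGNOSTICS_COLUMNS]
}

split_groups <- function(values, labels) {
  if (length(values) != length(labels))
    stop_icpdx("argument_error", "`values` and `labels` must have equal length.")
  keep <- !is.na(values) & !is.na(labels)
  if (any(!keep)) rlang::warn("dropping missing values/labels from group summary.")
  split(values[keep], factor(labels[keep]))
}

#' Per-group mean and standard error
#'
#' @param values Numeric vector.
#' @param labels Group labels, same length.
#' @return Tibble: `group_label`, `n`, `mean`, `se` (sd/sqrt(n), sd with
#'   n-1 denominator), `sd`.
#' @export
group_summary_mean_se <- function(values, labels) {
  groups <- split_groups(values, labels)
  purrr::imap(groups, function(v, g) {
    s <- if (length(v) > 1) stats::sd(v) else 0
    tibble::tibble(group_label = g, n = length(v), mean = mean(v),
                   se = s / sqrt(length(v)), sd = s)
  }) |> dplyr::bind_rows()
}

#' Per-group median and interquartile range
#'
#' @inheritParams group_summary_mean_se
#' @return Tibble: `group_label`, `n`, `median`, `iqr` (type-7 quantiles).
#' @export
group_summary_median_iqr <- function(values, labels) {
  groups <- split_groups(values, labels)
  purrr::imap(groups, function(v, g) {
    tibble::tibble(group_label = g, n = length(v),
                   median = stats::median(v),
                   iqr = stats::IQR(v, type = 7))
  }) |> dplyr::bind_rows()
}

#' Univariate F test of one predictor against a response
#'
#' For a categorical predictor, the one-way ANOVA F with df (k-1, n-k); for
#' a continuous predictor, the simple-linear-regression F with df (1, n-2).
#' Applied per predictor over the pooled case x vessel rows, this
#' reconstructs the cohort association table linking `Diff_ICPmd` to the
#' imaging and distribution characteristics.
#'
#' @param y Numeric response.
#' @param x Predictor (numeric, factor or character).
#' @param kind `"categorical"` or `"continuous"`.
#' @param predictor Label for the output row.
#' @return Tibble row: `predictor`, `f_value`, `p_value`, `df1`, `df2`.
#' @export
univariate_f <- function(y, x, kind = c("categorical", "continuous"),
                         predictor = deparse(substitute(x))) {
  predictor <- paste(as.character(predictor), collapse = " ")[1]
  kind <- match.arg(kind)
  if (length(y) != length(x) || length(y) < 3L)
    stop_icpdx("argument_error", "need >= 3 (y, x) pairs of equal length.")
  if (stats::var(y) == 0)
    stop_icpdx("degenerate_error", "response has zero variance.")
  if (kind == "categorical") {
    x <- factor(x)
    if (nlevels(x) < 2L)
      stop_icpdx("degenerate_error", "categorical predictor has a single level.")
    fit <- stats::lm(y ~ x)
  } else {
    x <- as.numeric(x)
    if (stats::var(x) == 0)
      stop_icpdx("degenerate_error", "continuous predictor has zero variance.")
    fit <- stats::lm(y ~ x)
  }
  a <- stats::anova(fit)
  tibble::tibble(predictor = predictor, f_value = a$`F value`[1],
                 p_value = a$`Pr(>F)`[1], df1 = a$Df[1], df2 = a$Df[2])
}

#' Pearson correlation with textbook standard error
#'
#' @param x,y Numeric vectors, n >= 3, both nonconstant.
#' @return Tibble row: `r`, `se_textbook` (`sqrt((1-r^2)/(n-2))`),
#'   `p_value` (two-sided t test), `n`, `method`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop_icpdx("argument_error", "need at least 3 complete pairs.")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_icpdx("degenerate_error", "constant vector: correlation undefined.")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tibble::tibble(r = r, se_textbook = sqrt((1 - r^2) / (n - 2)),
                 p_value = ct$p.value, n = n, method = "pearson")
}

# Integer coding of the discrete diagnostics-table variables for
# correlation analysis. Laterality is already coded 2 = bilateral,
# 1 = unilateral; the others follow the same smaller-is-first convention.
code_variable <- function(table, var) {
  v <- table[[var]]
  if (is.null(v)) stop_icpdx("name_error", sprintf("unknown variable: %s", var))
  switch(var,
    vessel = match(v, VESSELS),                 # arterial 1, venous 2
    subset = match(v, SUBSETS),                 # hold_out 1, cautionary 2
    dist_type = match(v, DIST_FAMILIES),
    as.numeric(v)
  )
}

discrete_vars <- c("laterality", "vessel", "subset", "dist_type")

#' Pairwise correlation matrix over diagnostics-table variables
#'
#' Discrete variables are numerically coded (laterality 2 = bilateral /
#' 1 = unilateral; vessel, subset and distribution family as stated integer
#' codes) and, by default, all pairs are correlated by Pearson on the
#' coded values. With `method = "polychoric"`, pairs where both variables
#' are discrete use the [polychoric_rho()] estimator on their contingency
#' table instead.
#'
#' @param table Diagnostics tibble.
#' @param variables Character vector of column names.
#' @param method `"pearson"` (default) or `"polychoric"`.
#' @return List with symmetric matrices `r` and `p` (p is `NA` for
#'   polychoric entries), `n`, and `method`.
#' @export
correlation_matrix <- function(table, variables,
                               method = c("pearson", "polychoric")) {
  method <- match.arg(method)
  coded <- purrr::map(setNames(variables, variables),
                      ~ code_variable(table, .x))
  k <- length(variables)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(variables, variables)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- variables[i]; vj <- variables[j]
    if (method == "polychoric" &&
        vi %in% discrete_vars && vj %in% discrete_vars) {
      tab <- base::table(factor(coded[[vi]]), factor(coded[[vj]]))
      est <- polychoric_rho(tab)
      r[i, j] <- r[j, i] <- est$rho
    } else {
      est <- pearson_r(coded[[vi]], coded[[vj]])
      r[i, j] <- r[j, i] <- est$r
      p[i, j] <- p[j, i] <- est$p_value
    }
  }
  list(r = r, p = p, n = nrow(table), method = method)
}

# Bivariate standard normal CDF P(X <= h, Y <= k; rho) via the
# correlation-integral identity Phi2 = Phi(h) Phi(k) + int_0^rho
# phi2(h, k; r) dr, integrated with stats::integrate.
pbinorm <- function(h, k, rho) {
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(stats::pnorm(k))
  if (is.infinite(k)) return(stats::pnorm(h))
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  dens <- function(r)
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) / (2 * pi * sqrt(1 - r^2))
  stats::pnorm(h) * stats::pnorm(k) +
    stats::integrate(function(r) vapply(r, dens, numeric(1)), 0, rho,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Polychoric correlation of a contingency table
#'
#' Two-step estimator: thresholds from the cumulative marginal proportions
#' via the inverse normal CDF, then the latent correlation maximizing the
#' multinomial likelihood of the bivariate-normal rectangle probabilities,
#' searched on `[-0.999, 0.999]` to tolerance 1e-6.
#'
#' @param contingency_table Matrix (or `table`) of counts, at least 2 x 2,
#'   all row and column margins positive.
#' @return List of class `icpdx_polychoric`: `rho`, `row_thresholds`,
#'   `col_thresholds`, `n`, `boundary` (TRUE when the optimum sits at the
#'   edge of the search interval, `|rho| >= 0.99`), `method`.
#' @export
polychoric_rho <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_icpdx("validation_error", "need at least a 2 x 2 table of counts.")
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_icpdx("validation_error", "all row and column margins must be positive.")
  n <- sum(tab)
  a <- stats::qnorm(cumsum(rowSums(tab)) / n)   # last entry Inf
  b <- stats::qnorm(cumsum(colSums(tab)) / n)
  a_full <- c(-Inf, a); b_full <- c(-Inf, b)
  cell_probs <- function(rho) {
    cdf <- outer(seq_along(a_full), seq_along(b_full),
                 Vectorize(function(i, j) pbinorm(a_full[i], b_full[j], rho)))
    diff(t(diff(t(cdf))))  # rectangle probabilities via double differencing
  }
  negll <- function(rho) {
    pr <- pmax(cell_probs(rho), 1e-12)
    -sum(tab * log(pr))
  }
  opt <- stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  structure(
    list(rho = rho, row_thresholds = a[-length(a)], col_thresholds = b[-length(b)],
         n = n, boundary = abs(rho) >= 0.99, method = "polychoric"),
    class = "icpdx_polychoric"
  )
}

#' @export
print.icpdx_polychoric <- function(x, ...) {
  cat(sprintf("<icpdx_polychoric> rho = %.4f (n = %d%s)\n", x$rho, x$n,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test with Bonferroni correction
#'
#' Mann-Whitney U with exact enumeration for small combined samples
#' (`n1 + n2 <= 12`, no ties) and the tie- and continuity-corrected normal
#' approximation otherwise.
#'
#' @param group1,group2 Numeric vectors, each n >= 1.
#' @param m_tests Number of tests in the family (>= 1) for the Bonferroni
#'   correction.
#' @return Tibble row: `statistic` (U), `p_raw`, `p_bonferroni`
#'   (`min(1, m_tests * p_raw)`).
#' @export
wilcoxon_ranksum <- function(group1, group2, m_tests = 1L) {
  if (m_tests < 1) stop_icpdx("argument_error", "`m_tests` must be >= 1.")
  if (length(group1) < 1L || length(group2) < 1L)
    stop_icpdx("validation_error", "both groups must be non-empty.")
  ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- (length(group1) + length(group2) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_raw = wt$p.value,
                 p_bonferroni = min(1, m_tests * wt$p.value))
}

#' Descriptive statistics of harmonic-regression parameters
#'
#' Median, IQR, min, max, range, skew and kurtosis of one harmonic
#' parameter (`hrw_a`, `a_n1`, `b_n1`, `a_n2`, `b_n2`), grouped by vessel
#' site and study group -- the per-field summary of the pulse-waveform
#' decomposition feeding the ICP models.
#'
#' @param harmonics Tibble from [make_harmonic_samples()] (columns
#'   `vessel`, `group`, and the harmonic parameters).
#' @param field Which parameter to summarize.
#' @return Tibble with one row per vessel x group.
#' @export
describe_harmonics <- function(harmonics, field = "hrw_a") {
  if (!field %in% names(harmonics))
    stop_icpdx("name_error", sprintf("unknown harmonic field: %s", field))
  harmonics |>
    dplyr::group_by(.data$vessel, .data$group) |>
    dplyr::group_modify(function(df, key) {
      m <- sample_moments(df[[field]])
      tibble::tibble(parameter = field, n = m$n, median = m$median,
                     iqr = m$iqr, min = m$min, max = m$max, range = m$range,
                     skew = m$skew, kurtosis = m$kurtosis)
    }) |>
    dplyr::ungroup()
}

#' Flag values more than two reference standard deviations from the mean
#'
#' The cohort outlier rule: a diagnostic value is flagged when it lies more
#' than 2 sd (n-1 denominator) from the mean of a reference set -- e.g. a
#' cautionary case's venous `DI_ICP` against the hold-out venous column.
#'
#' @param values Numeric vector to flag.
#' @param reference_values Numeric reference set, n >= 2.
#' @return Logical vector along `values`.
#' @export
flag_two_sd_outliers <- function(values, reference_values) {
  if (length(reference_values) < 2L)
    stop_icpdx("validation_error", "need at least 2 reference values.")
  s <- stats::sd(reference_values)
  if (s == 0) {
    rlang::warn("zero reference sd: no values flagged.")
    return(rep(FALSE, length(values)))
  }
  abs(values - mean(reference_values)) > 2 * s
}
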