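# Orchestration: configuration, the simulate -> analyze round trip, and
# the packaged-fixture checks. These functions are the programmatic
# interface; inst/cli/icpdx.R wraps them for shell use.

#' Analysis configuration
#'
#' @param grid_size Density grid points (default 512).
#' @param cut Density grid extension in bandwidths (default 4; keeps the
#'   kernel-tail truncation below the 1.2e-4 normalization tolerance).
#' @param entropy_bins Bins for [shannon_entropy()] (default 64).
#' @param di_halfwidth Half-width of the `DI_ICP` window, cm water
#'   (default 1).
#' @param alpha Significance threshold for reported tests (default 0.05).
#' @param correlation_method `"pearson"` (numeric-coded, default) or
#'   `"polychoric"` for discrete pairs.
#' @param seed Integer seed echoed into reports.
#' @return A list of class `icpdx_config`.
#' @export
analysis_config <- function(grid_size = 512L, cut = 4, entropy_bins = 64L,
                            di_halfwidth = 1, alpha = 0.05,
                            correlation_method = c("pearson", "polychoric"),
                            seed = 1234L) {
  if (di_halfwidth <= 0) stop_icpdx("argument_error", "`di_halfwidth` must be > 0.")
  if (entropy_bins < 2) stop_icpdx("argument_error", "`entropy_bins` must be >= 2.")
  structure(
    list(grid_size = as.integer(grid_size), cut = cut,
         entropy_bins = as.integer(entropy_bins),
         di_halfwidth = di_halfwidth, alpha = alpha,
         correlation_method = match.arg(correlation_method),
         seed = as.integer(seed)),
    class = "icpdx_config"
  )
}

#' Simulate a cohort and write the interchange CSVs
#'
#' @param regime Cohort regime, see [make_synthetic_cohort()].
#' @param n_cases Number of cases.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed); receives
#'   `predictions.csv` and `metadata.csv`.
#' @return Invisible named list of the two file paths.
#' @export
run_simulate <- function(regime, n_cases, seed, out_dir) {
  records <- make_synthetic_cohort(regime, n_cases, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- purrr::map(records, function(r)
    tibble::tibble(case_id = r$case_id, vessel = r$vessel,
                   predicted_icp = r$samples)) |> dplyr::bind_rows()
  metas <- unique(purrr::map(records, "meta"))
  meta <- purrr::map(metas, ~ tibble::as_tibble(unclass(.x))) |> dplyr::bind_rows()
  paths <- list(predictions = file.path(out_dir, "predictions.csv"),
                metadata = file.path(out_dir, "metadata.csv"))
  readr::write_csv(pred, paths$predictions, progress = FALSE)
  readr::write_csv(meta, paths$metadata, progress = FALSE)
  invisible(paths)
}

case_concordance <- function(records) {
  ids <- unique(vapply(records, `[[`, character(1), "case_id"))
  rows <- purrr::map(ids, function(id) {
    recs <- purrr::keep(records, ~ .x$case_id == id)
    vs <- vapply(recs, `[[`, character(1), "vessel")
    if (!all(VESSELS %in% vs)) return(NULL)
    art <- recs[[match("arterial", vs)]]$samples
    ven <- recs[[match("venous", vs)]]$samples
    ks <- two_sample_ks(art, ven)
    tibble::tibble(case_id = id, tsks = ks$d_stat, p_value = ks$p_value,
                   x_at_max = ks$x_at_max, n1 = ks$n1, n2 = ks$n2,
                   n_eff = ks$n_eff)
  })
  dplyr::bind_rows(rows)
}

anova_surface <- function(diag, alpha = 0.05) {
  specs <- list(
    list("laterality", "categorical"), list("n_iop_levels", "continuous"),
    list("n", "continuous"), list("vessel", "categorical"),
    list("sd", "continuous"), list("kurtosis", "continuous"),
    list("skew", "continuous"), list("di_icp", "continuous"),
    list("ads", "continuous"), list("ks", "continuous"),
    list("dist_type", "categorical"), list("subset", "categorical"),
    list("sent", "continuous")
  )
  if ("tsks" %in% names(diag)) specs <- c(specs, list(list("tsks", "continuous")))
  rows <- purrr::map(specs, function(sp) {
    tryCatch(
      univariate_f(diag$diff_icp_md, diag[[sp[[1]]]], kind = sp[[2]],
                   predictor = sp[[1]]),
      icpdx_error = function(e) {
        rlang::warn(sprintf("predictor %s skipped: %s", sp[[1]],
                            conditionMessage(e)))
        NULL
      })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$significant <- out$p_value < alpha
  out
}

correlation_surface <- function(diag) {
  vars <- intersect(c("laterality", "n_iop_levels", "n", "di_icp", "sent",
                      "ads", "ks", "sd", "skew", "kurtosis", "tsks"),
                    names(diag))
  pooled <- purrr::map(vars, function(v) {
    res <- tryCatch(pearson_r(code_variable(diag, v), diag$diff_icp_md),
                    icpdx_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(var1 = v, var2 = "diff_icp_md",
                                    scope = "pooled"), res)
  })
  per_vessel <- purrr::map(VESSELS, function(vs) {
    sub <- diag[diag$vessel == vs, ]
    res <- tryCatch(pearson_r(sub$di_icp, sub$diff_icp_md),
                    icpdx_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(var1 = "di_icp", var2 = "diff_icp_md",
                                    scope = vs), res)
  })
  dplyr::bind_rows(pooled, per_vessel)
}

group_summary_surface <- function(diag) {
  out <- list()
  for (vs in VESSELS) {
    sub <- diag[diag$vessel == vs, ]
    if (length(unique(sub$subset)) > 0 && nrow(sub)) {
      g <- group_summary_mean_se(sub$di_icp, sub$subset)
      g$quantity <- paste0("di_icp_", vs)
      out <- c(out, list(g))
    }
  }
  g <- group_summary_mean_se(diag$diff_icp_md,
                             ifelse(diag$laterality == 2, "bilateral", "unilateral"))
  g$quantity <- "diff_icp_md_by_laterality"
  out <- c(out, list(g))
  for (v in c("sd", "kurtosis", "skew")) {
    m <- group_summary_median_iqr(diag[[v]], diag$subset)
    m$quantity <- paste0(v, "_by_subset")
    out <- c(out, list(m))
  }
  s <- group_summary_mean_se(diag$sent, diag$vessel)
  s$quantity <- "sent_by_vessel"
  dplyr::bind_rows(c(out, list(s)))
}

outlier_surface <- function(diag) {
  rows <- purrr::map(VESSELS, function(vs) {
    ref <- diag$di_icp[diag$vessel == vs & diag$subset == "hold_out"]
    tst <- diag[diag$vessel == vs & diag$subset == "cautionary", ]
    if (length(ref) < 2L || nrow(tst) == 0L) return(NULL)
    tibble::tibble(case_id = tst$case_id, vessel = vs, di_icp = tst$di_icp,
                   reference_mean = mean(ref), reference_sd = stats::sd(ref),
                   flagged = flag_two_sd_outliers(tst$di_icp, ref))
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline on interchange CSVs
#'
#' Reads a predictions CSV and a metadata CSV, builds the per-case
#' diagnostics table, the per-case arterial/venous concordance, group
#' summaries, the univariate-F association table and the correlation
#' surface, applies the 2-sd outlier rule, and writes all numeric exports
#' plus a `report.json` echoing the effective configuration. Outputs are a
#' deterministic function of (inputs, config).
#'
#' @param predictions_path,metadata_path Input CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @return Invisible list with the computed tables (`diagnostics`,
#'   `concordance`, `group_summaries`, `anova`, `correlations`,
#'   `outliers`) and the output paths.
#' @export
run_analyze <- function(predictions_path, metadata_path, out_dir,
                        config = analysis_config()) {
  records <- attach_metadata(read_predictions_csv(predictions_path),
                             read_metadata_csv(metadata_path))
  diag <- build_diagnostics_table(records, config)
  conc <- case_concordance(records)
  if (nrow(conc))
    diag <- dplyr::left_join(diag, conc[c("case_id", "tsks")], by = "case_id")
  summaries <- group_summary_surface(diag)
  anova_tbl <- anova_surface(diag, alpha = config$alpha)
  corr_tbl <- correlation_surface(diag)
  outliers <- outlier_surface(diag)

  # all computation succeeded; only now touch the filesystem
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dens_dir <- file.path(out_dir, "densities")
  ecdf_dir <- file.path(out_dir, "ecdf")
  dir.create(dens_dir, showWarnings = FALSE)
  dir.create(ecdf_dir, showWarnings = FALSE)
  for (rec in records) {
    pdf <- estimate_pdf(rec$samples, grid_size = config$grid_size, cut = config$cut)
    readr::write_csv(density_to_tibble(pdf),
                     file.path(dens_dir, sprintf("%s_%s.csv", rec$case_id, rec$vessel)),
                     progress = FALSE)
  }
  for (id in unique(conc$case_id)) {
    recs <- purrr::keep(records, ~ .x$case_id == id)
    vs <- vapply(recs, `[[`, character(1), "vessel")
    readr::write_csv(
      ecdf_pair_to_tibble(recs[[match("arterial", vs)]]$samples,
                          recs[[match("venous", vs)]]$samples,
                          grid_size = config$grid_size),
      file.path(ecdf_dir, paste0(id, ".csv")), progress = FALSE)
  }
  write_diagnostics_csv(diag, file.path(out_dir, "diagnostics.csv"))
  readr::write_csv(anova_tbl, file.path(out_dir, "anova.csv"), progress = FALSE)
  readr::write_csv(corr_tbl, file.path(out_dir, "correlations.csv"), progress = FALSE)
  readr::write_csv(summaries, file.path(out_dir, "group_summaries.csv"), progress = FALSE)
  report <- list(
    software = list(package = "icpdx",
                    version = as.character(utils::packageVersion("icpdx"))),
    config = unclass(config),
    n_cases = length(unique(diag$case_id)),
    n_records = nrow(diag),
    concordance = conc,
    outlier_flags = outliers
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(diagnostics = diag, concordance = conc,
                 group_summaries = summaries, anova = anova_tbl,
                 correlations = corr_tbl, outliers = outliers,
                 out_dir = out_dir))
}

fixture_check_row <- function(quantity, computed, reference, tol) {
  tibble::tibble(quantity = quantity, computed = computed,
                 reference = reference, abs_diff = abs(computed - reference),
                 tolerance = tol, pass = abs(computed - reference) <= tol)
}

#' Recompute the reference-cohort aggregates and compare to printed values
#'
#' Recomputes every cohort-level quantity derivable from the packaged
#' per-case diagnostics fixture -- group means/SEs and medians/IQRs of the
#' reliability diagnostics, the pooled and per-vessel correlations with the
#' prediction error, the laterality and case-subtype F statistics, and the
#' 2-sd outlier flags -- and tabulates each against its published value.
#'
#' @param out_dir Optional output directory for `fixture_checks.csv`.
#' @return Tibble: `quantity`, `computed`, `reference`, `abs_diff`,
#'   `tolerance`, `pass`.
#' @export
run_fixture_checks <- function(out_dir = NULL) {
  t2 <- load_table2_fixture()
  ho <- t2[t2$subset == "hold_out", ]
  ca <- t2[t2$subset == "cautionary", ]
  art <- t2[t2$vessel == "arterial", ]
  ven <- t2[t2$vessel == "venous", ]
  se <- function(x) stats::sd(x) / sqrt(length(x))
  di_art <- group_summary_mean_se(art$di_icp, art$subset)
  lat <- group_summary_mean_se(
    t2$diff_icp_md, ifelse(t2$laterality == 2, "bilateral", "unilateral"))
  f_lat <- univariate_f(t2$diff_icp_md, t2$laterality, "categorical")
  f_case <- univariate_f(t2$diff_icp_md, t2$subset, "categorical")
  flags <- flag_two_sd_outliers(ca$di_icp[ca$vessel == "venous"],
                                ho$di_icp[ho$vessel == "venous"])
  checks <- dplyr::bind_rows(
    fixture_check_row("arterial_holdout_di_mean",
                      di_art$mean[di_art$group_label == "hold_out"], 14.14, 0.005),
    fixture_check_row("arterial_holdout_di_se",
                      di_art$se[di_art$group_label == "hold_out"], 1.07, 0.005),
    fixture_check_row("arterial_cautionary_di_mean",
                      di_art$mean[di_art$group_label == "cautionary"], 3.83, 0.005),
    fixture_check_row("arterial_cautionary_di_se",
                      di_art$se[di_art$group_label == "cautionary"], 0.56, 0.005),
    fixture_check_row("arterial_cautionary_di_sd",
                      di_art$sd[di_art$group_label == "cautionary"], 0.792, 0.0005),
    fixture_check_row("bilateral_diff_mean",
                      lat$mean[lat$group_label == "bilateral"], 3.07, 0.005),
    fixture_check_row("bilateral_diff_se",
                      lat$se[lat$group_label == "bilateral"], 0.56, 0.005),
    fixture_check_row("unilateral_diff_mean",
                      lat$mean[lat$group_label == "unilateral"], 14.54, 0.005),
    fixture_check_row("unilateral_diff_se",
                      lat$se[lat$group_label == "unilateral"], 4.37, 0.005),
    fixture_check_row("holdout_sd_median", stats::median(ho$sd), 7.852, 0.0005),
    fixture_check_row("holdout_kurtosis_median", stats::median(ho$kurtosis), 4.845, 0.0005),
    fixture_check_row("holdout_skew_median", stats::median(ho$skew), 1.0850, 0.0005),
    fixture_check_row("cautionary_sd_median", stats::median(ca$sd), 11.843, 0.0005),
    fixture_check_row("cautionary_kurtosis_median", stats::median(ca$kurtosis), 2.425, 0.0005),
    fixture_check_row("cautionary_skew_median", stats::median(ca$skew), -0.0450, 0.0005),
    fixture_check_row("arterial_sent_mean", mean(art$sent), 5.577, 0.0005),
    fixture_check_row("arterial_sent_min", min(art$sent), 5.171, 0.0005),
    fixture_check_row("arterial_sent_max", max(art$sent), 5.848, 0.0005),
    fixture_check_row("venous_sent_mean", mean(ven$sent), 5.451, 0.0005),
    fixture_check_row("venous_sent_min", min(ven$sent), 5.353, 0.0005),
    fixture_check_row("venous_sent_max", max(ven$sent), 5.592, 0.0005),
    fixture_check_row("r_di_diff", pearson_r(t2$di_icp, t2$diff_icp_md)$r,
                      -0.5213, 0.001),
    fixture_check_row("r_sent_diff", pearson_r(t2$sent, t2$diff_icp_md)$r,
                      0.4832, 0.001),
    fixture_check_row("r_di_diff_arterial",
                      pearson_r(art$di_icp, art$diff_icp_md)$r, -0.76, 0.005),
    fixture_check_row("r_di_diff_venous",
                      pearson_r(ven$di_icp, ven$diff_icp_md)$r, -0.10, 0.005),
    fixture_check_row("r_laterality_diff",
                      pearson_r(code_variable(t2, "laterality"), t2$diff_icp_md)$r,
                      -0.59, 0.005),
    fixture_check_row("f_laterality", f_lat$f_value, 8.5062, 0.005),
    fixture_check_row("p_laterality", f_lat$p_value, 0.01009, 0.00005),
    fixture_check_row("f_case_subtype", f_case$f_value, 65.217, 0.05),
    fixture_check_row("venous_case8_flagged", as.numeric(flags[1]), 1, 0),
    fixture_check_row("venous_case9_flagged", as.numeric(flags[2]), 1, 0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(checks, file.path(out_dir, "fixture_checks.csv"),
                     progress = FALSE)
  }
  checks
}
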