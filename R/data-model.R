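# Domain containers and CSV interchange.
#
# A "case" is one examined subject; each case carries up to two prediction
# sample sets (arterial and venous vessel models), every sample being one
# predicted ICP value (cm water) at one vascular data point. Case metadata
# holds the lumbar-puncture measured ICP and the imaging characteristics.

VESSELS <- c("arterial", "venous")
SUBSETS <- c("hold_out", "cautionary")
DIST_FAMILIES <- c("normal", "uniform", "logistic", "exponential",
                   "gamma", "lognormal", "beta")

# Column order of the diagnostics table (the cohort table twin); `subset`
# travels as a trailing column so that a written table re-reads losslessly.
DIAGNOSTICS_COLUMNS <- c(
  "case_id", "vessel", "icp_measured", "n", "n_iop_levels", "laterality",
  "mean", "median", "mode", "sd", "skew", "kurtosis", "di_icp", "ads",
  "ks", "dist_type", "diff_icp_md", "sent", "subset"
)

stop_icpdx <- function(class, msg) {
  rlang::abort(msg, class = c(paste0("icpdx_", class), "icpdx_error"))
}

#' Case metadata record
#'
#' @param case_id Opaque case label.
#' @param measured_icp Lumbar-puncture measured ICP, cm water (> 0).
#' @param laterality Imaging laterality code: 1 = unilateral, 2 = bilateral.
#' @param n_iop_levels Number of induced intraocular pressure levels
#'   applied during imaging (>= 1).
#' @param subset `"hold_out"` (external validation case) or `"cautionary"`
#'   (case with conflicting arterial/venous predictions).
#' @return A list of class `icpdx_case_metadata`.
#' @export
case_metadata <- function(case_id, measured_icp, laterality, n_iop_levels,
                          subset = c("hold_out", "cautionary")) {
  subset <- subset[1]
  if (!subset %in% SUBSETS)
    stop_icpdx("validation_error",
               sprintf("`subset` must be one of %s.", paste(SUBSETS, collapse = ", ")))
  if (!is.finite(measured_icp) || measured_icp <= 0)
    stop_icpdx("validation_error", "`measured_icp` must be a positive number (cm water).")
  laterality <- as.integer(laterality)
  if (!laterality %in% c(1L, 2L))
    stop_icpdx("validation_error",
               sprintf("`laterality` must be 1 (unilateral) or 2 (bilateral), got %s.", laterality))
  n_iop_levels <- as.integer(n_iop_levels)
  if (is.na(n_iop_levels) || n_iop_levels < 1L)
    stop_icpdx("validation_error", "`n_iop_levels` must be a count >= 1.")
  structure(
    list(case_id = as.character(case_id), measured_icp = as.numeric(measured_icp),
         laterality = laterality, n_iop_levels = n_iop_levels, subset = subset),
    class = "icpdx_case_metadata"
  )
}

normalize_vessel <- function(vessel) {
  v <- tolower(as.character(vessel))
  if (!all(v %in% VESSELS))
    stop_icpdx("validation_error",
               sprintf("`vessel` must be one of %s (case-insensitive).",
                       paste(VESSELS, collapse = ", ")))
  v
}

#' Case prediction record
#'
#' One case x vessel set of predicted ICP samples, optionally joined with
#' its case metadata.
#'
#' @param case_id Opaque case label.
#' @param vessel `"arterial"` or `"venous"` (case-insensitive).
#' @param samples Numeric vector of predicted ICP values, cm water; at
#'   least 3 finite values.
#' @param meta Optional [case_metadata()] for the case.
#' @return A list of class `icpdx_case_record` with fields `case_id`,
#'   `vessel`, `samples`, `n`, `meta`.
#' @export
case_record <- function(case_id, vessel, samples, meta = NULL) {
  vessel <- normalize_vessel(vessel)
  samples <- as.numeric(samples)
  if (length(samples) < 3L)
    stop_icpdx("validation_error",
               sprintf("case %s (%s): need at least 3 prediction samples, got %d.",
                       case_id, vessel, length(samples)))
  if (!all(is.finite(samples)))
    stop_icpdx("validation_error",
               sprintf("case %s (%s): all prediction samples must be finite.", case_id, vessel))
  if (!is.null(meta) && !inherits(meta, "icpdx_case_metadata"))
    stop_icpdx("validation_error", "`meta` must be built by case_metadata().")
  structure(
    list(case_id = as.character(case_id), vessel = vessel,
         samples = samples, n = length(samples), meta = meta),
    class = "icpdx_case_record"
  )
}

#' @export
print.icpdx_case_record <- function(x, ...) {
  cat(sprintf("<icpdx_case_record> %s / %s: n = %d, median = %.2f cm water\n",
              x$case_id, x$vessel, x$n, stats::median(x$samples)))
  invisible(x)
}

read_csv_quiet <- function(path, ...) {
  if (!file.exists(path))
    stop_icpdx("io_error", sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_icpdx("schema_error",
               sprintf("%s: missing required column(s): %s",
                       path, paste(missing, collapse = ", ")))
}

#' Read per-case prediction samples from CSV
#'
#' Expects columns `case_id,vessel,predicted_icp`; any additional columns
#' (e.g. `eye`, `iop_level`) are ignored for grouping. Rows are grouped by
#' (case_id, vessel) preserving sample order.
#'
#' Note on data provenance: the study this pipeline emulates reports its
#' arterial data-point total inconsistently (7,617 in the text versus a
#' per-case column summing to 8,623); readers of external data should trust
#' per-case counts, which is what this function reports.
#'
#' @param path CSV file path.
#' @return A list of [case_record()] objects (metadata not yet attached).
#' @export
read_predictions_csv <- function(path) {
  df <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(df, c("case_id", "vessel", "predicted_icp"), path)
  pred <- suppressWarnings(as.numeric(df$predicted_icp))
  bad <- which(is.na(pred) & !(is.na(df$predicted_icp) | df$predicted_icp == ""))
  if (length(bad))
    stop_icpdx("parse_error",
               sprintf("%s: non-numeric predicted_icp at data row(s) %s",
                       path, paste(head(bad, 5), collapse = ", ")))
  if (anyNA(pred))
    stop_icpdx("parse_error", sprintf("%s: empty predicted_icp values present.", path))
  df$predicted_icp <- pred
  df$vessel <- normalize_vessel(df$vessel)
  keys <- unique(df[c("case_id", "vessel")])
  records <- purrr::pmap(keys, function(case_id, vessel) {
    s <- df$predicted_icp[df$case_id == case_id & df$vessel == vessel]
    case_record(case_id, vessel, s)
  })
  records
}

#' Read case metadata from CSV
#'
#' Expects columns `case_id,measured_icp,laterality,n_iop_levels,subset`.
#'
#' @param path CSV file path.
#' @return A list of [case_metadata()] records (empty, with a warning, for
#'   a header-only file).
#' @export
read_metadata_csv <- function(path) {
  df <- read_csv_quiet(path)
  require_columns(df, c("case_id", "measured_icp", "laterality",
                        "n_iop_levels", "subset"), path)
  if (nrow(df) == 0L) {
    rlang::warn(sprintf("%s: metadata file has no rows.", path))
    return(list())
  }
  if (anyDuplicated(df$case_id))
    stop_icpdx("validation_error",
               sprintf("%s: duplicate case_id: %s", path,
                       paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", ")))
  purrr::pmap(df[c("case_id", "measured_icp", "laterality", "n_iop_levels", "subset")],
              case_metadata)
}

#' Attach case metadata to prediction records
#'
#' @param records List of [case_record()]s.
#' @param metadata List of [case_metadata()]s.
#' @return The records, each with `meta` populated.
#' @export
attach_metadata <- function(records, metadata) {
  meta_ids <- vapply(metadata, `[[`, character(1), "case_id")
  purrr::map(records, function(rec) {
    i <- match(rec$case_id, meta_ids)
    if (is.na(i))
      stop_icpdx("join_error",
                 sprintf("no metadata for case %s", rec$case_id))
    rec$meta <- metadata[[i]]
    rec
  })
}

validate_cohort_table <- function(table) {
  if (!is.data.frame(table))
    stop_icpdx("validation_error", "diagnostics table must be a data frame.")
  key <- paste(table$case_id, table$vessel)
  if (anyDuplicated(key))
    stop_icpdx("validation_error", "duplicate (case_id, vessel) rows in diagnostics table.")
  invisible(table)
}

#' Packaged cohort fixture: per-case diagnostics of the nine-case study
#'
#' Returns the 18-row (9 cases x arterial/venous) diagnostics table of the
#' reference cohort: seven hold-out external-validation cases plus two
#' cautionary cases whose arterial prediction distributions degenerated
#' toward uniform. Carries measured ICP, imaging characteristics, the
#' distribution moments, `DI_ICP`, Anderson-Darling and Lilliefors KS
#' statistics, Shannon entropy, the classified distribution family and the
#' prediction error `Diff_ICPmd` for every case x vessel.
#'
#' @return A tibble with the columns of [write_diagnostics_csv()].
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "reference_cohort_diagnostics.csv",
                      package = "icpdx", mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort_table(tbl)
  tbl
}

#' Packaged fixture: harmonic-regression descriptive statistics
#'
#' Reference descriptive statistics (median, IQR, min, max, range, skew,
#' kurtosis) of the harmonic regression wave amplitude `HRW_a` and the
#' Fourier cosine/sine coefficients of the first and second harmonics
#' (`a_n1`, `b_n1`, `a_n2`, `b_n2`), by vessel site and study group.
#'
#' @return A tibble with one row per parameter x site x group.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "reference_harmonics_summary.csv",
                      package = "icpdx", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a diagnostics table as CSV
#'
#' Columns follow the canonical diagnostics order; floats are serialized at
#' round-trip precision so that `read_diagnostics_csv(write_diagnostics_csv(x))`
#' is the identity.
#'
#' @param table Diagnostics tibble (see [build_diagnostics_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_csv <- function(table, path) {
  validate_cohort_table(table)
  cols <- intersect(DIAGNOSTICS_COLUMNS, names(table))
  extra <- setdiff(names(table), cols)
  out <- table[c(cols, extra)]
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_icpdx("io_error", sprintf("directory does not exist: %s", dir))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_diagnostics_csv
#' @export
read_diagnostics_csv <- function(path) {
  tbl <- read_csv_quiet(path)
  validate_cohort_table(tbl)
  tbl
}
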