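# CSV/JSON interchange with row-level validation. Laboratories submit
# spreadsheets; every reader validates the schema and reports offending rows
# by their data line number (header = line 1).

#' Read and validate a dPCR wells CSV
#'
#' Expected columns: `well_id`, `channel`, `n_total`, `n_negative`, and
#' optionally `sample`, `lab`, `set_id`, `partition_volume_ul`,
#' `dilution_factor`, `platform`. Rows failing the count invariants
#' (`n_total > 0`, `0 <= n_negative <= n_total`, positive volume, dilution
#' factor >= 1) are aggregated into one error naming each offending line.
#' A missing `partition_volume_ul` is filled from the platform default
#' ([default_partition_volume()]) when a `platform` column is present; a
#' missing `dilution_factor` defaults to 1.
#'
#' @param path CSV file path.
#' @return A validated wells tibble.
#' @export
read_wells_csv <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(wells, c("well_id", "channel", "n_total", "n_negative"),
                basename(path))
  if (!"partition_volume_ul" %in% names(wells)) wells$partition_volume_ul <- NA_real_
  if (!"dilution_factor" %in% names(wells)) wells$dilution_factor <- 1
  fill <- is.na(wells$partition_volume_ul)
  if (any(fill)) {
    if (!"platform" %in% names(wells)) {
      stop_vcnref(
        "partition_volume_ul missing and no platform column to supply a default",
        "vcnref_schema_error"
      )
    }
    wells$partition_volume_ul[fill] <-
      default_partition_volume(wells$platform[fill])
    inform(paste0("filled ", sum(fill),
                  " partition volume(s) from platform defaults"))
  }
  line <- seq_len(nrow(wells)) + 1  # header is line 1
  problems <- c(
    if (any(bad <- !is.finite(wells$n_total) | wells$n_total <= 0))
      paste0("line ", paste(line[bad], collapse = ","), ": n_total must be > 0"),
    if (any(bad <- !is.finite(wells$n_negative) | wells$n_negative < 0 |
              wells$n_negative > wells$n_total))
      paste0("line ", paste(line[bad], collapse = ","),
             ": need 0 <= n_negative <= n_total"),
    if (any(bad <- wells$partition_volume_ul <= 0))
      paste0("line ", paste(line[bad], collapse = ","),
             ": partition_volume_ul must be > 0"),
    if (any(bad <- wells$dilution_factor < 1))
      paste0("line ", paste(line[bad], collapse = ","),
             ": dilution_factor must be >= 1"),
    if (any(bad <- !wells$channel %in% c("target", "reference")))
      paste0("line ", paste(line[bad], collapse = ","),
             ": channel must be 'target' or 'reference'")
  )
  if (length(problems) > 0) {
    stop_vcnref(paste0("invalid wells file ", basename(path), ":\n  ",
                       paste(problems, collapse = "\n  ")),
                "vcnref_validation_error")
  }
  wells
}

#' Read a per-laboratory results CSV
#'
#' Columns: `lab_id`, `estimate`, `standard_uncertainty`, optionally
#' `sample`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_lab_results_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, c("lab_id", "estimate", "standard_uncertainty"),
                basename(path))
  if (any(!is.finite(d$estimate)) || any(d$standard_uncertainty < 0)) {
    stop_vcnref("estimates must be finite and uncertainties nonnegative",
                "vcnref_validation_error")
  }
  d
}

#' Read a Cq measurements CSV
#'
#' Columns: `sample`, `assay`, `cq`, `calibrator_quantity` (blank for
#' unknowns).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_cq_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, c("sample", "assay", "cq", "calibrator_quantity"),
                basename(path))
  if (any(d$cq <= 0, na.rm = TRUE)) {
    stop_vcnref("Cq values must be positive", "vcnref_validation_error")
  }
  d
}

#' Read an integration-site reports CSV
#'
#' Columns: `sample`, `lab_id`, `site_string`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_sites_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, c("sample", "lab_id", "site_string"), basename(path))
  d
}

#' Write results as CSV or JSON
#'
#' Serializes a result table (or a fitted object with a [glance()] method)
#' with full numeric precision; the CSV form appends `*_display` columns
#' rounded to three significant figures for report-style reading. JSON
#' round-trips values exactly (no digit truncation).
#'
#' @param x A data frame, `dl_consensus`, `standard_curve`, or `gmm_fit`.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default: by file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL) {
  if (!is.data.frame(x)) x <- generics::glance(x)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    num <- vapply(x, is.numeric, logical(1))
    disp <- x[num]
    names(disp) <- paste0(names(disp), "_display")
    disp[] <- lapply(disp, signif, digits = 3)
    readr::write_csv(dplyr::bind_cols(x, disp), path, progress = FALSE)
  }
  invisible(path)
}
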