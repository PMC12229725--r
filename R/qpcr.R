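# qPCR standard-curve quantification. Cq is linear in log10(quantity); the
# fitted slope yields the amplification efficiency E = 10^(-1/slope) - 1,
# which equals 1 for perfect per-cycle doubling (slope = -1/log10(2) ~ -3.32).

#' Amplification efficiency from a standard-curve slope
#'
#' \eqn{E = 10^{-1/slope} - 1}. A slope of \eqn{-1/\log_{10} 2 \approx -3.32}
#' corresponds to perfect doubling, \eqn{E = 1}.
#'
#' @param slope Numeric vector of standard-curve slopes (cycles per
#'   log10 copies); must be negative for a meaningful efficiency.
#' @return Numeric vector of efficiencies.
#' @examples
#' amplification_efficiency(-1 / log10(2))  # exactly 1
#' amplification_efficiency(-3.6)
#' @export
amplification_efficiency <- function(slope) {
  10^(-1 / slope) - 1
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(calibrator quantity) across the
#' calibrator dilution series. Calibrator replicates enter as individual
#' points. A valid amplification curve has a negative slope; a nonnegative
#' fitted slope or fewer than three distinct calibrator quantities is a
#' curve-failure error.
#'
#' @param calibrators Data frame with columns `cq` and `calibrator_quantity`
#'   (copies/reaction, > 0); rows with missing quantity are dropped.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_points`, `quantity_range`,
#'   and the underlying `lm` fit.
#' @examples
#' cal <- tibble::tibble(calibrator_quantity = rep(10^(3:5), each = 2),
#'                       cq = 39.9657 - 3.3219 * rep(3:5, each = 2))
#' fit_standard_curve(cal)
#' @export
fit_standard_curve <- function(calibrators) {
  check_columns(calibrators, c("cq", "calibrator_quantity"), "calibrator table")
  cal <- calibrators[!is.na(calibrators$calibrator_quantity), , drop = FALSE]
  if (any(cal$calibrator_quantity <= 0)) {
    stop_vcnref("calibrator quantities must be positive", "vcnref_curve_failure")
  }
  if (any(cal$cq <= 0)) {
    stop_vcnref("Cq values must be positive", "vcnref_curve_failure")
  }
  if (length(unique(cal$calibrator_quantity)) < 3) {
    stop_vcnref("need at least 3 distinct calibrator quantities",
                "vcnref_curve_failure")
  }
  fit <- lm(cq ~ log10(calibrator_quantity), data = cal)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_vcnref("fitted standard-curve slope is not negative",
                "vcnref_curve_failure")
  }
  # r^2 computed directly; summary.lm warns on an exactly linear series
  sst <- sum((cal$cq - mean(cal$cq))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      efficiency = amplification_efficiency(slope),
      n_points = nrow(cal),
      quantity_range = range(cal$calibrator_quantity),
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  Cq = %.4f %+.4f * log10(quantity)\n", x$intercept, x$slope))
  cat(sprintf("  r^2 = %.5f, efficiency E = %.4f\n", x$r_squared, x$efficiency))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = unname(s[, "Std. Error"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    efficiency = x$efficiency, n_points = x$n_points
  )
}

#' Is the amplification efficiency within the acceptance range?
#'
#' QC gate on the fitted efficiency; the conventional acceptance window is
#' 0.9 to 1.10, inclusive at both ends.
#'
#' @param curve A `standard_curve` object (or a numeric efficiency).
#' @param lo,hi Inclusive bounds (defaults 0.9 and 1.10).
#' @return Logical.
#' @export
efficiency_in_range <- function(curve, lo = 0.9, hi = 1.10) {
  e <- if (inherits(curve, "standard_curve")) curve$efficiency else curve
  e >= lo & e <= hi
}

#' Interpolate copy quantities from Cq values
#'
#' Inverts the standard curve: \eqn{quantity = 10^{(cq - intercept)/slope}}.
#' Cq values implying quantities outside the calibrator range are still
#' returned but trigger an extrapolation warning.
#'
#' @param curve A fitted `standard_curve`.
#' @param cq Numeric vector of quantification cycles.
#' @return Numeric vector of copies/reaction.
#' @export
quantify_cq <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((cq - curve$intercept) / curve$slope)
  out_of_range <- q < curve$quantity_range[1] * (1 - 1e-9) |
    q > curve$quantity_range[2] * (1 + 1e-9)
  if (any(out_of_range)) {
    warn(paste0(sum(out_of_range),
                " Cq value(s) fall outside the calibrator range (extrapolated)"))
  }
  q
}

#' VCN from calibrated qPCR quantities
#'
#' \eqn{VCN = ploidy \times target/reference}, with replicate variability
#' propagated by the ratio delta method when standard uncertainties are
#' supplied.
#'
#' @param target_quantity,reference_quantity Copies/reaction (vectors pair
#'   row-wise); reference must be positive.
#' @param ploidy_factor Default 2.
#' @param target_u,reference_u Optional standard uncertainties (default 0).
#' @return A tibble with `vcn`, `standard_uncertainty`, `ploidy_factor`.
#' @export
vcn_from_qpcr <- function(target_quantity, reference_quantity,
                          ploidy_factor = 2, target_u = 0, reference_u = 0) {
  vcn_from_duplex(
    tibble::tibble(value = target_quantity, standard_uncertainty = target_u),
    tibble::tibble(value = reference_quantity, standard_uncertainty = reference_u),
    ploidy_factor = ploidy_factor
  )
}

#' Cq table to per-sample VCN estimates
#'
#' Fits one standard curve per assay from the calibrator rows (those with a
#' `calibrator_quantity`), interpolates the unknown rows, and forms per-sample
#' VCNs from the mean target and reference quantities with the between-
#' replicate standard error carried through the ratio.
#'
#' @param cq_data Data frame with columns `sample`, `assay` (`"target"` /
#'   `"reference"`), `cq`, and `calibrator_quantity` (`NA` for unknowns).
#' @param ploidy_factor Default 2.
#' @param efficiency_range Length-2 QC bounds; out-of-range assays are
#'   flagged in the `efficiency_ok` column of the attached curve summary.
#' @return A tibble of per-sample VCN estimates; the per-assay curve
#'   summaries are attached as attribute `"curves"`.
#' @export
qpcr_vcn <- function(cq_data, ploidy_factor = 2,
                     efficiency_range = c(0.9, 1.10)) {
  check_columns(cq_data, c("sample", "assay", "cq", "calibrator_quantity"),
                "Cq table")
  if (!all(cq_data$assay %in% c("target", "reference"))) {
    stop_vcnref("assay must be 'target' or 'reference'", "vcnref_schema_error")
  }
  curves <- cq_data |>
    dplyr::filter(!is.na(.data$calibrator_quantity)) |>
    dplyr::group_by(.data$assay) |>
    dplyr::group_map(~ fit_standard_curve(.x)) |>
    setNames(sort(unique(cq_data$assay[!is.na(cq_data$calibrator_quantity)])))
  if (!all(c("target", "reference") %in% names(curves))) {
    stop_vcnref("calibrators required for both target and reference assays",
                "vcnref_curve_failure")
  }
  unknowns <- cq_data |>
    dplyr::filter(is.na(.data$calibrator_quantity)) |>
    dplyr::mutate(quantity = ifelse(
      .data$assay == "target",
      quantify_cq(curves$target, .data$cq),
      quantify_cq(curves$reference, .data$cq)
    ))
  per <- unknowns |>
    dplyr::group_by(.data$sample, .data$assay) |>
    dplyr::summarise(
      mean_q = mean(.data$quantity),
      se_q = if (dplyr::n() > 1) sd(.data$quantity) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "assay",
                       values_from = c("mean_q", "se_q", "n"))
  est <- vcn_from_qpcr(per$mean_q_target, per$mean_q_reference,
                       ploidy_factor = ploidy_factor,
                       target_u = per$se_q_target,
                       reference_u = per$se_q_reference)
  out <- tibble::tibble(
    sample = per$sample,
    vcn = est$vcn,
    standard_uncertainty = est$standard_uncertainty,
    n_replicates = pmin(per$n_target, per$n_reference)
  )
  curve_summary <- dplyr::bind_rows(lapply(curves, glance.standard_curve),
                                    .id = "assay")
  curve_summary$efficiency_ok <- efficiency_in_range(
    curve_summary$efficiency, efficiency_range[1], efficiency_range[2])
  attr(out, "curves") <- curve_summary
  out
}
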