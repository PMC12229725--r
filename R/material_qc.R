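# Homogeneity and stability assessment of a candidate reference material.
#
# Homogeneity: VCN is measured on sample sets drawn across the dispensing
# order; the DerSimonian-Laird dark uncertainty across sets estimates the
# set-to-set (between-vial) standard deviation. A separate weighted trend
# test checks the negative-partition proportion against dispensing order.
# Stability: VCN at increasing storage times is compared to baseline within
# expanded uncertainty (coverage factor k) and through a weighted slope test.

apply_exclusions <- function(wells, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(wells)
  check_columns(exclusions, c("set_id", "reason"), "exclusion list")
  if (any(is.na(exclusions$reason) | !nzchar(exclusions$reason))) {
    stop_vcnref("every exclusion must carry a nonempty reason",
                "vcnref_schema_error")
  }
  if ("well_id" %in% names(exclusions) && any(!is.na(exclusions$well_id))) {
    by_well <- exclusions[!is.na(exclusions$well_id), ]
    wells <- dplyr::anti_join(wells, by_well[c("set_id", "well_id")],
                              by = c("set_id", "well_id"))
    exclusions <- exclusions[is.na(exclusions$well_id), ]
  }
  dplyr::anti_join(wells, exclusions["set_id"], by = "set_id")
}

#' Homogeneity assessment across dispensed sample sets
#'
#' Quantifies a VCN per set (merging replicate wells' partitions), then pools
#' sets with the DerSimonian-Laird procedure. The dark uncertainty of that
#' pooling is the set-to-set standard deviation; `relative_set_sd` expresses
#' it as a fraction of the consensus VCN (absolute when the consensus is 0,
#' as for a vector-free component where every set measures exactly 0).
#'
#' @param wells Well table (see [dpcr_quantify()]) carrying a `set_id`
#'   column.
#' @param exclusions Optional data frame (`set_id`, optional `well_id`,
#'   `reason`) of notebook-documented exclusions, e.g. known dispensing
#'   errors; excluded records never enter any statistic.
#' @param min_sets Minimum usable sets (default 3).
#' @param ploidy_factor Passed to [dpcr_vcn()].
#' @return A list of class `homogeneity_result`: `per_set` (tibble of
#'   per-set VCNs), `set_effect` (a `dl_consensus`), `relative_set_sd`.
#' @examples
#' w <- gen_homogeneity_wells(vcn = 4, n_sets = 8, seed = 3)
#' h <- homogeneity_assessment(w)
#' h$relative_set_sd
#' @export
homogeneity_assessment <- function(wells, exclusions = NULL, min_sets = 3,
                                   ploidy_factor = 2) {
  check_columns(wells, c("set_id", "channel", "n_total", "n_negative"),
                "wells table")
  wells <- apply_exclusions(wells, exclusions)
  n_sets <- length(unique(wells$set_id))
  if (n_sets < min_sets) {
    stop_vcnref(paste0("only ", n_sets, " usable sets; need at least ",
                       min_sets), "vcnref_insufficient_data")
  }
  per_set <- dpcr_vcn(wells, method = "merge_partitions",
                      ploidy_factor = ploidy_factor)
  all_zero <- all(per_set$vcn == 0)
  fit <- dersimonian_laird(
    tibble::tibble(lab_id = as.character(per_set$set_id),
                   estimate = per_set$vcn,
                   standard_uncertainty = if (all_zero) 0 else
                     per_set$standard_uncertainty)
  )
  rel <- if (fit$estimate == 0) fit$dark_uncertainty else
    relative_dark_uncertainty(fit)
  structure(
    list(per_set = per_set, set_effect = fit, relative_set_sd = rel),
    class = "homogeneity_result"
  )
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat("Homogeneity assessment over", nrow(x$per_set), "sets\n")
  cat(sprintf("  consensus VCN %.4g, set-to-set SD (tau) %.3g (%.2f%% of VCN)\n",
              x$set_effect$estimate, x$set_effect$dark_uncertainty,
              100 * x$relative_set_sd))
  invisible(x)
}

#' Trend of the negative-partition proportion with dispensing order
#'
#' Pools each set's wells for one channel, computes the negative-partition
#' proportion, and regresses it on dispensing order by weighted least
#' squares (weights are reciprocal binomial variances). A significant slope
#' indicates a fill-order trend in the material.
#'
#' @param wells Well table with `set_id`, `channel`, counts.
#' @param sets Data frame mapping `set_id` to `dispense_order`; if omitted,
#'   `set_id` itself must be numeric and is used as the order.
#' @param channel `"reference"` (default) or `"target"`.
#' @param exclusions As in [homogeneity_assessment()].
#' @return A one-row tibble: `slope`, `std_error`, `p_value` (two-sided),
#'   `n_sets`, `channel`.
#' @export
dispense_trend_test <- function(wells, sets = NULL,
                                channel = c("reference", "target"),
                                exclusions = NULL) {
  channel <- match.arg(channel)
  check_columns(wells, c("set_id", "channel", "n_total", "n_negative"),
                "wells table")
  wells <- apply_exclusions(wells, exclusions)
  d <- wells |>
    dplyr::filter(.data$channel == !!channel) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(n = sum(.data$n_total), x = sum(.data$n_negative),
                     .groups = "drop")
  if (!is.null(sets)) {
    check_columns(sets, c("set_id", "dispense_order"), "sets table")
    d <- dplyr::inner_join(d, sets, by = "set_id")
  } else {
    d$dispense_order <- suppressWarnings(as.numeric(d$set_id))
    if (anyNA(d$dispense_order)) {
      stop_vcnref("supply a sets table when set_id is not numeric",
                  "vcnref_schema_error")
    }
  }
  if (nrow(d) < 3) {
    stop_vcnref("need at least 3 usable sets for the trend test",
                "vcnref_insufficient_data")
  }
  d$prop <- d$x / d$n
  if (sd(d$prop) == 0) {
    return(tibble::tibble(slope = 0, std_error = 0, p_value = 1,
                          n_sets = nrow(d), channel = channel))
  }
  # shrink extreme proportions off the boundary for the variance weights only
  pt <- (d$x + 0.5) / (d$n + 1)
  d$w <- d$n / (pt * (1 - pt))
  fit <- lm(prop ~ dispense_order, data = d, weights = w)
  # an exactly linear series triggers the perfect-fit note; the zero p is valid
  s <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(slope = unname(s["dispense_order", "Estimate"]),
                 std_error = unname(s["dispense_order", "Std. Error"]),
                 p_value = unname(s["dispense_order", "Pr(>|t|)"]),
                 n_sets = nrow(d), channel = channel)
}

#' Stability assessment of VCN over storage time
#'
#' A component is called stable when (a) every time point's VCN lies within
#' `k` times the combined standard uncertainty of the baseline value
#' (inclusive; `k = 2` approximates 95 % coverage) and (b) the 95 %
#' confidence interval of the weighted least-squares slope of VCN on day
#' contains zero. Both diagnostics are reported regardless of the verdict.
#'
#' @param timeseries Data frame with columns `day` (>= 0, nondecreasing in
#'   meaning, any order accepted), `vcn`, `standard_uncertainty`.
#' @param k Coverage factor (default 2).
#' @return A list of class `stability_result`: `stable`, `max_abs_shift`,
#'   `slope_per_day`, `slope_ci`, `points` (per-point diagnostics).
#' @examples
#' ts <- tibble::tibble(day = c(0, 400, 810), vcn = c(4.01, 3.99, 4.02),
#'                      standard_uncertainty = 0.05)
#' stability_assessment(ts)
#' @export
stability_assessment <- function(timeseries, k = 2) {
  check_columns(timeseries, c("day", "vcn", "standard_uncertainty"),
                "time series")
  ts <- dplyr::arrange(tibble::as_tibble(timeseries), .data$day)
  if (nrow(ts) < 3) {
    stop_vcnref("need at least 3 time points", "vcnref_insufficient_data")
  }
  if (any(ts$day < 0)) {
    stop_vcnref("days must be nonnegative", "vcnref_schema_error")
  }
  base <- ts[ts$day == min(ts$day), ]
  if (all(base$standard_uncertainty > 0)) {
    wb <- 1 / base$standard_uncertainty^2
    baseline <- sum(wb * base$vcn) / sum(wb)
    u_base <- 1 / sqrt(sum(wb))
  } else {
    baseline <- mean(base$vcn)
    u_base <- 0
  }
  ts$shift <- abs(ts$vcn - baseline)
  ts$allowed <- k * sqrt(ts$standard_uncertainty^2 + u_base^2)
  ts$within <- ts$shift <= ts$allowed

  if (all(ts$standard_uncertainty > 0)) {
    fit <- lm(vcn ~ day, data = ts, weights = 1 / standard_uncertainty^2)
  } else {
    fit <- lm(vcn ~ day, data = ts)
  }
  ci <- suppressWarnings(confint(fit, "day", level = 0.95))
  slope <- unname(coef(fit)["day"])
  slope_ok <- ci[1] <= 0 && 0 <= ci[2]
  structure(
    list(
      stable = all(ts$within) && slope_ok,
      max_abs_shift = max(ts$shift),
      slope_per_day = slope,
      slope_ci = c(lo = ci[1], hi = ci[2]),
      k = k,
      points = ts
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability over", nrow(x$points), "time points (",
      max(x$points$day), "days )\n")
  cat(sprintf("  stable: %s; max |shift| %.3g; slope %.2e/day, 95%% CI [%.2e, %.2e]\n",
              x$stable, x$max_abs_shift, x$slope_per_day,
              x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Negative-droplet proportion by dispensing order
#'
#' Diagnostic plot for homogeneity: per-set negative-partition proportions
#' against dispensing order, by channel.
#'
#' @param wells Well table with `set_id`, `channel`, counts.
#' @param sets Optional `set_id` to `dispense_order` map.
#' @return A ggplot object.
#' @export
plot_negative_fraction <- function(wells, sets = NULL) {
  d <- wells |>
    dplyr::group_by(.data$set_id, .data$channel) |>
    dplyr::summarise(prop = sum(.data$n_negative) / sum(.data$n_total),
                     .groups = "drop")
  if (!is.null(sets)) {
    d <- dplyr::inner_join(d, sets, by = "set_id")
  } else {
    d$dispense_order <- suppressWarnings(as.numeric(d$set_id))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dispense_order, y = .data$prop,
                                  colour = .data$channel)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "dispensing order", y = "proportion of negative partitions",
                  title = "Homogeneity across dispensed sets")
}
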