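# Digital PCR quantification under the Poisson occupancy model.
#
# Each dPCR well partitions a reaction into n_total droplets/chambers of
# volume Vd. Target molecules distribute over partitions approximately as a
# Poisson process, so the fraction of negative partitions p estimates
# exp(-lambda), where lambda is the mean copies per partition. Inverting,
# lambda = -ln(p), concentration in the reaction = lambda / Vd, and in the
# original sample = Df * lambda / Vd for dilution factor Df.

#' Poisson occupancy from partition counts
#'
#' Converts a well's negative-partition fraction into the mean copies per
#' partition, \eqn{\lambda = -\ln(n_{neg}/n_{tot})}, with a delta-method
#' standard error from the binomial variance of the negative fraction:
#' \eqn{se(\lambda) = \sqrt{(1-p)/(n_{tot}\,p)}} with \eqn{p = n_{neg}/n_{tot}}.
#'
#' Wells with no negative partitions are saturated: the Poisson inversion is
#' undefined (the true concentration exceeds the dynamic range), so they are
#' a hard error rather than an infinite estimate. All-negative wells return
#' \eqn{\lambda = 0} exactly.
#'
#' @param n_total Integer vector, total partitions per well (> 0).
#' @param n_negative Integer vector, negative partitions per well
#'   (0 < n_negative allowed up to n_total; 0 is a saturation error).
#' @param well_id Optional character vector used to name offending wells in
#'   error messages.
#' @return A tibble with columns `lambda`, `se_lambda`, `p_negative`.
#' @examples
#' poisson_lambda(20000, 10000)  # lambda = ln 2
#' @export
poisson_lambda <- function(n_total, n_negative, well_id = NULL) {
  n_total <- as.numeric(n_total)
  n_negative <- as.numeric(n_negative)
  k <- max(length(n_total), length(n_negative))
  n_total <- rep_len(n_total, k)
  n_negative <- rep_len(n_negative, k)
  ids <- if (is.null(well_id)) paste0("well ", seq_len(k)) else rep_len(as.character(well_id), k)

  bad <- !is.finite(n_total) | n_total <= 0 | !is.finite(n_negative) |
    n_negative < 0 | n_negative > n_total
  if (any(bad)) {
    stop_vcnref(
      paste0("invalid partition counts for ", paste(ids[bad], collapse = ", "),
             " (need 0 <= n_negative <= n_total and n_total > 0)"),
      "vcnref_invalid_counts"
    )
  }
  sat <- n_negative == 0
  if (any(sat)) {
    stop_vcnref(
      paste0("saturated well(s) with no negative partitions: ",
             paste(ids[sat], collapse = ", "),
             "; concentration exceeds the dPCR dynamic range"),
      "vcnref_saturation_error"
    )
  }
  p <- n_negative / n_total
  tibble::tibble(
    lambda = -log(p),
    se_lambda = sqrt((1 - p) / (n_total * p)),
    p_negative = p
  )
}

#' Quantify dPCR wells as copy concentrations
#'
#' Applies the Poisson inversion well-by-well and scales the occupancy
#' \eqn{\lambda} to a copy concentration: `scope = "reaction"` gives
#' \eqn{\lambda / V_d} (copies/uL in the reaction), `scope = "sample"` gives
#' \eqn{D_f \lambda / V_d} (copies/uL in the undiluted sample). The
#' delta-method uncertainty scales by the same factor.
#'
#' @param wells A data frame with one row per well-channel, columns
#'   `n_total`, `n_negative`, `partition_volume_ul`, `dilution_factor`
#'   (and typically `well_id`, `sample`, `lab`, `channel`, which are carried
#'   through).
#' @param scope `"sample"` (default) or `"reaction"`.
#' @param min_partitions Wells below this total partition count are kept but
#'   flagged with a warning (default 10000).
#' @return The input tibble with appended columns `lambda`, `se_lambda`,
#'   `p_negative`, `value`, `standard_uncertainty`, `scope`.
#' @examples
#' w <- tibble::tibble(well_id = "A01", channel = "target",
#'                     n_total = 20000, n_negative = 10000,
#'                     partition_volume_ul = 0.00085, dilution_factor = 1)
#' dpcr_quantify(w, scope = "reaction")
#' @export
dpcr_quantify <- function(wells, scope = c("sample", "reaction"),
                          min_partitions = 10000) {
  scope <- match.arg(scope)
  check_columns(wells, c("n_total", "n_negative", "partition_volume_ul"),
                "wells table")
  wells <- tibble::as_tibble(wells)
  if (!"dilution_factor" %in% names(wells)) wells$dilution_factor <- 1
  if (any(wells$partition_volume_ul <= 0)) {
    stop_vcnref("partition_volume_ul must be positive", "vcnref_invalid_volume")
  }
  if (any(wells$dilution_factor < 1)) {
    stop_vcnref("dilution_factor must be >= 1", "vcnref_invalid_dilution")
  }
  low <- wells$n_total < min_partitions
  if (any(low)) {
    warn(paste0(sum(low), " well(s) below the minimum partition count of ",
                min_partitions))
  }
  ids <- if ("well_id" %in% names(wells)) wells$well_id else NULL
  occ <- poisson_lambda(wells$n_total, wells$n_negative, well_id = ids)
  factor <- if (scope == "sample") wells$dilution_factor else 1
  dplyr::bind_cols(
    wells,
    occ,
    tibble::tibble(
      value = factor * occ$lambda / wells$partition_volume_ul,
      standard_uncertainty = factor * occ$se_lambda / wells$partition_volume_ul,
      scope = scope
    )
  )
}

#' Rescale copy concentrations to a different partition volume
#'
#' Laboratories report concentrations under their own partition volume; for
#' cross-lab comparison all results are converted to a common default volume.
#' The occupancy \eqn{\lambda} is the invariant: a concentration computed with
#' volume `from_vd` becomes `value * from_vd / to_vd` at volume `to_vd`, and
#' the standard uncertainty scales identically.
#'
#' @param x A quantified tibble (from [dpcr_quantify()]) with columns `value`,
#'   `standard_uncertainty` and `partition_volume_ul`.
#' @param to_vd Target partition volume in uL (> 0).
#' @param from_vd Optional source volume; defaults to `x$partition_volume_ul`.
#' @return `x` with `value`, `standard_uncertainty` rescaled and
#'   `partition_volume_ul` set to `to_vd`.
#' @export
convert_partition_volume <- function(x, to_vd, from_vd = NULL) {
  check_columns(x, c("value", "standard_uncertainty"), "concentration table")
  if (is.null(from_vd)) {
    check_columns(x, "partition_volume_ul", "concentration table")
    from_vd <- x$partition_volume_ul
  }
  if (any(to_vd <= 0) || any(from_vd <= 0)) {
    stop_vcnref("partition volumes must be positive", "vcnref_invalid_volume")
  }
  f <- from_vd / to_vd
  x$value <- x$value * f
  x$standard_uncertainty <- x$standard_uncertainty * f
  x$partition_volume_ul <- to_vd
  x
}

#' Vector copy number from a duplex target/reference pair
#'
#' VCN is the copy ratio of the vector target to a single-copy-per-haploid
#' host reference gene, multiplied by the ploidy factor (2 for a diploid
#' genome): \eqn{VCN = 2\, c_{target}/c_{reference}}. Uncertainty follows the
#' ratio delta method,
#' \eqn{u = VCN \sqrt{(u_t/c_t)^2 + (u_r/c_r)^2}}. Because both channels share
#' any partition-volume rescaling, VCN is invariant to the partition volume.
#'
#' @param target,reference One-row data frames (or equal-length tibbles,
#'   paired row-wise) with columns `value` and `standard_uncertainty`; if a
#'   `scope` column is present on both it must agree.
#' @param ploidy_factor Copies of the reference locus per cell (default 2).
#' @return A tibble with columns `vcn`, `standard_uncertainty`,
#'   `ploidy_factor`.
#' @export
vcn_from_duplex <- function(target, reference, ploidy_factor = 2) {
  check_columns(target, c("value", "standard_uncertainty"), "target")
  check_columns(reference, c("value", "standard_uncertainty"), "reference")
  if (nrow(target) != nrow(reference)) {
    stop_vcnref("target and reference must pair row-wise", "vcnref_contract_error")
  }
  if ("scope" %in% names(target) && "scope" %in% names(reference) &&
      any(target$scope != reference$scope)) {
    stop_vcnref("target and reference quantified at different scopes",
                "vcnref_contract_error")
  }
  if ("partition_volume_ul" %in% names(target) &&
      "partition_volume_ul" %in% names(reference) &&
      any(abs(target$partition_volume_ul - reference$partition_volume_ul) >
            1e-12 * reference$partition_volume_ul)) {
    stop_vcnref("target and reference quantified at different partition volumes",
                "vcnref_contract_error")
  }
  if (any(reference$value <= 0)) {
    stop_vcnref("reference concentration must be positive for a VCN ratio",
                "vcnref_no_reference")
  }
  if (ploidy_factor <= 0) {
    stop_vcnref("ploidy_factor must be positive", "vcnref_contract_error")
  }
  ratio <- target$value / reference$value
  vcn <- ploidy_factor * ratio
  rel_t <- ifelse(target$value > 0, target$standard_uncertainty / target$value, 0)
  rel_r <- reference$standard_uncertainty / reference$value
  u <- ifelse(
    target$value > 0,
    vcn * sqrt(rel_t^2 + rel_r^2),
    # zero-target wells: uncertainty from the target channel alone, scaled
    ploidy_factor * target$standard_uncertainty / reference$value
  )
  tibble::tibble(vcn = vcn, standard_uncertainty = u,
                 ploidy_factor = ploidy_factor)
}

#' Pool replicate wells
#'
#' `merge_partitions` (default) sums `n_total` and `n_negative` per channel
#' (within any grouping columns present among `sample`, `lab`, `set_id`) and
#' returns one pooled well per channel, to be quantified once; this maximizes
#' the partition count behind a single Poisson inversion. Merging requires a
#' common partition volume and dilution factor within each pooled group.
#'
#' @param wells Well table as for [dpcr_quantify()] (raw counts).
#' @param method Only `"merge_partitions"` operates on raw counts; well-level
#'   averaging of VCN estimates is provided by [dpcr_vcn()].
#' @return A pooled wells tibble (one row per group x channel,
#'   `well_id = "pooled"`).
#' @export
pool_replicates <- function(wells, method = "merge_partitions") {
  method <- match.arg(method, "merge_partitions")
  check_columns(wells, c("channel", "n_total", "n_negative",
                         "partition_volume_ul"), "wells table")
  if (nrow(wells) == 0) {
    stop_vcnref("no wells to pool", "vcnref_empty_input")
  }
  if (!"dilution_factor" %in% names(wells)) wells$dilution_factor <- 1
  grp <- intersect(c("sample", "lab", "set_id"), names(wells))
  out <- wells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "channel")))) |>
    dplyr::summarise(
      well_id = "pooled",
      n_wells = dplyr::n(),
      n_total = sum(.data$n_total),
      n_negative = sum(.data$n_negative),
      vd_spread = diff(range(.data$partition_volume_ul)),
      df_spread = diff(range(.data$dilution_factor)),
      partition_volume_ul = .data$partition_volume_ul[1],
      dilution_factor = .data$dilution_factor[1],
      .groups = "drop"
    )
  if (any(out$vd_spread > 0) || any(out$df_spread > 0)) {
    stop_vcnref(
      "cannot merge partitions across differing partition volumes or dilution factors",
      "vcnref_contract_error"
    )
  }
  dplyr::select(out, -"vd_spread", -"df_spread")
}

#' dPCR wells to VCN estimates, end to end
#'
#' The standard duplex pipeline: pool replicate wells per group (sample x lab
#' by default), invert the Poisson occupancy per channel, and form the VCN
#' ratio. With `method = "average_wells"` each well pair is quantified
#' separately and per-group VCNs are the mean across wells with standard
#' error \eqn{sd/\sqrt{k}} (flagged `NA` for a single well).
#'
#' @param wells Well table with a `channel` column coded `"target"` /
#'   `"reference"`, paired by `well_id` within each group.
#' @param method `"merge_partitions"` (default) or `"average_wells"`.
#' @param scope Concentration scope passed to [dpcr_quantify()].
#' @param ploidy_factor Passed to [vcn_from_duplex()].
#' @param min_partitions Passed to [dpcr_quantify()].
#' @return A tibble with one row per group: grouping columns, `vcn`,
#'   `standard_uncertainty`, `n_wells`, `method`.
#' @examples
#' w <- gen_partition_wells(c_target = 1000, c_ref = 500, n_wells = 3, seed = 1)
#' dpcr_vcn(w)
#' @export
dpcr_vcn <- function(wells, method = c("merge_partitions", "average_wells"),
                     scope = c("sample", "reaction"), ploidy_factor = 2,
                     min_partitions = 10000) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  check_columns(wells, c("channel", "n_total", "n_negative"), "wells table")
  if (!all(wells$channel %in% c("target", "reference"))) {
    stop_vcnref("channel must be 'target' or 'reference'", "vcnref_schema_error")
  }
  grp <- intersect(c("sample", "lab", "set_id"), names(wells))

  if (method == "merge_partitions") {
    pooled <- pool_replicates(wells)
    q <- dpcr_quantify(pooled, scope = scope, min_partitions = 0)
    wide <- q |>
      dplyr::select(dplyr::all_of(grp), "channel", "n_wells", "value",
                    "standard_uncertainty", "scope", "partition_volume_ul") |>
      tidyr::pivot_wider(names_from = "channel",
                         values_from = c("value", "standard_uncertainty"))
    est <- vcn_from_duplex(
      tibble::tibble(value = wide$value_target,
                     standard_uncertainty = wide$standard_uncertainty_target),
      tibble::tibble(value = wide$value_reference,
                     standard_uncertainty = wide$standard_uncertainty_reference),
      ploidy_factor = ploidy_factor
    )
    out <- dplyr::bind_cols(
      dplyr::select(wide, dplyr::all_of(grp), "n_wells"),
      est[c("vcn", "standard_uncertainty")]
    )
  } else {
    q <- dpcr_quantify(wells, scope = scope, min_partitions = min_partitions)
    wide <- q |>
      dplyr::select(dplyr::all_of(grp), "well_id", "channel", "value",
                    "standard_uncertainty") |>
      tidyr::pivot_wider(names_from = "channel",
                         values_from = c("value", "standard_uncertainty"))
    per_well <- vcn_from_duplex(
      tibble::tibble(value = wide$value_target,
                     standard_uncertainty = wide$standard_uncertainty_target),
      tibble::tibble(value = wide$value_reference,
                     standard_uncertainty = wide$standard_uncertainty_reference),
      ploidy_factor = ploidy_factor
    )
    wide$vcn <- per_well$vcn
    out <- wide |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        n_wells = dplyr::n(),
        standard_uncertainty = if (dplyr::n() > 1)
          stats::sd(.data$vcn) / sqrt(dplyr::n()) else NA_real_,
        vcn = mean(.data$vcn),
        .groups = "drop"
      ) |>
      dplyr::relocate("vcn", .before = "standard_uncertainty")
    if (any(is.na(out$standard_uncertainty))) {
      warn("single-well groups have no between-well SE under average_wells")
    }
  }
  out$method <- method
  out
}
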