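#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats dnorm lm coef confint quantile rnorm rbinom sd median mad
#'   setNames qnorm pnorm shapiro.test var residuals
#' @importFrom utils head
NULL

# Evaluate `expr` under `seed` (restoring RNG state afterwards), or as-is when
# seed is NULL. All package randomness funnels through here.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

stop_vcnref <- function(msg, class) {
  abort(msg, class = c(class, "vcnref_error"))
}

# check that a data frame has the named columns, with a caller-facing message
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_vcnref(
      paste0(what, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      "vcnref_schema_error"
    )
  }
  invisible(df)
}

#' Default dPCR partition volumes by platform
#'
#' Instrument-default partition (droplet or chamber) volumes in microlitres:
#' 0.00085 uL (0.85 nL) for Bio-Rad droplet instruments and 0.00034 uL
#' (0.34 nL) for the QIAcuity chamber-based platform. Individual laboratories
#' may calibrate their own volume (e.g. 0.0007691 or 0.000749 uL); these
#' defaults are used only when a well record carries a `platform` field but no
#' explicit `partition_volume_ul`.
#'
#' @param platform Character vector of platform names (`"bio-rad"` or
#'   `"qiacuity"`, case-insensitive).
#' @return Numeric vector of partition volumes in uL.
#' @examples
#' default_partition_volume(c("bio-rad", "qiacuity"))
#' @export
default_partition_volume <- function(platform) {
  vols <- c("bio-rad" = 0.00085, "biorad" = 0.00085, "qiacuity" = 0.00034)
  key <- tolower(gsub("[ _]", "-", platform))
  out <- unname(vols[key])
  if (anyNA(out)) {
    stop_vcnref(
      paste0("unknown platform(s): ",
             paste(unique(platform[is.na(out)]), collapse = ", ")),
      "vcnref_platform_error"
    )
  }
  out
}
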