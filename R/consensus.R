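# DerSimonian-Laird random-effects consensus.
#
# Each laboratory i reports an estimate x_i with standard uncertainty u_i.
# The model is x_i = mu + b_i + e_i with lab effects b_i ~ N(0, tau^2) and
# measurement noise e_i ~ N(0, u_i^2). The method-of-moments (DL) estimate of
# tau^2 compares Cochran's Q to its expectation under homogeneity; tau is the
# "dark uncertainty" - between-lab variability beyond what the stated
# within-lab uncertainties explain.

# Core moment computation on vectors; no validation.
dl_core <- function(x, u) {
  n <- length(x)
  w <- 1 / u^2
  xbar <- sum(w * x) / sum(w)
  q <- sum(w * (x - xbar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (n - 1)) / cc)
  ws <- 1 / (u^2 + tau2)
  est <- sum(ws * x) / sum(ws)
  list(estimate = est, standard_uncertainty = 1 / sqrt(sum(ws)),
       tau = sqrt(tau2), tau2 = tau2, q = q, weights = ws / sum(ws), n = n)
}

# Vectorized DL over columns of a draws matrix (fixed u); used by the
# parametric bootstrap so refits stay cheap.
dl_core_mat <- function(X, u) {
  n <- nrow(X)
  w <- 1 / u^2
  sw <- sum(w)
  xbar <- colSums(w * X) / sw
  q <- colSums(w * (X - rep(xbar, each = n))^2)
  cc <- sw - sum(w^2) / sw
  tau2 <- pmax(0, (q - (n - 1)) / cc)
  WS <- 1 / outer(u^2, tau2, `+`)
  colSums(WS * X) / colSums(WS)
}

#' DerSimonian-Laird consensus of laboratory results
#'
#' Pools per-laboratory (estimate, standard uncertainty) pairs into a
#' consensus value. With fixed-effects weights \eqn{w_i = u_i^{-2}} and
#' weighted mean \eqn{\bar x}, Cochran's \eqn{Q = \sum w_i (x_i - \bar x)^2}
#' and the moment estimate
#' \eqn{\tau^2 = \max\{0, (Q - (n-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}}.
#' Final weights are \eqn{w_i^* = 1/(u_i^2 + \tau^2)}; the consensus is the
#' \eqn{w^*}-weighted mean with standard uncertainty
#' \eqn{(\sum w_i^*)^{-1/2}}. \eqn{\tau} is reported as the dark uncertainty.
#' The default 95 % interval is the normal approximation
#' \eqn{\hat x \pm 1.96\, u(\hat x)}; `ci = "bootstrap"` substitutes a
#' parametric-bootstrap percentile interval (see [bootstrap_ci()]).
#'
#' A degenerate input in which every uncertainty is zero and all estimates
#' are equal (the all-zero component of a panel, where no variability is
#' observed at all) returns that common value with zero uncertainty and
#' \eqn{\tau = 0}.
#'
#' @param data Data frame with columns `estimate` and `standard_uncertainty`
#'   (and optionally `lab_id`, carried into [tidy()]).
#' @param ci `"normal"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap controls when `ci = "bootstrap"`.
#' @return An object of class `dl_consensus`.
#' @examples
#' labs <- gen_lab_results(mu = 4, tau = 0.08,
#'                         u = c(0.03, 0.05, 0.02, 0.04, 0.06, 0.03, 0.05),
#'                         seed = 11)
#' fit <- dersimonian_laird(labs)
#' glance(fit)
#' @export
dersimonian_laird <- function(data, ci = c("normal", "bootstrap"),
                              n_boot = 5000, seed = NULL) {
  ci <- match.arg(ci)
  check_columns(data, c("estimate", "standard_uncertainty"), "lab results")
  x <- data$estimate
  u <- data$standard_uncertainty
  if (length(x) < 2) {
    stop_vcnref("need at least 2 laboratory results", "vcnref_insufficient_data")
  }
  if (any(!is.finite(x)) || any(!is.finite(u)) || any(u < 0)) {
    stop_vcnref("estimates must be finite and uncertainties nonnegative",
                "vcnref_schema_error")
  }
  if (any(u == 0)) {
    if (all(u == 0) && length(unique(x)) == 1) {
      res <- list(estimate = x[1], standard_uncertainty = 0, tau = 0,
                  tau2 = 0, q = 0, weights = rep(1 / length(x), length(x)),
                  n = length(x))
    } else {
      stop_vcnref(
        "zero standard uncertainties with unequal estimates give degenerate weights",
        "vcnref_degenerate_weights"
      )
    }
  } else {
    res <- dl_core(x, u)
  }
  obj <- structure(
    list(
      estimate = res$estimate,
      standard_uncertainty = res$standard_uncertainty,
      dark_uncertainty = res$tau,
      tau2 = res$tau2,
      q_statistic = res$q,
      n_labs = res$n,
      weights = res$weights,
      ci_method = ci,
      data = tibble::tibble(
        lab_id = if ("lab_id" %in% names(data)) data$lab_id
                 else paste0("lab", seq_along(x)),
        estimate = x, standard_uncertainty = u
      )
    ),
    class = "dl_consensus"
  )
  if (ci == "normal") {
    half <- 1.96 * obj$standard_uncertainty
    obj$ci95_lo <- obj$estimate - half
    obj$ci95_hi <- obj$estimate + half
  } else {
    bci <- bootstrap_ci(obj, n_boot = n_boot, seed = seed)
    obj$ci95_lo <- bci[[1]]
    obj$ci95_hi <- bci[[2]]
  }
  obj
}

#' @export
print.dl_consensus <- function(x, ...) {
  cat("DerSimonian-Laird consensus of", x$n_labs, "results\n")
  cat(sprintf("  estimate %.4g, standard uncertainty %.3g\n",
              x$estimate, x$standard_uncertainty))
  cat(sprintf("  95%% CI (%s) [%.4g, %.4g]\n", x$ci_method, x$ci95_lo, x$ci95_hi))
  cat(sprintf("  dark uncertainty tau = %.3g (Q = %.3g)\n",
              x$dark_uncertainty, x$q_statistic))
  invisible(x)
}

#' @rdname dersimonian_laird
#' @param x A `dl_consensus` object.
#' @param ... Unused.
#' @export
tidy.dl_consensus <- function(x, ...) {
  dplyr::mutate(x$data, weight = x$weights,
                deviation = .data$estimate - x$estimate)
}

#' @rdname dersimonian_laird
#' @export
glance.dl_consensus <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    standard_uncertainty = x$standard_uncertainty,
    ci95_lo = x$ci95_lo, ci95_hi = x$ci95_hi,
    dark_uncertainty = x$dark_uncertainty,
    q_statistic = x$q_statistic,
    n_labs = x$n_labs,
    ci_method = x$ci_method
  )
}

#' Dark uncertainty relative to the consensus value
#'
#' \eqn{\tau / |\hat x|}, the between-lab (or between-set) standard deviation
#' as a fraction of the consensus estimate. Undefined at a zero consensus
#' (report the absolute \eqn{\tau} instead in that case).
#'
#' @param cr A `dl_consensus` object.
#' @return A fraction.
#' @export
relative_dark_uncertainty <- function(cr) {
  stopifnot(inherits(cr, "dl_consensus"))
  if (cr$estimate == 0) {
    stop_vcnref(
      "relative dark uncertainty undefined at a zero consensus; report absolute tau",
      "vcnref_zero_estimate"
    )
  }
  cr$dark_uncertainty / abs(cr$estimate)
}

#' Parametric-bootstrap confidence interval for a DL consensus
#'
#' Resamples \eqn{x_i^* \sim N(\hat x, \sqrt{u_i^2 + \hat\tau^2})}, refits the
#' DL pooling for each draw, and returns the percentile 95 % interval.
#' Reproducible under a fixed seed.
#'
#' @param cr A `dl_consensus` object.
#' @param n_boot Number of bootstrap draws (>= 100).
#' @param seed Optional integer seed.
#' @param probs Percentiles (default `c(0.025, 0.975)`).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(cr, n_boot = 5000, seed = NULL,
                         probs = c(0.025, 0.975)) {
  stopifnot(inherits(cr, "dl_consensus"))
  if (n_boot < 100) {
    stop_vcnref("n_boot must be at least 100", "vcnref_insufficient_data")
  }
  u <- cr$data$standard_uncertainty
  n <- length(u)
  if (all(u == 0)) {
    return(c(lo = cr$estimate, hi = cr$estimate))
  }
  est <- with_seed_or_not(seed, {
    X <- cr$estimate + matrix(rnorm(n * n_boot), n, n_boot) *
      sqrt(u^2 + cr$tau2)
    dl_core_mat(X, u)
  })
  qs <- unname(quantile(est, probs))
  c(lo = qs[1], hi = qs[2])
}

#' @rdname dersimonian_laird
#' @param object A `dl_consensus` object (for `autoplot`).
#' @export
autoplot.dl_consensus <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$lab_id)) +
    ggplot2::annotate("rect", xmin = object$ci95_lo, xmax = object$ci95_hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$estimate,
                        colour = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$standard_uncertainty,
                   xmax = .data$estimate + 1.96 * .data$standard_uncertainty),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Laboratory results and consensus",
                  subtitle = sprintf("consensus %.3g ± %.2g, tau = %.2g",
                                     object$estimate,
                                     object$standard_uncertainty,
                                     object$dark_uncertainty))
}
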