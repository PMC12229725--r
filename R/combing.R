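# Molecular-combing probe-length classification.
#
# On fully stretched fibers the length of a hybridized probe is approximately
# Gaussian. An integrated provirus lengthens the spanned probe, so a
# population mixing wild-type and integration-bearing fibers is a
# two-component Gaussian mixture. Abundant variants (above ~5 % of signals)
# are separated by a two-component EM fit; rare variants (below ~2 %) are
# counted by the 3-sigma rule against the wild-type distribution.

#' Normality check of a probe-length population
#'
#' Shapiro-Wilk test on the signal lengths; advisory only (a low p-value
#' flags departure from the single-Gaussian assumption, it never blocks the
#' downstream classifiers). Constant lengths are degenerate and flagged. For
#' populations above the Shapiro-Wilk limit of 5000 a seeded subsample of
#' 5000 signals is tested.
#'
#' @param lengths Numeric vector of probe lengths (kb), at least 3.
#' @return A one-row tibble: `statistic`, `p_value`, `n`, `degenerate`.
#' @export
normality_check <- function(lengths) {
  if (length(lengths) < 3) {
    stop_vcnref("need at least 3 signals", "vcnref_insufficient_data")
  }
  if (sd(lengths) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n = length(lengths), degenerate = TRUE))
  }
  x <- if (length(lengths) > 5000) {
    with_seed_or_not(1L, sample(lengths, 5000))
  } else lengths
  sw <- shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value, n = length(lengths),
                 degenerate = FALSE)
}

# Two-component univariate Gaussian EM with deterministic initialization at
# the 25th/75th length percentiles. Returns raw component parameters.
em_two_gaussian <- function(x, max_iter = 500, tol = 1e-10) {
  n <- length(x)
  mu <- unname(quantile(x, c(0.25, 0.75)))
  s0 <- max(sd(x) / 2, 1e-8)
  sigma <- c(s0, s0)
  pi1 <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  floor_sd <- max(sd(x), 1e-8) * 1e-6
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sigma[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    pi1 <- mean(g)
    # guard against component collapse
    pi1 <- min(max(pi1, 1e-10), 1 - 1e-10)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sigma[1] <- max(sqrt(sum(g * (x - mu[1])^2) / sum(g)), floor_sd)
    sigma[2] <- max(sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)), floor_sd)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  d1 <- pi1 * dnorm(x, mu[1], sigma[1])
  d2 <- (1 - pi1) * dnorm(x, mu[2], sigma[2])
  list(mu = mu, sigma = sigma, pi1 = pi1, resp1 = d1 / pmax(d1 + d2, .Machine$double.xmin),
       loglik = sum(log(pmax(d1 + d2, .Machine$double.xmin))),
       converged = converged, n_iter = it)
}

#' Two-component Gaussian mixture classification of probe lengths
#'
#' Fits a two-component univariate Gaussian mixture by expectation-
#' maximization with deterministic initialization (component means at the
#' 25th and 75th length percentiles), so repeated runs are bit-identical.
#' Signals are assigned to the component with posterior probability >= 0.5.
#' With `direction = "longer"` (integration lengthens the spanned probe) the
#' larger-mean component is the alternative ("alt") class.
#'
#' @param lengths Numeric vector of probe lengths (kb).
#' @param seed Accepted for interface uniformity; the fit is deterministic
#'   and ignores it.
#' @param min_signals Floor on the population size (default 20).
#' @param direction `"longer"` (default) or `"shorter"`: which component is
#'   the integration class.
#' @param max_iter,tol EM controls.
#' @return An object of class `gmm_fit` with `mu_wt`, `sigma_wt`, `mu_alt`,
#'   `sigma_alt`, `pi_alt`, `assignments` (`"wt"`/`"alt"`), `converged`,
#'   `loglik`, `n_iter`.
#' @examples
#' x <- gen_probe_lengths(500, pi_alt = 0.5, mu_wt = 30, sigma_wt = 1.5,
#'                        mu_alt = 45, sigma_alt = 1.5, seed = 2)
#' fit <- classify_gmm(x$length_kb)
#' fit$pi_alt
#' @export
classify_gmm <- function(lengths, seed = NULL, min_signals = 20,
                         direction = c("longer", "shorter"),
                         max_iter = 500, tol = 1e-10) {
  direction <- match.arg(direction)
  if (length(lengths) < min_signals) {
    stop_vcnref(paste0("need at least ", min_signals, " signals for a GMM fit"),
                "vcnref_insufficient_data")
  }
  em <- em_two_gaussian(lengths, max_iter = max_iter, tol = tol)
  alt_is_2 <- if (direction == "longer") em$mu[2] >= em$mu[1] else
    em$mu[2] < em$mu[1]
  wt_i <- if (alt_is_2) 1 else 2
  alt_i <- if (alt_is_2) 2 else 1
  p_alt_each <- if (alt_is_2) 1 - em$resp1 else em$resp1
  structure(
    list(
      mu_wt = em$mu[wt_i], sigma_wt = em$sigma[wt_i],
      mu_alt = em$mu[alt_i], sigma_alt = em$sigma[alt_i],
      pi_alt = if (alt_is_2) 1 - em$pi1 else em$pi1,
      assignments = ifelse(p_alt_each >= 0.5, "alt", "wt"),
      posterior_alt = p_alt_each,
      converged = em$converged, loglik = em$loglik, n_iter = em$n_iter,
      lengths = lengths, direction = direction
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture of", length(x$lengths), "probe lengths\n")
  cat(sprintf("  wild-type: mu %.3f, sigma %.3f\n", x$mu_wt, x$sigma_wt))
  cat(sprintf("  alternative: mu %.3f, sigma %.3f, proportion %.4f\n",
              x$mu_alt, x$sigma_alt, x$pi_alt))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged, x$n_iter))
  invisible(x)
}

#' @rdname classify_gmm
#' @param x A `gmm_fit` object.
#' @param ... Unused.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(
    component = c("wt", "alt"),
    mean = c(x$mu_wt, x$mu_alt),
    sd = c(x$sigma_wt, x$sigma_alt),
    proportion = c(1 - x$pi_alt, x$pi_alt),
    n_assigned = c(sum(x$assignments == "wt"), sum(x$assignments == "alt"))
  )
}

#' @rdname classify_gmm
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(pi_alt = x$pi_alt, mu_wt = x$mu_wt, sigma_wt = x$sigma_wt,
                 mu_alt = x$mu_alt, sigma_alt = x$sigma_alt,
                 converged = x$converged, loglik = x$loglik,
                 n = length(x$lengths))
}

#' @rdname classify_gmm
#' @param object A `gmm_fit` object (for `autoplot`).
#' @export
autoplot.gmm_fit <- function(object, ...) {
  d <- tibble::tibble(length_kb = object$lengths,
                      class = object$assignments)
  grid <- seq(min(object$lengths), max(object$lengths), length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(length_kb = grid, class = "wt",
                   density = (1 - object$pi_alt) *
                     dnorm(grid, object$mu_wt, object$sigma_wt)),
    tibble::tibble(length_kb = grid, class = "alt",
                   density = object$pi_alt *
                     dnorm(grid, object$mu_alt, object$sigma_alt))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_kb)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density),
                                         fill = .data$class),
                            bins = 60, alpha = 0.5, position = "identity") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$class)) +
    ggplot2::labs(x = "probe length (kb)", y = "density",
                  title = "Probe-length mixture classification")
}

#' Rare-variant classification by the 3-sigma rule
#'
#' A signal endorses the alternative design when its length strays more than
#' three wild-type standard deviations from the wild-type mean (strict
#' inequality; a signal at exactly 3 sigma is not endorsed). Two-sided by
#' default; `sides = "one"` counts only lengthening beyond
#' \eqn{\mu + 3\sigma}. The integration frequency is the endorsed fraction.
#'
#' @param lengths Numeric vector of probe lengths (kb).
#' @param mu_wt,sigma_wt Wild-type distribution parameters, from a control
#'   coverslip or pooled historical values; `sigma_wt` must be positive.
#' @param sides `"two"` (default) or `"one"`.
#' @param n_sigma Threshold multiplier (default 3).
#' @return A one-row tibble: `frequency`, `n_alt`, `n_total`, `regime`,
#'   `sides`.
#' @export
classify_three_sigma <- function(lengths, mu_wt, sigma_wt,
                                 sides = c("two", "one"), n_sigma = 3) {
  sides <- match.arg(sides)
  if (sigma_wt <= 0) {
    stop_vcnref("sigma_wt must be positive", "vcnref_schema_error")
  }
  dev <- lengths - mu_wt
  endorsed <- if (sides == "two") abs(dev) > n_sigma * sigma_wt else
    dev > n_sigma * sigma_wt
  tibble::tibble(
    frequency = sum(endorsed) / length(lengths),
    n_alt = sum(endorsed), n_total = length(lengths),
    regime = "three_sigma", sides = sides
  )
}

#' Integration frequency with regime dispatch
#'
#' Chooses the classifier by the expected integration proportion: the GMM
#' regime above 5 %, the 3-sigma rule below 2 %. In the 2-5 % gap, or with
#' no hint, the GMM is fit first and the 3-sigma rule is used as a fallback
#' when the mixture is degenerate (component means closer than twice the
#' pooled within-component SD, or non-convergence). The decision path is
#' recorded in the result.
#'
#' @param lengths Numeric vector of probe lengths (kb).
#' @param regime_hint Expected alternative fraction, or `NULL`.
#' @param mu_wt,sigma_wt Wild-type parameters for the 3-sigma rule; when
#'   absent they are estimated robustly (median and MAD) from the data.
#' @param seed Passed to [classify_gmm()] (deterministic; kept for interface
#'   uniformity).
#' @param sides Passed to [classify_three_sigma()].
#' @return A one-row tibble: `frequency`, `n_alt`, `n_total`, `regime`,
#'   `path`.
#' @export
estimate_frequency <- function(lengths, regime_hint = NULL, mu_wt = NULL,
                               sigma_wt = NULL, seed = NULL,
                               sides = "two") {
  wt_params <- function() {
    if (is.null(mu_wt) || is.null(sigma_wt)) {
      list(mu = median(lengths), sigma = mad(lengths))
    } else {
      list(mu = mu_wt, sigma = sigma_wt)
    }
  }
  as_freq <- function(ts, regime, path) {
    tibble::tibble(frequency = ts$frequency, n_alt = ts$n_alt,
                   n_total = ts$n_total, regime = regime, path = path)
  }
  three_sigma_result <- function(path) {
    p <- wt_params()
    as_freq(classify_three_sigma(lengths, p$mu, p$sigma, sides = sides),
            "three_sigma", path)
  }
  gmm_result <- function(fit, path) {
    tibble::tibble(frequency = fit$pi_alt,
                   n_alt = sum(fit$assignments == "alt"),
                   n_total = length(lengths), regime = "gmm", path = path)
  }

  if (!is.null(regime_hint) && regime_hint > 0.05) {
    return(gmm_result(classify_gmm(lengths, seed = seed),
                      "hint > 5% -> gmm"))
  }
  if (!is.null(regime_hint) && regime_hint < 0.02) {
    return(three_sigma_result("hint < 2% -> three_sigma"))
  }
  path0 <- if (is.null(regime_hint)) "no hint" else "hint in 2-5% gap"
  fit <- classify_gmm(lengths, seed = seed)
  pooled <- sqrt((fit$sigma_wt^2 + fit$sigma_alt^2) / 2)
  degenerate <- !fit$converged ||
    abs(fit$mu_alt - fit$mu_wt) < 2 * pooled
  if (degenerate) {
    if (is.null(mu_wt) || is.null(sigma_wt)) {
      # dominant component stands in for the wild-type distribution
      dom_wt <- fit$pi_alt <= 0.5
      mu_wt <- if (dom_wt) fit$mu_wt else fit$mu_alt
      sigma_wt <- if (dom_wt) fit$sigma_wt else fit$sigma_alt
    }
    return(as_freq(classify_three_sigma(lengths, mu_wt, sigma_wt, sides = sides),
                   "three_sigma",
                   paste0(path0, " -> gmm degenerate -> three_sigma")))
  }
  gmm_result(fit, paste0(path0, " -> gmm"))
}

#' Descriptive report of combing signals per design
#'
#' Per-design counts, length moments, and the normality check - the summary
#' that accompanies a coverslip's classification results.
#'
#' @param signals Data frame with columns `design_id` and `length_kb`.
#' @return A tibble, one row per design.
#' @export
combing_report <- function(signals) {
  check_columns(signals, c("design_id", "length_kb"), "signals table")
  signals |>
    dplyr::group_by(.data$design_id) |>
    dplyr::summarise(
      n_signals = dplyr::n(),
      mean_kb = mean(.data$length_kb),
      sd_kb = sd(.data$length_kb),
      min_kb = min(.data$length_kb),
      max_kb = max(.data$length_kb),
      shapiro_p = if (dplyr::n() >= 3 && sd(.data$length_kb) > 0)
        normality_check(.data$length_kb)$p_value else NA_real_,
      .groups = "drop"
    )
}
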