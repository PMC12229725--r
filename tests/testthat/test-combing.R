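test_that("normality check passes Gaussian data and rejects bimodal data", {
  # calibration under the null over seeded runs
  pvals <- withr::with_seed(50, {
    vapply(1:100, function(i) normality_check(rnorm(500, 30, 1))$p_value,
           numeric(1))
  })
  expect_gte(mean(pvals > 0.01), 0.95)

  # strongly bimodal mixture is decisively non-Gaussian
  x <- gen_probe_lengths(500, pi_alt = 0.5, mu_wt = 30, sigma_wt = 1,
                         mu_alt = 40, sigma_alt = 1, seed = 51)
  expect_lt(normality_check(x$length_kb)$p_value, 0.01)

  deg <- normality_check(rep(30, 10))
  expect_true(deg$degenerate)
  expect_error(normality_check(c(1, 2)), class = "vcnref_insufficient_data")
  # above the Shapiro-Wilk n limit, a subsample is tested without error
  big <- withr::with_seed(52, rnorm(6000, 30, 1))
  expect_gt(normality_check(big)$p_value, 1e-6)
})

test_that("GMM classification recovers mixture proportions", {
  # balanced heterozygous-like mixture, 10-sigma separation
  x <- gen_probe_lengths(1000, pi_alt = 0.5, mu_wt = 30, sigma_wt = 1.5,
                         mu_alt = 45, sigma_alt = 1.5, seed = 60)
  fit <- classify_gmm(x$length_kb)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi_alt - 0.5), 0.05)
  expect_lt(abs(fit$mu_wt - 30), 0.5)
  expect_lt(abs(fit$mu_alt - 45), 0.5)
  # assignments agree with the generating class almost everywhere
  expect_gt(mean(fit$assignments == x$class), 0.99)

  # the 10 % regime boundary at 6-sigma separation
  y <- gen_probe_lengths(2000, pi_alt = 0.10, mu_wt = 30, sigma_wt = 1.5,
                         mu_alt = 39, sigma_alt = 1.5, seed = 61)
  fit2 <- classify_gmm(y$length_kb)
  expect_lt(abs(fit2$pi_alt - 0.10), 0.03)

  expect_error(classify_gmm(rnorm(10)), class = "vcnref_insufficient_data")
})

test_that("GMM fits are deterministic and match an independent EM", {
  x <- gen_probe_lengths(800, pi_alt = 0.3, mu_wt = 30, sigma_wt = 1.5,
                         mu_alt = 42, sigma_alt = 2, seed = 62)
  f1 <- classify_gmm(x$length_kb, seed = 1)
  f2 <- classify_gmm(x$length_kb, seed = 999)
  expect_identical(glance(f1), glance(f2))  # bit-reproducible, seed-free

  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  m <- mclust::Mclust(x$length_kb, G = 2, modelNames = "V", verbose = FALSE)
  mu_m <- sort(m$parameters$mean)
  expect_equal(sort(c(f1$mu_wt, f1$mu_alt)), unname(mu_m), tolerance = 0.02)
  pi_alt_m <- m$parameters$pro[which.max(m$parameters$mean)]
  expect_equal(f1$pi_alt, pi_alt_m, tolerance = 0.02)
})

test_that("mean recovery error stays within 0.05 across conditions", {
  conds <- expand.grid(pi_alt = c(0.5, 0.1), rep = 1:100)
  errs <- withr::with_seed(63, {
    mapply(function(pi_alt, rep) {
      x <- gen_probe_lengths(1000, pi_alt = pi_alt, mu_wt = 30,
                             sigma_wt = 1.5, mu_alt = 39, sigma_alt = 1.5)
      abs(classify_gmm(x$length_kb)$pi_alt - pi_alt)
    }, conds$pi_alt, conds$rep)
  })
  expect_lte(mean(errs), 0.05)
})

test_that("3-sigma rule calibrates on pure wild-type and finds spike-ins", {
  # two-sided false-endorsement rate ~ 2*pnorm(-3) = 0.0027
  rates <- withr::with_seed(70, {
    vapply(1:200, function(i) {
      classify_three_sigma(rnorm(10000, 30, 1), mu_wt = 30,
                           sigma_wt = 1)$frequency
    }, numeric(1))
  })
  expect_gte(mean(rates), 0.0017)
  expect_lte(mean(rates), 0.0037)

  # boundary: exactly 3 sigma is NOT endorsed (strict inequality)
  expect_equal(classify_three_sigma(c(33), mu_wt = 30, sigma_wt = 1)$n_alt, 0)
  expect_equal(classify_three_sigma(c(33 + 1e-9), 30, 1)$n_alt, 1)

  # 1 % spike-in at +10 sigma: frequency ~ 0.01 + background tail
  freqs <- withr::with_seed(71, {
    vapply(1:50, function(i) {
      x <- gen_probe_lengths(5000, pi_alt = 0.01, mu_wt = 30, sigma_wt = 1,
                             mu_alt = 40, sigma_alt = 1)
      classify_three_sigma(x$length_kb, 30, 1)$frequency
    }, numeric(1))
  })
  expect_lt(abs(mean(freqs) - (0.01 + 0.99 * 2 * pnorm(-3))), 0.005)

  # one-sided variant only counts lengthening
  x <- c(25, 35)
  expect_equal(classify_three_sigma(x, 30, 1, sides = "two")$n_alt, 2)
  expect_equal(classify_three_sigma(x, 30, 1, sides = "one")$n_alt, 1)
})

test_that("endorsed frequency is monotone nonincreasing in sigma_wt", {
  x <- withr::with_seed(72, rnorm(2000, 30, 2))
  freqs <- vapply(c(0.5, 1, 1.5, 2, 3),
                  function(s) classify_three_sigma(x, 30, s)$frequency,
                  numeric(1))
  expect_true(all(diff(freqs) <= 0))
  # bookkeeping identity
  res <- classify_three_sigma(x, 30, 1)
  expect_identical(res$frequency * res$n_total, as.numeric(res$n_alt))
})

test_that("frequency estimation dispatches by regime hint with GMM fallback", {
  abundant <- gen_probe_lengths(1000, pi_alt = 0.5, mu_wt = 30,
                                sigma_wt = 1.5, mu_alt = 45,
                                sigma_alt = 1.5, seed = 80)
  r1 <- estimate_frequency(abundant$length_kb, regime_hint = 0.5)
  expect_equal(r1$regime, "gmm")
  expect_lt(abs(r1$frequency - 0.5), 0.05)

  rare <- gen_probe_lengths(5000, pi_alt = 0.01, mu_wt = 30, sigma_wt = 1,
                            mu_alt = 40, sigma_alt = 1, seed = 81)
  r2 <- estimate_frequency(rare$length_kb, regime_hint = 0.01,
                           mu_wt = 30, sigma_wt = 1)
  expect_equal(r2$regime, "three_sigma")
  expect_lt(abs(r2$frequency - 0.013), 0.006)

  # single-Gaussian data: the GMM is degenerate, so the unhinted path
  # falls back to the 3-sigma rule
  pure <- withr::with_seed(82, rnorm(1000, 30, 1))
  r3 <- estimate_frequency(pure)
  expect_equal(r3$regime, "three_sigma")
  expect_match(r3$path, "degenerate")
  # tail rate stays small; the degenerate split can narrow the estimated
  # wild-type sigma, so the false rate can exceed the ideal 0.27 %
  expect_lte(r3$frequency, 0.03)

  # well-separated data without a hint stays with the GMM
  r4 <- estimate_frequency(abundant$length_kb)
  expect_equal(r4$regime, "gmm")
})

test_that("the descriptive report summarizes designs", {
  x <- dplyr::bind_rows(
    gen_probe_lengths(200, 0, 30, 1, 45, 1, design_id = "GMC1", seed = 90),
    gen_probe_lengths(300, 0.5, 30, 1, 45, 1, design_id = "GMC2", seed = 91)
  )
  rep <- combing_report(x)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n_signals, c(200, 300))
  expect_gt(rep$shapiro_p[1], 0.001)
  expect_lt(rep$shapiro_p[2], 0.01)
})
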