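test_that("Poisson inversion matches closed forms and flags bad wells", {
  # half-negative well: lambda = ln 2
  expect_equal(poisson_lambda(20000, 10000)$lambda, log(2), tolerance = 1e-12)
  # all-negative well: exactly zero occupancy with zero SE
  allneg <- poisson_lambda(20000, 20000)
  expect_identical(allneg$lambda, 0)
  expect_identical(allneg$se_lambda, 0)
  # near-saturated well: -ln(1e-4) with the delta-method SE
  near <- poisson_lambda(10000, 1)
  expect_equal(near$lambda, -log(1e-4), tolerance = 1e-9)
  expect_equal(near$se_lambda, sqrt(0.9999 / (10000 * 1e-4)), tolerance = 1e-9)

  expect_error(poisson_lambda(10000, 0, well_id = "B07"),
               class = "vcnref_saturation_error")
  expect_error(poisson_lambda(10000, 0, well_id = "B07"), "B07")
  expect_error(poisson_lambda(0, 0), class = "vcnref_invalid_counts")
  expect_error(poisson_lambda(100, 200), class = "vcnref_invalid_counts")
})

test_that("concentration scales with dilution factor and partition volume", {
  w <- make_wells(20000, 10000, df = 20)
  rxn <- dpcr_quantify(w, scope = "reaction")
  smp <- dpcr_quantify(w, scope = "sample")
  expect_equal(rxn$value, log(2) / 0.00085, tolerance = 1e-9)  # 815.47
  expect_equal(smp$value, 20 * rxn$value, tolerance = 1e-12)
  expect_equal(smp$standard_uncertainty, 20 * rxn$standard_uncertainty)

  # lambda = 0 gives zero concentration regardless of Df, Vd
  z <- dpcr_quantify(make_wells(20000, 20000, df = 50, vd = 3e-4),
                     scope = "sample")
  expect_identical(z$value, 0)

  # linearity in Df, inverse linearity in Vd
  a <- dpcr_quantify(make_wells(20000, 8000, vd = 0.00085), scope = "reaction")
  b <- dpcr_quantify(make_wells(20000, 8000, vd = 0.00034), scope = "reaction")
  expect_equal(b$value / a$value, 0.00085 / 0.00034, tolerance = 1e-12)
})

test_that("lambda is strictly decreasing in the negative fraction", {
  negs <- seq(1000, 20000, by = 1000)
  lam <- poisson_lambda(rep(20000, length(negs)), negs)$lambda
  expect_true(all(diff(lam) < 0))
})

test_that("partition-volume conversion rescales by the volume ratio", {
  x <- tibble::tibble(value = 1000, standard_uncertainty = 10,
                      partition_volume_ul = 0.000769)
  y <- convert_partition_volume(x, to_vd = 0.00085)
  expect_equal(y$value, 1000 * 0.769 / 0.85, tolerance = 1e-9)  # 904.7
  expect_equal(y$standard_uncertainty, 10 * 0.769 / 0.85, tolerance = 1e-9)
  expect_equal(y$partition_volume_ul, 0.00085)

  # identity and the chamber-platform factor
  expect_equal(convert_partition_volume(x, to_vd = 0.000769)$value, 1000)
  x2 <- tibble::tibble(value = 1000, standard_uncertainty = 0,
                       partition_volume_ul = 0.00034)
  expect_equal(convert_partition_volume(x2, to_vd = 0.00085)$value, 400,
               tolerance = 1e-9)
  expect_error(convert_partition_volume(x, to_vd = -1),
               class = "vcnref_invalid_volume")
})

test_that("duplex VCN is the ploidy-scaled ratio with delta-method uncertainty", {
  t0 <- tibble::tibble(value = 2000, standard_uncertainty = 0)
  r0 <- tibble::tibble(value = 1000, standard_uncertainty = 0)
  expect_equal(vcn_from_duplex(t0, r0)$vcn, 4)

  # zero target (the vector-free component) gives VCN 0
  expect_equal(vcn_from_duplex(
    tibble::tibble(value = 0, standard_uncertainty = 0), r0)$vcn, 0)

  # uncertainty: value * sqrt((u_t/c_t)^2 + (u_r/c_r)^2)
  tu <- tibble::tibble(value = 2000, standard_uncertainty = 40)
  ru <- tibble::tibble(value = 1000, standard_uncertainty = 30)
  est <- vcn_from_duplex(tu, ru)
  expect_equal(est$standard_uncertainty,
               4 * sqrt((40 / 2000)^2 + (30 / 1000)^2), tolerance = 1e-12)

  expect_error(vcn_from_duplex(t0, tibble::tibble(value = 0,
                                                  standard_uncertainty = 0)),
               class = "vcnref_no_reference")
  expect_error(
    vcn_from_duplex(dplyr::mutate(t0, scope = "sample"),
                    dplyr::mutate(r0, scope = "reaction")),
    class = "vcnref_contract_error"
  )
})

test_that("VCN is invariant under a common partition-volume conversion", {
  w <- gen_partition_wells(c_target = 1000, c_ref = 500, n_wells = 3, seed = 42)
  q <- dpcr_quantify(pool_replicates(w), scope = "sample", min_partitions = 0)
  tgt <- q[q$channel == "target", ]
  ref <- q[q$channel == "reference", ]
  v1 <- vcn_from_duplex(tgt, ref)$vcn
  v2 <- vcn_from_duplex(convert_partition_volume(tgt, 0.00034),
                        convert_partition_volume(ref, 0.00034))$vcn
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("merging partitions equals quantifying the summed counts", {
  w <- make_wells(c(20000, 20000), c(10000, 5000), channel = "target")
  pooled <- pool_replicates(w)
  expect_equal(pooled$n_negative, 15000)
  lam <- poisson_lambda(pooled$n_total, pooled$n_negative)$lambda
  expect_equal(lam, -log(15000 / 40000), tolerance = 1e-12)  # 0.9808

  # two identical wells merge to the same lambda as either
  w2 <- make_wells(c(20000, 20000), c(8000, 8000), channel = "target")
  p2 <- pool_replicates(w2)
  expect_equal(poisson_lambda(p2$n_total, p2$n_negative)$lambda,
               poisson_lambda(20000, 8000)$lambda)

  # mixed partition volumes are a contract error under merging
  w3 <- make_wells(c(20000, 20000), c(8000, 8000), channel = "target")
  w3$partition_volume_ul <- c(0.00085, 0.00034)
  expect_error(pool_replicates(w3), class = "vcnref_contract_error")
  expect_error(pool_replicates(w3[0, ]), class = "vcnref_empty_input")
})

test_that("average_wells flags the single-well case", {
  w <- gen_partition_wells(800, 400, n_wells = 1, seed = 7)
  expect_warning(res <- dpcr_vcn(w, method = "average_wells"),
                 "single-well")
  expect_true(is.na(res$standard_uncertainty))
  expect_equal(res$n_wells, 1)
})

test_that("simulated counts round-trip through the Poisson inversion", {
  # n_negative ~ Binomial(20000, exp(-c * vd)) at c = 500 copies/uL;
  # the inversion must recover c without bias and with a calibrated SE
  c_true <- 500
  vd <- 0.00085
  reps <- 1000
  est <- withr::with_seed(101, {
    nneg <- rbinom(reps, 20000, exp(-c_true * vd))
    occ <- poisson_lambda(rep(20000, reps), nneg)
    list(c_hat = occ$lambda / vd, se = occ$se_lambda / vd)
  })
  mean_se <- mean(est$se)
  expect_lt(abs(mean(est$c_hat) - c_true), 3 * mean_se / sqrt(reps))
  expect_lt(abs(sd(est$c_hat) - mean_se) / mean_se, 0.2)
})
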