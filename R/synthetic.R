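# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments and seed (base R Mersenne-Twister; RNG state is restored
# after each call), so the whole pipeline is testable without any external
# submission data.

#' Simulate dPCR partition counts for a duplex assay
#'
#' Emulates Poisson occupancy: for a channel at sample concentration `c`
#' (copies/uL), the reaction carries `c / dilution_factor` and each of the
#' `n_partitions` partitions of volume `vd` is negative with probability
#' \eqn{\exp(-c\, v_d / D_f)}, so `n_negative ~ Binomial(n, exp(-lambda))`.
#'
#' @param c_target,c_ref Sample concentrations of the target and reference
#'   channels (copies/uL, >= 0).
#' @param vd Partition volume in uL (default 0.00085, the droplet-platform
#'   default).
#' @param n_partitions Partitions per well (default 20000).
#' @param n_wells Replicate wells (default 3).
#' @param dilution_factor Default 1.
#' @param sample,lab Metadata carried on each row.
#' @param seed Optional integer seed.
#' @return A wells tibble consumable by [dpcr_quantify()] / [dpcr_vcn()].
#' @examples
#' gen_partition_wells(1000, 500, n_wells = 2, seed = 1)
#' @export
gen_partition_wells <- function(c_target, c_ref, vd = 0.00085,
                                n_partitions = 20000, n_wells = 3,
                                dilution_factor = 1, sample = "S1",
                                lab = "lab1", seed = NULL) {
  stopifnot(c_target >= 0, c_ref >= 0, n_partitions > 0, n_wells >= 1,
            vd > 0, dilution_factor >= 1)
  with_seed_or_not(seed, {
    draw <- function(conc, channel) {
      p_neg <- exp(-conc * vd / dilution_factor)
      tibble::tibble(
        well_id = sprintf("W%02d", seq_len(n_wells)),
        sample = sample, lab = lab, channel = channel,
        n_total = n_partitions,
        n_negative = rbinom(n_wells, n_partitions, p_neg),
        partition_volume_ul = vd, dilution_factor = dilution_factor
      )
    }
    dplyr::bind_rows(draw(c_target, "target"), draw(c_ref, "reference"))
  })
}

#' Simulate per-laboratory results under the random-effects model
#'
#' \eqn{x_i = \mu + b_i + e_i} with lab biases \eqn{b_i \sim N(0, \tau^2)}
#' and measurement noise \eqn{e_i \sim N(0, u_i^2)}; the stated standard
#' uncertainty of lab i is \eqn{u_i}.
#'
#' @param mu True consensus value.
#' @param tau Between-lab SD (>= 0).
#' @param u Vector of within-lab standard uncertainties (> 0), one per lab.
#' @param seed Optional integer seed.
#' @return A tibble with `lab_id`, `estimate`, `standard_uncertainty`.
#' @export
gen_lab_results <- function(mu, tau, u, seed = NULL) {
  stopifnot(tau >= 0, all(u > 0))
  with_seed_or_not(seed, {
    n <- length(u)
    tibble::tibble(
      lab_id = sprintf("lab%02d", seq_len(n)),
      estimate = mu + rnorm(n, 0, tau) + rnorm(n, 0, u),
      standard_uncertainty = u
    )
  })
}

#' Simulate Cq measurements from a known standard curve
#'
#' Calibrator rows follow `cq = intercept + slope * log10(quantity)` plus
#' Gaussian noise; unknown rows are generated at the Cq implied by
#' `unknown_quantity`.
#'
#' @param slope,intercept True curve parameters (slope < 0).
#' @param calibrator_quantities Dilution series (default `10^(2:6)`).
#' @param replicates Calibrator replicates per level (default 2).
#' @param sigma_cq Cq noise SD (default 0).
#' @param unknown_quantity Optional named vector of true copies/reaction for
#'   unknown samples; one Cq row per `replicates` is emitted per sample and
#'   assay label `"target"`.
#' @param seed Optional integer seed.
#' @return A Cq tibble consumable by [fit_standard_curve()] / [qpcr_vcn()].
#' @export
gen_cq_data <- function(slope, intercept, calibrator_quantities = 10^(2:6),
                        replicates = 2, sigma_cq = 0,
                        unknown_quantity = NULL, seed = NULL) {
  stopifnot(slope < 0)
  with_seed_or_not(seed, {
    q <- rep(calibrator_quantities, each = replicates)
    cal <- tibble::tibble(
      sample = "calibrator", assay = "target",
      cq = intercept + slope * log10(q) + rnorm(length(q), 0, sigma_cq),
      calibrator_quantity = q
    )
    if (is.null(unknown_quantity)) return(cal)
    uq <- rep(unknown_quantity, each = replicates)
    unk <- tibble::tibble(
      sample = rep(names(unknown_quantity), each = replicates),
      assay = "target",
      cq = intercept + slope * log10(uq) + rnorm(length(uq), 0, sigma_cq),
      calibrator_quantity = NA_real_
    )
    dplyr::bind_rows(cal, unk)
  })
}

#' Simulate wells for a homogeneity study
#'
#' Draws `n_sets` dispensed sets, each with `n_wells` duplex wells, where the
#' per-set true VCN is `vcn` plus a Gaussian set effect of SD `set_sd`
#' (set-to-set inhomogeneity; 0 for a perfectly homogeneous material).
#'
#' @param vcn True vector copy number of the component.
#' @param c_ref Reference-channel sample concentration (copies/uL); the
#'   target concentration is `vcn / 2 * c_ref`.
#' @param set_sd Between-set SD on the VCN scale (default 0).
#' @param n_sets Number of sets (default 8).
#' @param n_wells Wells per set per channel (default 3).
#' @param n_partitions,vd As in [gen_partition_wells()].
#' @param dispense_orders Optional dispensing orders, default `1:n_sets`.
#' @param seed Optional integer seed.
#' @return A wells tibble with a `set_id` column.
#' @export
gen_homogeneity_wells <- function(vcn, c_ref = 500, set_sd = 0, n_sets = 8,
                                  n_wells = 3, n_partitions = 20000,
                                  vd = 0.00085, dispense_orders = NULL,
                                  seed = NULL) {
  stopifnot(vcn >= 0, set_sd >= 0, n_sets >= 1)
  if (is.null(dispense_orders)) dispense_orders <- seq_len(n_sets)
  with_seed_or_not(seed, {
    purrr::map_dfr(seq_len(n_sets), function(s) {
      vcn_s <- max(0, vcn + rnorm(1, 0, set_sd))
      w <- gen_partition_wells(c_target = vcn_s / 2 * c_ref, c_ref = c_ref,
                               vd = vd, n_partitions = n_partitions,
                               n_wells = n_wells, sample = "S1", lab = "lab1")
      w$set_id <- dispense_orders[s]
      w
    })
  })
}

#' Render integration-site reports in laboratory dialects
#'
#' Renders each true duplication interval in each laboratory's reporting
#' dialect, optionally perturbing coordinates (emulating pre-curation
#' discrepancies) or relocating a site to a different chromosome (emulating
#' a mismapping event). Samples with no true sites are rendered as
#' `"not detected"`.
#'
#' @param truth Tibble of true sites (`sample`, `chrom`, `tsd_start`,
#'   `tsd_end`); defaults to the packaged consensus panel. Samples listed in
#'   `samples` but absent from `truth` get "not detected" rows.
#' @param dialect_by_lab Named character vector, lab id to dialect
#'   (`"junction_pair"`, `"bare_range"`, `"single_junction"`).
#' @param p_offset Probability a rendered coordinate is shifted by
#'   `U{1..max_offset_bp}` in a random direction.
#' @param max_offset_bp Maximum perturbation (default 5).
#' @param p_chrom_swap Probability a site is relocated to another chromosome.
#' @param samples Sample universe (default: those in `truth`).
#' @param seed Optional integer seed.
#' @return A tibble with `sample`, `lab_id`, `site_string`.
#' @export
gen_is_reports <- function(truth = NULL,
                           dialect_by_lab = c(lab9 = "junction_pair",
                                              lab10 = "bare_range",
                                              lab11 = "single_junction"),
                           p_offset = 0, max_offset_bp = 5,
                           p_chrom_swap = 0, samples = NULL, seed = NULL) {
  if (is.null(truth)) truth <- fixture_panel()$sites
  check_columns(truth, c("sample", "chrom", "tsd_start", "tsd_end"), "truth")
  if (is.null(samples)) samples <- unique(truth$sample)
  fmt <- function(x) formatC(x, format = "d", big.mark = ",")
  decoys <- paste0("chr", c(2, 5, 7, 9, 11, 19))
  with_seed_or_not(seed, {
    rows <- list()
    for (lab in names(dialect_by_lab)) {
      dialect <- dialect_by_lab[[lab]]
      for (smp in samples) {
        sites <- truth[truth$sample == smp, , drop = FALSE]
        if (nrow(sites) == 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample = smp, lab_id = lab, site_string = "not detected")
          next
        }
        for (i in seq_len(nrow(sites))) {
          chrom <- sites$chrom[i]
          a <- sites$tsd_start[i]
          b <- sites$tsd_end[i]
          if (p_chrom_swap > 0 && stats::runif(1) < p_chrom_swap) {
            chrom <- sample(setdiff(decoys, chrom), 1)
          }
          jitter <- function(x) {
            if (p_offset > 0 && stats::runif(1) < p_offset) {
              x + sample(c(-1, 1), 1) * sample.int(max_offset_bp, 1)
            } else x
          }
          s <- switch(
            dialect,
            junction_pair = sprintf("%s:%s(+) - %s(-)", chrom,
                                    fmt(jitter(a)), fmt(jitter(b))),
            bare_range = sprintf("%s:%s-%s", chrom, fmt(jitter(a)),
                                 fmt(jitter(b))),
            single_junction = if (stats::runif(1) < 0.5) {
              sprintf("%s:%s(+)", chrom, fmt(jitter(a)))
            } else {
              sprintf("%s:%s(-)", chrom, fmt(jitter(b)))
            },
            stop_vcnref(paste0("unknown dialect: ", dialect),
                        "vcnref_schema_error")
          )
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample = smp, lab_id = lab, site_string = s)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a combing probe-length population
#'
#' Two-component Gaussian mixture draw: a fraction `pi_alt` of signals from
#' the integration-bearing distribution, the rest wild-type.
#'
#' @param n Number of signals.
#' @param pi_alt Alternative fraction in `[0, 1]`.
#' @param mu_wt,sigma_wt,mu_alt,sigma_alt Component parameters (kb).
#' @param design_id Label carried on each row.
#' @param seed Optional integer seed.
#' @return A tibble with `design_id`, `signal_id`, `length_kb`, and the
#'   generating `class` (`"wt"`/`"alt"`).
#' @export
gen_probe_lengths <- function(n, pi_alt, mu_wt, sigma_wt, mu_alt, sigma_alt,
                              design_id = "GMC1", seed = NULL) {
  stopifnot(n >= 1, pi_alt >= 0, pi_alt <= 1, sigma_wt > 0, sigma_alt > 0)
  with_seed_or_not(seed, {
    is_alt <- stats::runif(n) < pi_alt
    tibble::tibble(
      design_id = design_id,
      signal_id = sprintf("sig%05d", seq_len(n)),
      length_kb = ifelse(is_alt, rnorm(n, mu_alt, sigma_alt),
                         rnorm(n, mu_wt, sigma_wt)),
      class = ifelse(is_alt, "alt", "wt")
    )
  })
}

#' Packaged reference-panel fixtures
#'
#' The in-study panel, machine-readable: the five blinded components and
#' their true VCNs (A = 4, B = 2, C = 0, D = 3, E = 1), the three
#' laboratories' verbatim integration-site report strings, the prior
#' reference list the consensus is compared against, the 10 consensus
#' duplication intervals with gene/region labels and duplication sequences,
#' the long-read insertion calls, and a synthetic annotation interval set
#' reproducing the printed gene/region labels (real gene extents are not
#' part of the panel; intervals are constructed around the sites).
#'
#' Duplication sequences are carried verbatim per source table; the two
#' source tables disagree for some sites (reverse complements and shifted
#' windows), so they are never reconciled.
#'
#' @return A list: `true_vcn` (named numeric), `blinding_map`, `reports`,
#'   `reference`, `sites`, `pacbio`, `annotation`.
#' @examples
#' panel <- fixture_panel()
#' panel$true_vcn
#' @export
fixture_panel <- function() {
  path <- function(f) system.file("extdata", f, package = "vcnref",
                                  mustWork = TRUE)
  read <- function(f) readr::read_csv(path(f), show_col_types = FALSE,
                                      progress = FALSE)
  truth <- read("panel_truth.csv")
  sites <- read("table5_consensus_sites.csv")
  stopifnot(nrow(sites) == 10)
  list(
    true_vcn = setNames(truth$true_vcn, truth$sample),
    blinding_map = truth,
    reports = read("table4_reports.csv"),
    reference = read("prior_reference.csv"),
    sites = sites,
    pacbio = read("table6_pacbio_insertions.csv"),
    annotation = read("table5_annotation_synthetic.csv")
  )
}
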