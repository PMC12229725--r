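---
title: "Characterizing vector copy number reference materials with vcnref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing vector copy number reference materials with vcnref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcnref)
library(dplyr)
```

## The measurement problem

Lentiviral-vector cell and gene therapy products must report the average
number of integrated vector copies per cell (the vector copy number, VCN)
and, increasingly, the genomic locations of those integrations. Neither
measurement is standardized: different laboratories use different PCR
chemistries, partition volumes, reference genes, sequencing pipelines, and
coordinate-reporting conventions. A candidate reference material — a panel
of clonal cell lines (and genomic DNA extracted from them) with defined
VCNs of 0 through 4 and known integration sites — lets each of those
methods be benchmarked against the same ground truth.

`vcnref` implements the statistical layer of that characterization:

* Poisson quantification of digital PCR (dPCR) partition counts, with
  uncertainty, partition-volume conversion, and duplex VCN ratios;
* qPCR standard curves with amplification-efficiency QC;
* consensus estimation across laboratories by the DerSimonian–Laird
  random-effects procedure, reporting "dark uncertainty";
* homogeneity (set-to-set) and stability (time-trend) assessment of the
  material itself;
* harmonization of integration-site reports across laboratory dialects
  under the 5-bp target-site-duplication model; and
* classification of molecular-combing probe-length signals into wild-type
  and integration-bearing classes.

Every input the pipeline consumes can be simulated by the packaged
generators, so the full analysis is testable without any laboratory
submission data.

## dPCR: Poisson occupancy and VCN

A dPCR well splits a reaction into $n$ partitions of volume $V_d$
(microlitres). Under Poisson loading, the fraction of negative partitions
$p$ estimates $e^{-\lambda}$, where $\lambda$ is the mean copies per
partition, so

$$\hat\lambda = -\ln\frac{n_{neg}}{n},\qquad
  se(\hat\lambda) = \sqrt{\frac{1-p}{n\,p}},$$

the second expression being the binomial delta method. Concentration in
the reaction is $\lambda / V_d$ and in the undiluted sample
$D_f\,\lambda / V_d$ for dilution factor $D_f$. VCN is the ploidy-scaled
ratio of the vector target to a single-copy host reference gene:

$$\mathrm{VCN} = 2\,\frac{c_{target}}{c_{reference}},$$

with uncertainty by the ratio delta method. Because both channels share
the partition volume, VCN is exactly invariant to it — a property the test
suite asserts to $10^{-12}$ relative — while concentrations convert
between platforms by the volume ratio (`convert_partition_volume()`;
droplet instruments default to 0.85 nL, chamber instruments to 0.34 nL,
with per-laboratory calibrated overrides carried per well).

```{r dpcr}
wells <- gen_partition_wells(c_target = 1000, c_ref = 500,
                             n_partitions = 20000, n_wells = 3, seed = 11)
dpcr_vcn(wells)
```

Design choices worth noting:

* **Saturated wells** (no negative partitions) are a hard error, not
  $\lambda = \infty$: the concentration is beyond the method's dynamic
  range and no finite estimate is defensible.
* **Replicate pooling** defaults to summing partition counts across wells
  (`merge_partitions`), which maximizes the partition count behind a
  single inversion and is exactly equivalent to quantifying the summed
  tallies; averaging per-well VCNs (`average_wells`) is available when
  wells are not exchangeable. A single well under averaging has no
  between-well SE and is flagged rather than given a fabricated one.
* **Well QC**: wells below 10,000 partitions (configurable) warn but are
  not dropped — the paper trail belongs to the analyst.
* Uncertainty is the per-well binomial delta method; partition-volume
  variation between droplets is out of scope.

## qPCR standard curves

Cq is modeled as linear in $\log_{10}$(copies). The amplification
efficiency is $E = 10^{-1/slope} - 1$, with $E = 1$ at perfect
per-cycle doubling ($slope = -1/\log_{10}2 \approx -3.32$); the
conventional acceptance window $0.9 \le E \le 1.10$ is applied inclusively
by `efficiency_in_range()`. Calibrator replicates enter the fit as
individual points to preserve residual information. Quantities for unknown
wells invert the curve, $10^{(Cq - b)/m}$, and per-sample VCNs carry the
between-replicate standard error only — curve-parameter uncertainty is not
propagated, matching the convention of reporting replicate SD in
interlaboratory summaries.

```{r qpcr}
cal <- tibble::tibble(calibrator_quantity = 10^(3:7),
                      cq = 40 - (1 / log10(2)) * log10(10^(3:7)))
fit_standard_curve(cal)
```

## Consensus with dark uncertainty

Each laboratory $i$ reports $x_i \pm u_i$. The model is
$x_i = \mu + b_i + e_i$ with lab effects $b_i \sim N(0, \tau^2)$ and noise
$e_i \sim N(0, u_i^2)$. With fixed-effects weights $w_i = u_i^{-2}$ and
Cochran's $Q$, the DerSimonian–Laird moment estimate is

$$\hat\tau^2 = \max\!\left\{0,\;
  \frac{Q - (n-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right\},$$

after which the consensus is the $w_i^* = 1/(u_i^2 + \hat\tau^2)$-weighted
mean with standard uncertainty $(\sum w_i^*)^{-1/2}$. $\hat\tau$ — the
*dark uncertainty* — is the between-laboratory standard deviation beyond
what the stated uncertainties explain; in a homogeneity assessment the
same machinery applied across dispensed sets estimates set-to-set
variability.

```{r dl}
labs <- gen_lab_results(mu = 4, tau = 0.08,
                        u = c(0.03, 0.05, 0.02, 0.04, 0.06, 0.03, 0.05),
                        seed = 17)
fit <- dersimonian_laird(labs)
glance(fit)
```

Numerical and design choices:

* The default 95 % interval is the normal approximation
  $\hat x \pm 1.96\,u(\hat x)$; a parametric-bootstrap percentile interval
  (`bootstrap_ci()`, resampling $x_i^* \sim N(\hat x, \sqrt{u_i^2 +
  \hat\tau^2})$ and refitting) is provided because the reference
  implementation's internal interval method is not published. Neither is
  asserted to be "the" method. At seven laboratories both intervals sit
  near the lower edge of nominal coverage (~90 %), the familiar small-$n$
  behaviour of DL intervals; small-sample corrections such as
  Knapp–Hartung are deliberately out of scope.
* Multiple submissions from one laboratory (e.g. a droplet and a chamber
  instrument) are pooled as distinct results.
* A degenerate input where every uncertainty is zero *and* all estimates
  agree — the vector-free component, where every measurement is exactly
  0 — returns that value with $\tau = 0$ rather than erroring; zero
  uncertainties with disagreeing estimates remain an error.
* `relative_dark_uncertainty()` is undefined at a zero consensus and says
  so; the homogeneity wrapper reports absolute $\tau$ there instead.

## Homogeneity and stability of the material

Homogeneity: eight sets are drawn across the dispensing order, a VCN is
quantified per set (pooling its wells' partitions), and DL across sets
turns dark uncertainty into the set-to-set SD. A complementary weighted
regression of the negative-partition proportion on dispensing order
(`dispense_trend_test()`, weights reciprocal binomial variances, two-sided
$\alpha = 0.05$) checks for fill-order trends. The trend test operates on
the negative-droplet proportion, not on VCN, because that is the raw
signal in which a dispensing artifact would first appear. Exclusions are
config-driven (set, well, and a mandatory reason) — notebook-documented
dispensing errors, never statistical outlier hunting.

Stability: a component is stable when every time point lies within
$k\sqrt{u_t^2 + u_0^2}$ of baseline (coverage factor $k = 2$, the
metrology convention, inclusive at the boundary) *and* the 95 % CI of the
weighted VCN-on-day slope contains zero. Both diagnostics are always
reported.

```{r stability}
ts <- tibble::tibble(day = c(0, 400, 810), vcn = c(4.01, 3.99, 4.02),
                     standard_uncertainty = 0.05)
stability_assessment(ts)
```

## Integration-site harmonization

Lentiviral integration duplicates 5 bp of host sequence around the
insertion point, leaving a provirus–host junction at each end of the
duplicated interval. Laboratories report the *same* event as the
plus-strand junction, the minus-strand junction, both, or a bare
coordinate range in either order — so raw reports legitimately disagree by
up to 4 bp. `vcnref` parses the three dialects, maps every report onto its
canonical duplication interval (1-based, inclusive; plus junction = start,
minus junction = end), groups per-sample sites with a configurable
tolerance (default 0 bp: base-exact agreement after canonicalization), and
compares the consensus against a prior reference list by greedy pairing —
exact junction matches first, then nearest same-chromosome, leftovers as
chromosome mismatches.

```{r sites}
panel <- fixture_panel()
consensus <- parse_site_report(panel$reports$site_string,
                               panel$reports$sample,
                               panel$reports$lab_id) |>
  canonicalize_sites() |>
  build_site_consensus()
sum(consensus$consensus)
compare_to_reference(consensus, panel$reference) |> count(category)
```

On the packaged panel this harmonization yields: 10 consensus
sites across the five components (none in the VCN0 component), all with
5-bp intervals; against the prior reference list, 4 exact junction
matches, 5 same-chromosome offsets (1, 1, 28, 77, and 100 bp), and one
chromosome mismatch — a site reported on chr4 in earlier work but located
on chr16 here, attributed to short-read mismapping near an LTR-adjacent
repeat. The long-read insertion model ties the picture together: a
4,154-bp provirus with one extra inserted base yields a 4,155-bp inserted
sequence, and 4,160 bp when a structural-variant caller includes the 5-bp
duplication in the insertion call.

Sites convert to BED6 on output (0-based half-open, the interval's
strand-symmetric representation). The gene/region annotation operation
takes user-supplied labeled intervals; the packaged annotation fixture is
*synthetic* — intervals constructed around the known sites to carry the
published gene and region labels — because real gene extents are not part
of the panel. Duplication sequences are stored verbatim per source table
and never reconciled: the two published tables disagree for some sites
(reverse complements, 1-bp shifted windows), and no orientation convention
is stated.

## Molecular-combing signal classification

On fully stretched fibers, probe length is approximately Gaussian
(`normality_check()`, Shapiro–Wilk, advisory only). An integration
lengthens the spanned probe, so:

* **Abundant variants** (expected above ~5 % of signals): a two-component
  univariate Gaussian mixture fit by EM (`classify_gmm()`). Initialization
  is deterministic — component means at the 25th/75th percentiles, equal
  variances at half the pooled SD — so fits are bit-reproducible without a
  seed; "default parameters" of any particular library are not portable,
  determinism is.
* **Rare variants** (below ~2 %): the 3σ rule (`classify_three_sigma()`)
  endorses a signal when it strays more than three wild-type SDs from the
  wild-type mean (strict inequality; two-sided by default, one-sided
  optional since an insertion lengthens the probe). The two-sided false
  endorsement rate on pure wild-type is $2\Phi(-3) \approx 0.27\,\%$,
  which the tests verify empirically.
* **The unstated 2–5 % gap** resolves to GMM-with-fallback: fit the
  mixture, and fall back to 3σ when it is degenerate (component means
  closer than twice the pooled within-component SD, or non-convergence).
  `estimate_frequency()` records the decision path taken.

```{r combing}
signals <- gen_probe_lengths(1000, pi_alt = 0.5, mu_wt = 30, sigma_wt = 1.5,
                             mu_alt = 45, sigma_alt = 1.5, seed = 7)
estimate_frequency(signals$length_kb, regime_hint = 0.5)
```

## What the generators emulate — and what they do not

The synthetic module generates binomial negative-partition counts under
Poisson occupancy, Gaussian lab effects on top of stated uncertainties,
Cq values from a log-linear curve, site reports rendered in each dialect
with optional coordinate jitter and chromosome swaps, and two-component
Gaussian probe-length mixtures. Default scales mirror the study design:
20,000 partitions per well, three wells, seven laboratories, eight
dispensed sets, and the panel's true VCNs $\{A{:}4, B{:}2, C{:}0, D{:}3,
E{:}1\}$. The reference-gene concentration defaults to 500 copies/µL, a
round value in the range implied by ~25 ng/µL genomic DNA input; the true
per-sample reference concentrations were never published, so this is a
stated choice, not an inference.

What passing tests on synthetic data do *not* show: real droplet
misclassification near the fluorescence threshold, partition-volume
variation between droplets, PCR inhibition, reference-gene copy-number
aberrations in the cell line (the panel's karyotype argues for avoiding
chr2, chr18, and chrY reference genes), sequencing pipeline artifacts
beyond coordinate conventions, or combing-image segmentation errors. The
harmonizer consumes reported coordinates, not reads.

## Problem sizes and determinism

All randomness flows through explicit `seed` arguments (base R
Mersenne–Twister, state restored after each call), so every simulated
result in the test suite is reproducible. Simulation-based tests use
100–1000 replicates per property (e.g. 1000 simulated studies for CI
coverage, 200 seeds for the 3σ calibration, 200 mixtures for EM
recovery) — sizes chosen so each property's Monte-Carlo error is well
inside its asserted band.

## Known limitations

* No Knapp–Hartung or $t$-based small-sample adjustment for the DL
  interval; at $n \le 7$ laboratories nominal 95 % intervals run near
  90 % coverage.
* The qPCR module does not model calibrator-value uncertainty or
  inter-plate effects, and ΔΔCq relative quantification is out of scope.
* The mixture classifier is univariate by construction; multi-probe
  pattern features would need a different model.
* Genome-sequence operations (extracting duplication sequences, liftover)
  are out of scope; the harmonizer never touches a reference genome.
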