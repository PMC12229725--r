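# Shared helpers for building small in-memory fixtures.

make_wells <- function(n_total, n_negative, channel = "target",
                       vd = 0.00085, df = 1, well_id = NULL, ...) {
  k <- max(length(n_total), length(n_negative), length(channel))
  tibble::tibble(
    well_id = well_id %||% sprintf("W%02d", seq_len(k)),
    channel = rep_len(channel, k),
    n_total = rep_len(n_total, k),
    n_negative = rep_len(n_negative, k),
    partition_volume_ul = vd,
    dilution_factor = df,
    ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force solver for the between-group variance moment
# equation: with fixed weights w_i = u_i^-2 and Cochran's Q at those weights,
# E[Q] = (n - 1) + tau2 * (sum w - sum w^2 / sum w). Solve for tau2 >= 0 by
# grid search, never by the closed-form division the implementation uses.
brute_force_tau2 <- function(x, u, grid_max = NULL, grid_n = 200001) {
  n <- length(x)
  w <- 1 / u^2
  xb <- sum(w * x) / sum(w)
  q <- sum(w * (x - xb)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  if (is.null(grid_max)) grid_max <- (max(x) - min(x))^2 + max(u)^2
  grid <- seq(0, grid_max, length.out = grid_n)
  grid[which.min(abs(q - (n - 1) - grid * cc))]
}
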