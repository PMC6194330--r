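# Physics-flavoured symbol sources: single-site 2D Ising Gibbs dynamics
# and a thresholded double-well Langevin ion-channel model.

#' Critical temperature of the 2D Ising model
#'
#' The exact square-lattice value `2 / log(1 + sqrt(2))` (J = 1,
#' k_B = 1), approximately 2.269.
#'
#' @return A numeric scalar.
#' @export
ising_critical_temperature <- function() 2 / log(1 + sqrt(2))

#' Single-site time series of 2D Ising Gibbs dynamics
#'
#' Simulates a square-lattice Ising model (ferromagnetic coupling J = 1,
#' periodic boundaries) by systematic raster-scan Gibbs sweeps: each site
#' is set to +1 with probability `1 / (1 + exp(-2 * beta * S))` where `S`
#' is its neighbour sum and `beta = 1/T`. One value of the selected site
#' is recorded per full sweep after burn-in, with spins mapped
#' `-1 -> 0`, `+1 -> 1`. Near the critical temperature the site series
#' shows slow power-law-like decay of autoinformation; far above it the
#' decay is fast and the series approaches an iid coin.
#'
#' @param temperature Temperature in units of J/k_B (> 0).
#' @param side Lattice side length (default 50).
#' @param n_sweeps Number of recorded sweeps (default 1e6).
#' @param burn_in Discarded initial sweeps (default 1e4).
#' @param site Lattice coordinates (row, column) of the recorded site.
#' @param record_configs Also record the full configuration per sweep as
#'   a bit code (requires `side^2 <= 50`; used for small-lattice exact
#'   checks).
#' @param seed Optional seed.
#' @return A binary [symbol_sequence()]; if `record_configs`, the
#'   per-sweep configuration codes are attached as attribute `configs`.
#' @export
simulate_ising_site <- function(temperature, side = 50, n_sweeps = 1e6,
                                burn_in = 1e4, site = c(1, 1),
                                record_configs = FALSE, seed = NULL) {
  stopifnot(temperature > 0, side >= 2, burn_in >= 0)
  if (record_configs && side^2 > 50)
    stop("record_configs requires side^2 <= 50")
  site <- as.integer(site)
  if (any(site < 1) || any(site > side)) stop("site out of range")
  res <- .local_seed(seed, {
    cpp_ising_site(as.integer(side), 1 / temperature, as.integer(n_sweeps),
                   as.integer(burn_in), site[1] - 1L, site[2] - 1L,
                   record_configs)
  })
  out <- symbol_sequence(res$site, 2)
  if (record_configs) attr(out, "configs") <- res$configs
  out
}

#' Double-well Langevin dynamics (two-state ion-channel model)
#'
#' Euler integration of motion in the potential
#' `V(x) = -(a/2) x^2 + (b/4) x^4`, which has stable minima at
#' `x = ±sqrt(a/b)` and an unstable maximum at 0, driven by iid Gaussian
#' per-step noise:
#' `X_{n+1} = X_n + (a X_n - b X_n^3) dt + xi_n`, `xi_n ~ N(0, sigma^2)`.
#' The defaults keep the minima at ±1 while making the relaxation time
#' comparable to the sampling interval (`a * dt = 0.5`), so threshold
#' crossings are resolved in a few samples — as in electrophysiological
#' recordings of channel gating — and produce clearly bistable
#' trajectories with well-to-well transitions every ~10^4 steps.
#'
#' @param n Number of samples.
#' @param a,b Potential coefficients (> 0).
#' @param noise_sigma Gaussian noise scale per step (default 0.17).
#' @param dt Integration step (default 1e-3).
#' @param x0 Initial value (default `sqrt(a/b)`, i.e. in a well).
#' @param seed Optional seed.
#' @return A numeric vector of length `n`. An error is raised if the
#'   trajectory diverges (`|x| > 10 sqrt(a/b)`).
#' @export
simulate_double_well <- function(n, a = 500, b = 500, noise_sigma = 0.17,
                                 dt = 1e-3, x0 = NULL, seed = NULL) {
  stopifnot(a > 0, b > 0, dt > 0, noise_sigma >= 0, n >= 1)
  if (is.null(x0)) x0 <- sqrt(a / b)
  .local_seed(seed, {
    cpp_double_well(as.integer(n), a, b, noise_sigma, dt, x0)
  })
}

#' Threshold a metric series into a binary symbol sequence
#'
#' Values strictly above the threshold map to symbol 1 (the "open"
#' state), all others — including exact threshold hits — to symbol 0
#' (the "closed" state; the tie rule is a measure-zero event under a
#' continuous model and is fixed for determinism).
#'
#' @param x Numeric vector.
#' @param threshold Threshold (default 0).
#' @return A binary [symbol_sequence()].
#' @examples
#' threshold_binarize(c(-1, 2, -3, 4))
#' @export
threshold_binarize <- function(x, threshold = 0) {
  symbol_sequence(as.integer(x > threshold), 2)
}
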