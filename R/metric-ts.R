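# Autoregressive simulation and ACF/PACF estimation: the classical
# metric-series counterpart that motivates the autoinformation analogy.

#' Autoregressive model specification
#'
#' @param coefficients Numeric vector `(phi_1, ..., phi_p)` of AR
#'   coefficients.
#' @param noise_sigma Innovation standard deviation (> 0).
#' @return An object of class `ar_model`. A warning (not an error) is
#'   issued when the characteristic polynomial has a root inside or on
#'   the unit circle, i.e. the model is not stationary.
#' @examples
#' ar_model(c(0.85, -0.2, 0.1))
#' @export
ar_model <- function(coefficients, noise_sigma = 1) {
  phi <- as.numeric(coefficients)
  if (length(phi) < 1) stop("at least one AR coefficient is required")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  roots <- polyroot(c(1, -phi))
  if (any(Mod(roots) <= 1 + 1e-10))
    warning("AR model is not stationary (characteristic root on or inside the unit circle)",
            call. = FALSE)
  structure(list(coefficients = phi, noise_sigma = noise_sigma,
                 p = length(phi)),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<AR(%d) model: phi = (%s), sigma = %g>\n", x$p,
              paste(format(x$coefficients), collapse = ", "),
              x$noise_sigma))
  invisible(x)
}

#' Simulate an autoregressive process
#'
#' Runs the AR(p) recursion with iid Gaussian innovations, zero initial
#' values, and discards the first `10 * p` samples as transient.
#'
#' @param model An [ar_model()].
#' @param n Number of retained samples (`n > p`).
#' @param seed Optional seed.
#' @return A numeric vector of length `n`.
#' @export
simulate_ar <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "ar_model"))
  n <- as.integer(n)
  if (n <= model$p) stop("n must exceed the model order")
  burn <- 10L * model$p
  .local_seed(seed, {
    eps <- rnorm(n + burn, sd = model$noise_sigma)
    x <- stats::filter(eps, model$coefficients, method = "recursive",
                       init = rep(0, model$p))
    as.numeric(x)[(burn + 1):(burn + n)]
  })
}

# biased (1/N) sample autocorrelations rho_0..rho_kmax
.sample_acf <- function(x, kmax) {
  as.numeric(stats::acf(x, lag.max = kmax, plot = FALSE,
                        demean = TRUE)$acf)
}

# Durbin-Levinson recursion on a sample ACF; returns phi_kk, k = 1..kmax
.durbin_levinson <- function(rho, kmax) {
  pacf_out <- numeric(kmax)
  phi_prev <- numeric(0)
  for (k in seq_len(kmax)) {
    if (k == 1) {
      phi_kk <- rho[2]
    } else {
      num <- rho[k + 1] - sum(phi_prev * rho[k:2])
      den <- 1 - sum(phi_prev * rho[2:k])
      phi_kk <- num / den
    }
    pacf_out[k] <- phi_kk
    phi_prev <- if (k == 1) phi_kk
                else c(phi_prev - phi_kk * rev(phi_prev), phi_kk)
  }
  pacf_out
}

#' Sample autocorrelation and partial autocorrelation profiles
#'
#' `acf_profile()` returns lag-k Pearson correlations of aligned pairs
#' (biased, 1/N normalization; value 1 at lag 0). `pacf_profile()`
#' computes partial autocorrelations by the Durbin-Levinson recursion on
#' the sample ACF, with the zero-lag coefficient defined as 1. Both
#' attach the classical Box-Jenkins iid confidence band
#' `±z_{1-alpha/2} / sqrt(N)`.
#'
#' @param x Numeric vector.
#' @param max_lag Largest lag.
#' @param alpha Significance level for the band.
#' @return A `lag_profile` tibble with columns `lag`, `value`, `ci_low`,
#'   `ci_high`.
#' @examples
#' x <- simulate_ar(ar_model(0.8), 2000, seed = 1)
#' pacf_profile(x, 5)
#' @export
acf_profile <- function(x, max_lag, alpha = 0.05) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("input has zero variance")
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= length(x))
    stop("max_lag must be in [0, length(x) - 1]")
  vals <- .sample_acf(x, max_lag)
  z <- qnorm(1 - alpha / 2) / sqrt(length(x))
  new_lag_profile(
    tibble::tibble(lag = 0:max_lag, value = vals,
                   ci_low = -z, ci_high = z),
    "acf", normalized = TRUE, alpha = alpha)
}

#' @rdname acf_profile
#' @export
pacf_profile <- function(x, max_lag, alpha = 0.05) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("input has zero variance")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= length(x) / 2)
    stop("max_lag must be in [1, length(x)/2)")
  rho <- .sample_acf(x, max_lag)
  vals <- c(1, .durbin_levinson(rho, max_lag))
  z <- qnorm(1 - alpha / 2) / sqrt(length(x))
  new_lag_profile(
    tibble::tibble(lag = 0:max_lag, value = vals,
                   ci_low = -z, ci_high = z),
    "pacf", normalized = TRUE, alpha = alpha)
}
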