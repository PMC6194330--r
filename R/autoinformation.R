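# Autoinformation (time-lagged mutual information) and partial
# autoinformation (conditional mutual information given the intermediate
# symbols) lag profiles, with permutation-surrogate confidence bands.

new_lag_profile <- function(df, kind, normalized = FALSE, alpha = NA_real_) {
  structure(df, kind = kind, normalized = normalized, alpha = alpha,
            class = c("lag_profile", class(df)))
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag profile: %s%s, %d lags>\n", attr(x, "kind"),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else "",
              nrow(x)))
  NextMethod()
}

# mutual information of the N-k aligned pairs (x_n, x_{n+k}); marginals
# are taken over the aligned subsets so the plug-in MI is >= 0 and
# symmetric under time reversal
.aif_value <- function(x, k, L) {
  N <- length(x)
  if (k == 0) return(.ent_counts(tabulate(x + 1L, L)))
  a <- x[seq_len(N - k)]
  b <- x[seq_len(N - k) + k]
  Ha <- .ent_counts(tabulate(a + 1L, L))
  Hb <- .ent_counts(tabulate(b + 1L, L))
  Hab <- .ent_counts(tabulate(a + L * b + 1L, L * L))
  Ha + Hb - Hab
}

.aif_values <- function(x, max_lag, L) {
  vapply(0:max_lag, function(k) .aif_value(x, k, L), 0)
}

# paif values for lags 0..max_lag; lags 0 and 1 equal the corresponding
# autoinformation coefficients by convention
.paif_values <- function(x, max_lag, L, mode) {
  out <- numeric(max_lag + 1)
  out[1] <- .aif_value(x, 0L, L)
  if (max_lag >= 1) out[2] <- .aif_value(x, 1L, L)
  if (max_lag >= 2) {
    if (mode == "windowed") {
      H <- .h_entropies(x, max_lag + 1L, L)
      ks <- 2:max_lag
      out[ks + 1] <- 2 * H[ks] - H[ks - 1] - H[ks + 1]
    } else {
      for (k in 2:max_lag)
        out[k + 1] <- .marginal_measures(x, k, L)$paif
    }
  }
  out
}

.profile_fun <- function(statistic) {
  switch(statistic,
         aif = function(x, max_lag, L, mode) .aif_values(x, max_lag, L),
         paif = .paif_values)
}

#' Autoinformation function (time-lagged mutual information)
#'
#' The autoinformation coefficient at lag `k` is the mutual information
#' `I(X_{n+k}; X_n)` between process values `k` steps apart, estimated
#' from all `N - k` aligned pairs — the information-theoretic analogue of
#' the autocorrelation function. The lag-0 coefficient is the single
#' symbol entropy `H_1`.
#'
#' @inheritParams joint_entropy
#' @param max_lag Largest lag (default 50).
#' @param normalize Divide all coefficients by the lag-0 value so the
#'   profile starts at 1?
#' @param n_surrogates If positive, attach an iid permutation-surrogate
#'   confidence band (see [iid_confidence_band()]); 0 skips the band.
#' @param alpha Significance level for the band.
#' @param seed Optional seed for the surrogate permutations.
#' @return A `lag_profile` tibble with columns `lag`, `value` and, when a
#'   band is requested, `ci_low`, `ci_high` (all in bits unless
#'   normalized).
#' @examples
#' x <- sample_markov(random_transition_model(2, 1, seed = 1), 2000, seed = 2)
#' aif(x, max_lag = 5)
#' @export
aif <- function(x, max_lag = 50, n_symbols = NULL, normalize = FALSE,
                n_surrogates = 0, alpha = 0.05, seed = NULL) {
  s <- .as_seq(x, n_symbols)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= length(s$x))
    stop("max_lag must be in [0, length(x) - 1]")
  vals <- .aif_values(s$x, max_lag, s$L)
  df <- tibble::tibble(lag = 0:max_lag, value = vals)
  if (n_surrogates > 0) {
    band <- iid_confidence_band(s$x, max_lag, statistic = "aif",
                                n_symbols = s$L, n_surrogates = n_surrogates,
                                alpha = alpha, seed = seed)
    df$ci_low <- band$ci_low
    df$ci_high <- band$ci_high
  }
  if (normalize && vals[1] > 0) {
    df$value <- df$value / vals[1]
    if ("ci_low" %in% names(df)) {
      df$ci_low <- df$ci_low / vals[1]
      df$ci_high <- df$ci_high / vals[1]
    }
  }
  new_lag_profile(df, "aif", normalized = normalize,
                  alpha = if (n_surrogates > 0) alpha else NA_real_)
}

#' Partial autoinformation function
#'
#' The partial autoinformation coefficient at lag `k` is the conditional
#' mutual information `I(X_{n+k}; X_n | X_{n+k-1}, ..., X_{n+1})`: the
#' dependence between values `k` steps apart that is not conveyed through
#' the intermediate symbols — the analogue of the partial autocorrelation
#' function. Lags 0 and 1, which have no intermediates, are set to the
#' corresponding autoinformation coefficients. In the stationary plug-in
#' form the coefficient equals the entropy-rate difference
#' `h_{k-1} - h_k`, i.e. minus the second difference of `H_k`; for a
#' Markov process of order `M` all coefficients beyond lag `M` vanish,
#' which is what makes the profile an order diagnostic.
#'
#' Estimation requires joint distributions over `L^(k+1)` bins, so the
#' cost grows exponentially with `max_lag`; a warning is issued when the
#' sample is too short to fill the bins and an error when `L^(max_lag+1)`
#' exceeds the hard cap (`getOption("painf.hard_cap", 2^26)`).
#'
#' @inheritParams aif
#' @param max_lag Largest lag (default 8, suited to small alphabets).
#' @param mode See [entropy_rate()]. In `"windowed"` mode small negative
#'   coefficients can occur and are reported as-is; in `"marginal"` mode
#'   coefficients are non-negative by construction.
#' @return A `lag_profile` tibble as for [aif()].
#' @examples
#' x <- sample_markov(random_transition_model(2, 1, seed = 1), 5000, seed = 2)
#' paif(x, max_lag = 4)
#' @export
paif <- function(x, max_lag = 8, n_symbols = NULL,
                 mode = c("windowed", "marginal"),
                 n_surrogates = 0, alpha = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  s <- .as_seq(x, n_symbols)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag + 1L > length(s$x))
    stop("max_lag + 1 must not exceed length(x)")
  if (s$L^(max_lag + 1) > .hard_cap())
    stop(sprintf("L^(max_lag+1) = %.3g exceeds the hard cap %.3g; reduce max_lag",
                 s$L^(max_lag + 1), .hard_cap()))
  .check_undersampling(length(s$x), max_lag + 1L, s$L, "partial autoinformation")
  vals <- .paif_values(s$x, max_lag, s$L, mode)
  df <- tibble::tibble(lag = 0:max_lag, value = vals)
  if (n_surrogates > 0) {
    band <- iid_confidence_band(s$x, max_lag, statistic = "paif",
                                n_symbols = s$L, n_surrogates = n_surrogates,
                                alpha = alpha, seed = seed, mode = mode)
    df$ci_low <- band$ci_low
    df$ci_high <- band$ci_high
  }
  new_lag_profile(df, "paif",
                  alpha = if (n_surrogates > 0) alpha else NA_real_)
}

#' Permutation-surrogate confidence band under the iid null
#'
#' Randomly permutes the symbols of the sequence (preserving the marginal
#' distribution, destroying all temporal structure), recomputes the
#' requested lag statistic for each surrogate, and returns the empirical
#' `alpha/2` and `1 - alpha/2` percentiles per lag. A data coefficient
#' above the band indicates temporal dependence at that lag beyond what
#' finite-sample bias produces in an uncorrelated sequence.
#'
#' @inheritParams aif
#' @param statistic `"aif"` or `"paif"`.
#' @param n_surrogates Number of permutation surrogates (default 100;
#'   at least 20 recommended).
#' @param mode Estimation mode for the PAIF statistic.
#' @return A tibble with columns `lag`, `ci_low`, `ci_high`.
#' @export
iid_confidence_band <- function(x, max_lag, statistic = c("aif", "paif"),
                                n_symbols = NULL, n_surrogates = 100,
                                alpha = 0.05, seed = NULL,
                                mode = c("windowed", "marginal")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  s <- .as_seq(x, n_symbols)
  max_lag <- as.integer(max_lag)
  n_surrogates <- as.integer(n_surrogates)
  if (n_surrogates < 1L) stop("n_surrogates must be positive")
  fun <- .profile_fun(statistic)
  vals <- .local_seed(seed, {
    vapply(seq_len(n_surrogates), function(i) {
      fun(sample(s$x), max_lag, s$L, mode)
    }, numeric(max_lag + 1))
  })
  vals <- matrix(vals, nrow = max_lag + 1)
  qs <- apply(vals, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  tibble::tibble(lag = 0:max_lag, ci_low = qs[1, ], ci_high = qs[2, ])
}

#' Export a lag profile as a delimited table
#'
#' Writes tab-separated columns `lag`, `value`, `ci_low`, `ci_high`,
#' `kind`, `normalized` (missing bands written as `NA`).
#'
#' @param profile A `lag_profile`.
#' @param path Output path.
#' @export
export_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lag_profile"))
  df <- tibble::as_tibble(profile)
  if (!"ci_low" %in% names(df)) { df$ci_low <- NA_real_; df$ci_high <- NA_real_ }
  df$kind <- attr(profile, "kind")
  df$normalized <- isTRUE(attr(profile, "normalized"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
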