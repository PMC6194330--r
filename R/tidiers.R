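# broom-style tidy() and glance() methods for the package's result
# objects; lag profiles are already tibbles, so their tidier is a thin
# coercion that materializes the attributes as columns.

#' @exportS3Method generics::tidy
tidy.lag_profile <- function(x, ...) {
  df <- tibble::as_tibble(x)
  df$kind <- attr(x, "kind")
  df
}

#' @exportS3Method generics::glance
glance.lag_profile <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"),
                 n_lags = nrow(x),
                 normalized = isTRUE(attr(x, "normalized")),
                 alpha = attr(x, "alpha"))
}

#' @exportS3Method generics::tidy
tidy.transition_model <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    history = rep(rownames(tab), times = ncol(tab)),
    symbol = rep(as.integer(colnames(tab)), each = nrow(tab)),
    probability = as.vector(tab))
}

#' @exportS3Method generics::glance
glance.transition_model <- function(x, ...) {
  tibble::tibble(order = x$order, n_symbols = x$n_symbols,
                 n_histories = nrow(x$table),
                 n_observed = sum(x$observed))
}

#' @exportS3Method generics::tidy
tidy.two_state_analytics <- function(x, ...) {
  tibble::tibble(quantity = c("H", "h", "a"),
                 value = c(x$H, x$h, x$a),
                 units = "bit")
}

#' @exportS3Method generics::glance
glance.two_state_analytics <- function(x, ...) {
  tibble::tibble(p = x$p, q = x$q,
                 p_A = x$stationary[[1]], p_B = x$stationary[[2]],
                 lambda_2 = x$eigenvalues[[2]],
                 H = x$H, h = x$h, a = x$a)
}

#' @exportS3Method generics::tidy
tidy.markov_lr_test <- function(x, ...) {
  tibble::tibble(order = x$order, statistic = x$statistic,
                 dof = x$dof, p_value = x$p_value)
}

#' @exportS3Method generics::glance
glance.markov_lr_test <- function(x, ...) {
  tibble::tibble(order = x$order, statistic = x$statistic,
                 dof = x$dof, p_value = x$p_value,
                 n = x$n, n_symbols = x$n_symbols)
}

#' @exportS3Method generics::tidy
tidy.ce_test <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.ce_test <- function(x, ...) {
  tibble::tibble(identified_order = x$identified_order,
                 none_accepted = is.na(x$identified_order),
                 M_max = x$M_max, k_max = x$k_max,
                 n_surrogates = x$n_surrogates, alpha = x$alpha,
                 n = x$n, n_symbols = x$n_symbols)
}
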