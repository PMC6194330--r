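# Hypothesis tests for the Markov order of a symbol sequence:
# likelihood-ratio (G) tests of orders 0-2 in the Kullback tradition,
# and the surrogate-based conditional-entropy order test.

#' Likelihood-ratio (Kullback) Markovianity test of order 0, 1 or 2
#'
#' Tests whether dependence of order `m + 1` is present beyond order `m`
#' using the likelihood-ratio G statistic on consecutive tuple counts:
#'
#' * order 0: `G = 2 sum n_ij log(n_ij n / (n_i. n_.j))`,
#'   dof `(L-1)^2` — independence of consecutive symbols;
#' * order 1: `G = 2 sum n_ijk log(n_ijk n_.j. / (n_ij. n_.jk))`,
#'   dof `L (L-1)^2` — first-order sufficiency against second-order;
#' * order 2: the analogous statistic on quadruples,
#'   dof `L^2 (L-1)^2`.
#'
#' Zero cells contribute zero (the continuity convention
#' `n log n -> 0`). The p-value is the upper chi-square tail with the
#' stated asymptotic degrees of freedom. A warning is issued when the
#' expected cell count falls below 5.
#'
#' @inheritParams joint_entropy
#' @param order Tested Markov order: 0, 1 or 2.
#' @return An object of class `markov_lr_test` with fields `order`,
#'   `statistic`, `dof`, `p_value`, `n_symbols`, `n`.
#' @examples
#' x <- sample_hmm(golden_mean_2state(), 5000, seed = 1)
#' kullback_markov_test(x, order = 0)
#' @export
kullback_markov_test <- function(x, order, n_symbols = NULL) {
  s <- .as_seq(x, n_symbols)
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  L <- s$L
  w <- order + 2L                       # tuple length used by the test
  if (length(s$x) < w) stop("sequence too short for this order")
  n_windows <- length(s$x) - w + 1L
  if (n_windows / L^w < 5)
    warning(sprintf("expected cell count %.2f < 5 for order-%d test; the chi-square approximation may be poor",
                    n_windows / L^w, order), call. = FALSE)
  cnt <- as.numeric(cpp_window_counts(s$x, w, L))
  # window digit 0 is the newest symbol; arrange as array with the
  # OLDEST tuple element in the first dimension (time order i, j, k, l)
  a <- array(cnt, dim = rep(L, w))
  a <- aperm(a, rev(seq_len(w)))
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  if (order == 0L) {
    ni <- rowSums(a); nj <- colSums(a); n <- sum(a)
    G <- 2 * (sum(xlx(a)) + xlx(n) - sum(xlx(ni)) - sum(xlx(nj)))
    dof <- (L - 1)^2
  } else if (order == 1L) {
    nij <- apply(a, c(1, 2), sum)
    njk <- apply(a, c(2, 3), sum)
    nj <- apply(a, 2, sum)
    G <- 2 * (sum(xlx(a)) + sum(xlx(nj)) - sum(xlx(nij)) - sum(xlx(njk)))
    dof <- L * (L - 1)^2
  } else {
    nijk <- apply(a, c(1, 2, 3), sum)
    njkl <- apply(a, c(2, 3, 4), sum)
    njk <- apply(a, c(2, 3), sum)
    G <- 2 * (sum(xlx(a)) + sum(xlx(njk)) - sum(xlx(nijk)) - sum(xlx(njkl)))
    dof <- L^2 * (L - 1)^2
  }
  structure(list(test = sprintf("likelihood-ratio Markovianity test, order %d", order),
                 order = order, statistic = G, dof = dof,
                 p_value = pchisq(G, dof, lower.tail = FALSE),
                 n_symbols = L, n = length(s$x)),
            class = "markov_lr_test")
}

#' @export
print.markov_lr_test <- function(x, ...) {
  cat(sprintf("%s\n  G = %.3f, dof = %d, p = %.4g (L = %d, N = %d)\n",
              x$test, x$statistic, x$dof, x$p_value, x$n_symbols, x$n))
  invisible(x)
}

#' Conditional-entropy Markov-order test with Markov surrogates
#'
#' For each candidate order `M = 0..M_max`, fits the maximum-likelihood
#' order-M transition model to the data, generates `n_surrogates`
#' surrogate sequences of the same length from it, and computes the
#' plug-in entropy-rate estimates `h_k` for `k = 1..k_max` on every
#' surrogate. The per-(M, k) confidence interval is the empirical
#' `[alpha/2, 1 - alpha/2]` percentile range across surrogates. The
#' identified order is the smallest `M` whose intervals contain the
#' data's `h_k` for all tested `k`; if no candidate qualifies the result
#' is the sentinel `NA` ("none <= M_max"), the signature of a process
#' with dependencies beyond `M_max` (such as the even process).
#'
#' @inheritParams joint_entropy
#' @param M_max Largest candidate order (default 5).
#' @param k_max Largest history length for the entropy-rate comparison
#'   (default `M_max + 1`, the smallest range that can discriminate all
#'   tested orders).
#' @param n_surrogates Surrogates per order (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional seed.
#' @return An object of class `ce_test` with fields `identified_order`
#'   (integer or `NA`), `accepted` (per-M logical), `summary` (tibble
#'   with `M`, `k`, `ci_low`, `ci_high`, `h_data`, `inside`), `h_data`,
#'   plus the call parameters.
#' @examples
#' x <- sample_hmm(golden_mean_2state(), 20000, seed = 1)
#' conditional_entropy_test(x, M_max = 2, n_surrogates = 30, seed = 2)
#' @export
conditional_entropy_test <- function(x, M_max = 5, k_max = M_max + 1,
                                     n_surrogates = 100, alpha = 0.05,
                                     n_symbols = NULL, seed = NULL) {
  s <- .as_seq(x, n_symbols)
  M_max <- as.integer(M_max); k_max <- as.integer(k_max)
  n_surrogates <- as.integer(n_surrogates)
  N <- length(s$x); L <- s$L
  if (k_max < 1L) stop("k_max must be >= 1")
  if (k_max + 1L > N) stop("k_max + 1 must not exceed length(x)")
  .check_undersampling(N, k_max + 1L, L, "conditional-entropy test")
  Hd <- .h_entropies(s$x, k_max + 1L, L)
  h_data <- Hd[seq_len(k_max) + 1L] - Hd[seq_len(k_max)]
  rows <- .local_seed(seed, {
    lapply(0:M_max, function(M) {
      model <- estimate_transition_model(s$x, M, n_symbols = L)
      hs <- vapply(seq_len(n_surrogates), function(i) {
        y <- suppressMessages(sample_markov(model, N))
        H <- .h_entropies(as.integer(y), k_max + 1L, L)
        H[seq_len(k_max) + 1L] - H[seq_len(k_max)]
      }, numeric(k_max))
      hs <- matrix(hs, nrow = k_max)
      qs <- apply(hs, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                  names = FALSE)
      tibble::tibble(M = M, k = seq_len(k_max),
                     ci_low = qs[1, ], ci_high = qs[2, ],
                     h_data = h_data,
                     inside = h_data >= qs[1, ] & h_data <= qs[2, ])
    })
  })
  summary <- dplyr::bind_rows(rows)
  accepted <- vapply(split(summary$inside, summary$M), all, TRUE)
  identified <- if (any(accepted)) as.integer(names(accepted)[which(accepted)[1]])
                else NA_integer_
  structure(list(identified_order = identified,
                 accepted = accepted, summary = summary, h_data = h_data,
                 M_max = M_max, k_max = k_max,
                 n_surrogates = n_surrogates, alpha = alpha,
                 n = N, n_symbols = L, seed = seed),
            class = "ce_test")
}

#' @export
print.ce_test <- function(x, ...) {
  cat(sprintf("Conditional-entropy Markov-order test (M = 0..%d, k = 1..%d, %d surrogates, alpha = %g)\n",
              x$M_max, x$k_max, x$n_surrogates, x$alpha))
  verdict <- if (is.na(x$identified_order))
    sprintf("no order <= %d accepted (extended, possibly non-Markovian memory)", x$M_max)
  else sprintf("identified Markov order M = %d", x$identified_order)
  cat(" ", verdict, "\n")
  acc <- paste(ifelse(x$accepted, "+", "-"), collapse = " ")
  cat(sprintf("  acceptance by order 0..%d: %s\n", x$M_max, acc))
  invisible(x)
}

#' Export a test report as structured text
#'
#' Writes `key: value` lines for a `markov_lr_test` or `ce_test`,
#' the human-readable counterpart of the JSON emitted by the
#' command-line `test` command.
#'
#' @param report A test object.
#' @param path Output path.
#' @export
export_test_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(report, "markov_lr_test")) {
    writeLines(sprintf("%s: %s",
                       c("test", "order", "statistic", "dof", "p_value",
                         "n", "n_symbols"),
                       c(report$test, report$order,
                         format(report$statistic, digits = 10), report$dof,
                         format(report$p_value, digits = 10),
                         report$n, report$n_symbols)), con)
  } else if (inherits(report, "ce_test")) {
    writeLines(c(sprintf("test: conditional-entropy Markov-order test"),
                 sprintf("identified_order: %s",
                         ifelse(is.na(report$identified_order),
                                sprintf("none <= %d", report$M_max),
                                report$identified_order)),
                 sprintf("M_max: %d", report$M_max),
                 sprintf("k_max: %d", report$k_max),
                 sprintf("n_surrogates: %d", report$n_surrogates),
                 sprintf("alpha: %g", report$alpha),
                 sprintf("accepted: %s",
                         paste(which(report$accepted) - 1, collapse = " "))),
               con)
  } else stop("unsupported report type")
  invisible(path)
}
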