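# Plug-in (maximum likelihood) entropy machinery over k-histories.
#
# Two estimation modes run through every derived quantity:
#  * "windowed" (default): each joint entropy H_k comes from its own
#    full window count (all N-k+1 contiguous windows).
#  * "marginal": for a requested history length k, a single (k+1)-window
#    distribution is estimated once and every lower-order entropy is
#    obtained by marginalizing it, which turns the conservation and
#    difference identities into exact algebraic identities and makes
#    conditional mutual information non-negative by construction.

.ent_counts <- function(counts) {
  cnt <- counts[counts > 0]
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

# dense or sparse window counting; returns positive counts only (sparse)
# or the full L^k vector (dense)
.wcounts <- function(x, k, L) {
  if (L^k <= .dense_cap()) {
    cpp_window_counts(x, k, L)
  } else {
    codes <- cpp_window_codes(x, k, L)
    as.integer(table(codes))
  }
}

.went <- function(x, k, L) .ent_counts(.wcounts(x, k, L))

# H_1..H_kmax, each from its own window count
.h_entropies <- function(x, kmax, L) {
  if (L^kmax <= .dense_cap()) cpp_entropy_profile(x, kmax, L)
  else vapply(seq_len(kmax), function(k) .went(x, k, L), 0)
}

.check_undersampling <- function(N, k, L, where = "joint entropy") {
  if (L^k > (N - k + 1) / 10)
    warning(sprintf(
      "%s at history length k = %d: L^k = %.3g bins for %d windows; plug-in estimates are likely biased (undersampling)",
      where, k, L^k, N - k + 1), call. = FALSE)
  invisible(NULL)
}

# All marginal-mode measures at history length k, derived from the single
# empirical (k+1)-window distribution. Digit 0 of a window code is the
# newest symbol; marginalization is a reshape + margin sum.
.marginal_measures <- function(x, k, L) {
  if (L^(k + 1) > .dense_cap())
    stop("marginal mode requires L^(k+1) dense-representable; use mode = 'windowed'")
  cnt <- as.numeric(cpp_window_counts(x, k + 1L, L))
  H_all <- .ent_counts(cnt)                       # H(X_n, ..., X_{n-k})
  m    <- matrix(cnt, nrow = L)                   # rows: newest symbol
  hist_k  <- colSums(m)                           # k-history before newest
  first_m <- rowSums(m)                           # newest-symbol marginal
  new_k   <- rowSums(matrix(cnt, ncol = L))       # newest k symbols
  mid     <- colSums(matrix(new_k, nrow = L))     # middle k-1 symbols
  H1   <- .ent_counts(first_m)
  H_hist <- .ent_counts(hist_k)
  H_newk <- .ent_counts(new_k)
  H_mid  <- if (k >= 2) .ent_counts(mid) else 0
  h_k   <- H_all - H_hist
  h_km1 <- if (k >= 2) H_newk - H_mid else H1     # k = 1: h_0 = H_1
  list(H1 = H1, Hk = H_newk, Hk_hist = H_hist, H_all = H_all,
       h_k = h_k, h_km1 = h_km1,
       a_k = H1 - h_k, a_km1 = H1 - h_km1,
       paif = h_km1 - h_k)
}

#' Empirical k-history distribution
#'
#' Counts every contiguous window of `k` symbols exactly once (`N - k + 1`
#' windows) and returns maximum-likelihood (plug-in) probabilities. The
#' history label lists symbols newest-first, i.e. `(X_n, X_{n-1}, ...,
#' X_{n-k+1})`.
#'
#' @param x A [symbol_sequence()] or integer vector of symbols.
#' @param k History length (positive integer, `k <= length(x)`).
#' @param n_symbols Optional alphabet-size override.
#' @return A tibble of class `khistory_dist` with columns `history`
#'   (comma-separated, newest symbol first), `count` and `probability`,
#'   restricted to observed histories; attributes `k`, `n_symbols`,
#'   `total` (number of windows) and `n_bins` (`L^k`).
#' @examples
#' khistory_distribution(c(0, 1, 0, 1, 0, 1), k = 2)
#' @export
khistory_distribution <- function(x, k, n_symbols = NULL) {
  s <- .as_seq(x, n_symbols)
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (k > length(s$x)) stop("k must not exceed the sequence length")
  .check_undersampling(length(s$x), k, s$L, "k-history distribution")
  dense <- s$L^k <= .dense_cap()
  if (dense) {
    cnt <- cpp_window_counts(s$x, k, s$L)
    codes <- which(cnt > 0) - 1
    cnt <- cnt[cnt > 0]
  } else {
    tab <- table(cpp_window_codes(s$x, k, s$L))
    codes <- as.numeric(names(tab))
    cnt <- as.integer(tab)
  }
  # decode base-L codes into newest-first labels (digit 0 = newest)
  lab <- vapply(codes, function(cd) {
    digs <- integer(k)
    for (j in seq_len(k)) { digs[j] <- cd %% s$L; cd <- cd %/% s$L }
    paste(digs, collapse = ",")
  }, "")
  total <- length(s$x) - k + 1L
  out <- tibble::tibble(history = lab, count = cnt,
                        probability = cnt / total)
  structure(out, k = k, n_symbols = s$L, total = total, n_bins = s$L^k,
            class = c("khistory_dist", class(out)))
}

#' Shannon entropy of a discrete distribution (bits)
#'
#' Plug-in entropy `-sum(p * log2(p))` with the convention `0 * log(0) = 0`.
#'
#' @param dist A `khistory_dist` from [khistory_distribution()], or a
#'   numeric probability vector summing to one.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))
#' @export
shannon_entropy <- function(dist) {
  if (inherits(dist, "khistory_dist")) {
    p <- dist$probability
  } else {
    p <- as.numeric(dist)
    if (any(p < 0)) stop("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy, entropy rate and active information storage
#'
#' Plug-in estimates of the joint entropy `H_k` of k-histories, the
#' finite-history entropy rate `h_k = H_{k+1} - H_k` (surprise per symbol
#' given a k-history) and the active information storage
#' `a_k = H_1 + H_k - H_{k+1}` (information about the next symbol stored
#' in its k-history), all in bits.
#'
#' @inheritParams khistory_distribution
#' @param mode `"windowed"` (each joint entropy from its own window
#'   count) or `"marginal"` (all terms marginalized from one
#'   (k+1)-history distribution, making the identities
#'   `H_1 = a_k + h_k` and the lag-profile difference identities exact).
#' @return A numeric scalar (bits).
#' @examples
#' x <- c(0, 1, 0, 1, 0, 1, 0, 1)
#' joint_entropy(x, 2)
#' entropy_rate(x, 1)
#' active_information_storage(x, 1)
#' @export
joint_entropy <- function(x, k, n_symbols = NULL) {
  s <- .as_seq(x, n_symbols)
  k <- as.integer(k)
  if (k < 1L || k > length(s$x)) stop("k must be in [1, length(x)]")
  .check_undersampling(length(s$x), k, s$L)
  .went(s$x, k, s$L)
}

#' @rdname joint_entropy
#' @export
entropy_rate <- function(x, k, n_symbols = NULL,
                         mode = c("windowed", "marginal")) {
  mode <- match.arg(mode)
  s <- .as_seq(x, n_symbols)
  k <- as.integer(k)
  if (k < 1L || k + 1L > length(s$x)) stop("need k + 1 <= length(x)")
  .check_undersampling(length(s$x), k + 1L, s$L, "entropy rate")
  if (mode == "windowed") {
    H <- .h_entropies(s$x, k + 1L, s$L)
    H[k + 1L] - H[k]
  } else {
    .marginal_measures(s$x, k, s$L)$h_k
  }
}

#' @rdname joint_entropy
#' @export
active_information_storage <- function(x, k, n_symbols = NULL,
                                       mode = c("windowed", "marginal")) {
  mode <- match.arg(mode)
  s <- .as_seq(x, n_symbols)
  k <- as.integer(k)
  if (k < 1L || k + 1L > length(s$x)) stop("need k + 1 <= length(x)")
  .check_undersampling(length(s$x), k + 1L, s$L, "active information storage")
  if (mode == "windowed") {
    H <- .h_entropies(s$x, k + 1L, s$L)
    H[1] + H[k] - H[k + 1L]
  } else {
    .marginal_measures(s$x, k, s$L)$a_k
  }
}

#' Entropy profile over history lengths
#'
#' Computes `H_k`, `h_k` and `a_k` for `k = 1..k_max` in one pass,
#' sharing window counts across quantities.
#'
#' @inheritParams joint_entropy
#' @param k_max Largest history length.
#' @param mode See [entropy_rate()].
#' @return A tibble with columns `k`, `H`, `h`, `a`.
#' @export
entropy_profile <- function(x, k_max, n_symbols = NULL,
                            mode = c("windowed", "marginal")) {
  mode <- match.arg(mode)
  s <- .as_seq(x, n_symbols)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max + 1L > length(s$x)) stop("need k_max + 1 <= length(x)")
  .check_undersampling(length(s$x), k_max + 1L, s$L, "entropy profile")
  if (mode == "windowed") {
    Hv <- .h_entropies(s$x, k_max + 1L, s$L)
    ks <- seq_len(k_max)
    tibble::tibble(k = ks, H = Hv[ks], h = Hv[ks + 1L] - Hv[ks],
                   a = Hv[1] + Hv[ks] - Hv[ks + 1L])
  } else {
    rows <- lapply(seq_len(k_max), function(k) {
      m <- .marginal_measures(s$x, k, s$L)
      tibble::tibble(k = k, H = m$Hk, h = m$h_k, a = m$a_k)
    })
    dplyr::bind_rows(rows)
  }
}
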