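# Order-M transition models: maximum-likelihood estimation, inverse-CDF
# surrogate sampling, random and lag-skipping constructions, and the
# two-state closed forms.
#
# History coding convention (also used by the text serialization): an
# M-history (X_n, X_{n-1}, ..., X_{n-M+1}) is coded in base L with the
# most recent symbol X_n in the lowest digit; row labels list symbols
# newest-first.

.hist_labels <- function(L, M) {
  if (M == 0) return("()")
  codes <- 0:(L^M - 1)
  vapply(codes, function(cd) {
    digs <- integer(M)
    for (j in seq_len(M)) { digs[j] <- cd %% L; cd <- cd %/% L }
    paste(digs, collapse = ",")
  }, "")
}

new_transition_model <- function(table, history_distribution, order, L,
                                 observed = NULL) {
  if (is.null(observed)) observed <- !is.na(table[, 1])
  rownames(table) <- .hist_labels(L, order)
  colnames(table) <- as.character(0:(L - 1))
  structure(list(order = as.integer(order), n_symbols = as.integer(L),
                 table = table,
                 history_distribution = history_distribution,
                 observed = observed),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<order-%d transition model over %d symbols (%d histories, %d observed)>\n",
              x$order, x$n_symbols, nrow(x$table), sum(x$observed)))
  print(utils::head(round(x$table, 4), 8))
  if (nrow(x$table) > 8) cat("...\n")
  invisible(x)
}

#' Maximum-likelihood estimation of an order-M transition model
#'
#' Estimates `P(X_{n+1} | X_n, ..., X_{n-M+1})` from all contiguous
#' `(M+1)`-tuples of the sequence; the empirical joint distribution of
#' M-histories is recorded in the same pass and is used to initialize
#' surrogate sampling. Rows for histories never observed in the data are
#' flagged invalid (`NA`) rather than silently uniform.
#'
#' @inheritParams joint_entropy
#' @param M Markov order (non-negative integer; `M = 0` gives the iid
#'   symbol distribution).
#' @return A `transition_model`: list with `order`, `n_symbols`, `table`
#'   (`L^M` by `L` matrix of transition probabilities, histories coded
#'   newest-symbol-first in base L), `history_distribution` and
#'   `observed`.
#' @examples
#' estimate_transition_model(c(0, 1, 0, 1, 0, 1, 0, 1), M = 1)
#' @export
estimate_transition_model <- function(x, M, n_symbols = NULL) {
  s <- .as_seq(x, n_symbols)
  M <- as.integer(M)
  if (M < 0L) stop("M must be a non-negative integer")
  if (M + 1L > length(s$x)) stop("need M + 1 <= length(x)")
  L <- s$L
  if (L^(M + 1) > .dense_cap()) stop("L^(M+1) too large for dense estimation")
  cnt <- cpp_window_counts(s$x, M + 1L, L)
  # digit 0 = newest = X_{n+1}; higher digits = history (X_n lowest)
  m <- matrix(as.numeric(cnt), nrow = L)     # rows: next symbol, cols: history
  hist_counts <- colSums(m)
  tab <- t(m) / ifelse(hist_counts > 0, hist_counts, NA_real_)
  observed <- hist_counts > 0
  tab[!observed, ] <- NA_real_
  new_transition_model(tab, hist_counts / sum(hist_counts), M, L, observed)
}

#' Sample a symbol sequence from a transition model
#'
#' The first `M` symbols are drawn from the recorded history
#' distribution; each subsequent symbol is drawn from the transition row
#' of the current M-history by inverse-CDF sampling (cumulative-sum
#' inversion of a uniform variate). If the chain reaches a history whose
#' row is invalid (never observed during estimation), the current history
#' is redrawn from the history distribution and the event is counted.
#'
#' @param model A `transition_model`.
#' @param n Length of the sequence to generate (`n > M`).
#' @param seed Optional seed.
#' @return A [symbol_sequence()]; the number of unobserved-history
#'   restarts is attached as attribute `n_fallback`.
#' @export
sample_markov <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "transition_model"))
  n <- as.integer(n)
  if (n <= model$order) stop("n must exceed the model order")
  tab <- model$table
  tab[is.na(tab)] <- 0
  cum <- t(apply(tab, 1, cumsum))
  if (ncol(model$table) == 1) cum <- matrix(1, nrow = nrow(tab))
  hd <- model$history_distribution
  if (is.null(hd) || !any(hd > 0)) hd <- rep(1 / nrow(tab), nrow(tab))
  res <- .local_seed(seed, {
    cpp_sample_markov(cum, model$observed, cumsum(hd / sum(hd)),
                      model$order, model$n_symbols, n)
  })
  if (res$n_fallback > 0)
    message(sprintf("sample_markov: %d unobserved-history restart(s)",
                    res$n_fallback))
  out <- symbol_sequence(res$seq, model$n_symbols)
  attr(out, "n_fallback") <- res$n_fallback
  out
}

# stationary distribution over history codes of the lifted first-order
# chain on L^M states (power iteration; exact enough for the model sizes
# shipped here)
.stationary_histories <- function(table, L, M) {
  if (M == 0) return(1)
  nh <- L^M
  topdiv <- L^(M - 1)
  v <- rep(1 / nh, nh)
  # history h emits s and becomes (h %% topdiv) * L + s; histories that
  # agree modulo topdiv collide, so accumulate by reshaping over the
  # (kept digits, dropped oldest digit) factorization h = hi*topdiv + lo
  for (it in 1:5000) {
    vn <- numeric(nh)
    for (s in 1:L) {
      w <- rowSums(matrix(v * table[, s], nrow = topdiv))  # by h %% topdiv
      vn[(0:(topdiv - 1)) * L + s] <- vn[(0:(topdiv - 1)) * L + s] + w
    }
    if (max(abs(vn - v)) < 1e-15) { v <- vn; break }
    v <- vn
  }
  v / sum(v)
}

#' Random order-M transition model
#'
#' Each transition row is an independent random point on the probability
#' simplex (normalized iid uniform variates). The history distribution is
#' set to the stationary distribution of the lifted chain so that samples
#' start in equilibrium.
#'
#' @param L Alphabet size (>= 2).
#' @param M Markov order (>= 1).
#' @param seed Optional seed.
#' @return A `transition_model`.
#' @export
random_transition_model <- function(L, M, seed = NULL) {
  L <- as.integer(L); M <- as.integer(M)
  if (L < 2L) stop("L must be >= 2")
  if (M < 1L) stop("M must be >= 1")
  tab <- .local_seed(seed, {
    m <- matrix(runif(L^M * L), nrow = L^M)
    m / rowSums(m)
  })
  new_transition_model(tab, .stationary_histories(tab, L, M), M, L,
                       observed = rep(TRUE, L^M))
}

#' Lag-skipping third-order Markov model
#'
#' An order-3 model in which the transition `X_n -> X_{n+1}` depends only
#' on `X_{n-2}`: all rows sharing the same oldest history symbol are
#' identical. The `L` conditional distributions are random simplex draws,
#' rejection-sampled until every pair is at least `min_tv` apart in total
#' variation so the skipped-lag dependence is statistically detectable.
#' The autoinformation of samples has period 3, while the partial
#' autoinformation peaks only at lag 3.
#'
#' @param L Alphabet size (default 3).
#' @param seed Optional seed.
#' @param min_tv Minimum pairwise total-variation separation between
#'   the conditional distributions (default 0.2).
#' @return A `transition_model` of order 3.
#' @export
lag_skipping_model <- function(L = 3, seed = NULL, min_tv = 0.2) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  cond <- .local_seed(seed, {
    repeat {
      cm <- matrix(runif(L * L), nrow = L)
      cm <- cm / rowSums(cm)
      tv <- utils::combn(L, 2, function(ij)
        sum(abs(cm[ij[1], ] - cm[ij[2], ])) / 2)
      if (min(tv) >= min_tv) break
    }
    cm
  })
  codes <- 0:(L^3 - 1)
  oldest <- codes %/% L^2          # digit 2 = X_{n-2}
  tab <- cond[oldest + 1, , drop = FALSE]
  new_transition_model(tab, .stationary_histories(tab, L, 3L), 3L, L,
                       observed = rep(TRUE, L^3))
}

#' Two-state first-order Markov chain as a transition model
#'
#' Builds the order-1 [estimate_transition_model()]-compatible model with
#' transition rates `p` (state 0 to 1) and `q` (1 to 0); the history
#' distribution is the stationary distribution `(q, p) / (p + q)`, so
#' samples start in equilibrium. The information-theoretic closed forms
#' of the same chain are available from [two_state_analytics()].
#'
#' @inheritParams two_state_analytics
#' @return A `transition_model` of order 1 over two symbols.
#' @examples
#' sample_markov(two_state_model(0.5, 1), 10, seed = 1)
#' @export
two_state_model <- function(p, q) {
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("p and q must lie in [0, 1]")
  if (p + q <= 0) stop("p + q must be positive")
  tab <- matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE)
  new_transition_model(tab, c(q, p) / (p + q), 1L, 2L,
                       observed = c(TRUE, TRUE))
}

#' Closed-form information measures of the two-state Markov process
#'
#' For the first-order chain with transition rates `p` (A to B) and `q`
#' (B to A): transition matrix, eigenvalues `1` and `1 - (p + q)`,
#' stationary distribution `(q, p) / (p + q)`, and — with
#' `phi(x) = -x log2 x`, `psi(x) = phi(x) + phi(1 - x)` — the Shannon
#' entropy `H = psi(p_A)`, entropy rate `h = p_A psi(p) + p_B psi(q)` and
#' active information storage `a = H - h`, all in bits. Total entropy is
#' conserved: `H = a + h` exactly.
#'
#' @param p,q Transition rates in `[0, 1]` with `p + q > 0`.
#' @return An object of class `two_state_analytics`.
#' @examples
#' two_state_analytics(0.5, 1)  # the golden-mean chain
#' @export
two_state_analytics <- function(p, q) {
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("p and q must lie in [0, 1]")
  if (p + q <= 0) stop("p + q must be positive (no stationary distribution otherwise)")
  phi <- function(x) ifelse(x > 0, -x * log2(x), 0)
  psi <- function(x) phi(x) + phi(1 - x)
  pA <- q / (p + q); pB <- p / (p + q)
  H <- psi(pA)
  h <- pA * psi(p) + pB * psi(q)
  structure(list(p = p, q = q,
                 transition_matrix = matrix(c(1 - p, p, q, 1 - q), 2, 2,
                                            byrow = TRUE,
                                            dimnames = list(c("A", "B"),
                                                            c("A", "B"))),
                 eigenvalues = c(1, 1 - (p + q)),
                 stationary = c(A = pA, B = pB),
                 H = H, h = h, a = H - h),
            class = "two_state_analytics")
}

#' @export
print.two_state_analytics <- function(x, ...) {
  cat(sprintf("<two-state Markov chain: p = %g, q = %g>\n", x$p, x$q))
  cat(sprintf("  stationary (p_A, p_B) = (%.4f, %.4f); eigenvalues 1, %.4f\n",
              x$stationary[1], x$stationary[2], x$eigenvalues[2]))
  cat(sprintf("  H = %.4f bit, h = %.4f bit, a = %.4f bit\n", x$H, x$h, x$a))
  invisible(x)
}

#' Read and write transition models as delimited text
#'
#' Header comment lines record `L`, `M`, the history coding convention
#' (base-L lexicographic order, most-recent symbol in the lowest digit)
#' and the history distribution; the body holds `L^M` rows of `L`
#' transition probabilities (`NA` for unobserved histories).
#'
#' @param model A `transition_model`.
#' @param path File path.
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# painf transition model",
    sprintf("# L=%d M=%d", model$n_symbols, model$order),
    "# rows: histories in base-L lexicographic code order; most-recent history symbol in the lowest digit",
    paste("# history_distribution:",
          paste(format(model$history_distribution, digits = 17),
                collapse = " "))), con)
  utils::write.table(format(model$table, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  lm <- regmatches(hdr, regexec("L=([0-9]+) M=([0-9]+)", hdr))
  lm <- lm[vapply(lm, length, 0L) == 3][[1]]
  L <- as.integer(lm[2]); M <- as.integer(lm[3])
  hd_line <- grep("history_distribution:", hdr, value = TRUE)
  hd <- as.numeric(strsplit(sub(".*history_distribution:\\s*", "", hd_line),
                            "\\s+")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                               function(r) suppressWarnings(as.numeric(r))))
  stopifnot(nrow(tab) == L^M, ncol(tab) == L)
  new_transition_model(tab, hd, M, L)
}
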