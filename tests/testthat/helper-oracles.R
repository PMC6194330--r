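# Independent brute-force oracles used by the test suite. Each oracle is
# deliberately written by explicit enumeration / direct summation over
# the empirical distribution, sharing no code path with the estimators
# it checks.

# joint entropy by explicit window scanning and string-keyed counting
oracle_joint_entropy <- function(x, k) {
  n <- length(x)
  words <- vapply(seq_len(n - k + 1), function(i)
    paste(x[i:(i + k - 1)], collapse = ","), "")
  p <- as.numeric(table(words)) / length(words)
  -sum(p * log2(p))
}

# conditional mutual information I(X_{n+k}; X_n | intermediates) by
# direct summation over the empirical joint distribution of the
# (k+1)-tuples (all marginals from that one distribution)
oracle_cmi <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 2)
  tup <- t(vapply(seq_len(n - k), function(i) x[i:(i + k)],
                  integer(k + 1)))
  key <- function(m) apply(m, 1, paste, collapse = ",")
  joint <- table(key(tup)) / nrow(tup)
  left <- table(key(tup[, 1:k, drop = FALSE])) / nrow(tup)        # X_n + mid
  right <- table(key(tup[, 2:(k + 1), drop = FALSE])) / nrow(tup) # mid + X_{n+k}
  mid <- table(key(tup[, 2:k, drop = FALSE])) / nrow(tup)
  s <- 0
  for (w in names(joint)) {
    parts <- strsplit(w, ",")[[1]]
    pj <- joint[[w]]
    pl <- left[[paste(parts[1:k], collapse = ",")]]
    pr <- right[[paste(parts[2:(k + 1)], collapse = ",")]]
    pm <- mid[[paste(parts[2:k], collapse = ",")]]
    s <- s + pj * log2(pj * pm / (pl * pr))
  }
  s
}

# regression-based partial autocorrelation: correlate the residuals of
# X_{n+k} and X_n after regressing both on the intermediate values
oracle_pacf_regression <- function(x, kmax) {
  vapply(seq_len(kmax), function(k) {
    n <- length(x) - k
    y <- x[(k + 1):length(x)]
    x0 <- x[1:n]
    if (k == 1) return(stats::cor(x0, y))
    Z <- vapply(1:(k - 1), function(j) x[(1 + j):(n + j)], numeric(n))
    stats::cor(stats::resid(stats::lm(y ~ Z)),
               stats::resid(stats::lm(x0 ~ Z)))
  }, 0)
}

# exact Boltzmann distribution of the 3x3 periodic Ising lattice
# (J = 1), over configuration bit codes (site r*3+c is bit r*3+c)
oracle_boltzmann_3x3 <- function(temperature) {
  p <- numeric(512)
  for (c0 in 0:511) {
    s <- 2 * ((c0 %/% 2^(0:8)) %% 2) - 1
    m <- matrix(s, 3, 3)
    en <- 0
    for (r in 1:3) for (cc in 1:3)
      en <- en - m[r, cc] * (m[r %% 3 + 1, cc] + m[r, cc %% 3 + 1])
    p[c0 + 1] <- exp(-en / temperature)
  }
  p / sum(p)
}

# exact stationary word probability of an edge-emitting hidden Markov
# machine via per-symbol transfer matrices
oracle_word_prob <- function(machine, word) {
  st <- machine$states
  S <- length(st)
  Ts <- lapply(0:(machine$n_observables - 1), function(s) {
    m <- matrix(0, S, S, dimnames = list(st, st))
    e <- machine$edges[machine$edges$symbol == s, ]
    for (i in seq_len(nrow(e)))
      m[e$from[i], e$to[i]] <- m[e$from[i], e$to[i]] + e$prob[i]
    m
  })
  v <- machine$start
  for (s in word) v <- as.numeric(v %*% Ts[[s + 1]])
  sum(v)
}

# likelihood-ratio statistic as 2 * n * KL(empirical || null) by direct
# probability summation (order 0 and 1)
oracle_g_statistic <- function(x, order) {
  n <- length(x)
  w <- order + 2
  tup <- t(vapply(seq_len(n - w + 1), function(i) x[i:(i + w - 1)],
                  integer(w)))
  nt <- nrow(tup)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  joint <- table(key(tup)) / nt
  if (order == 0) {
    p1 <- table(tup[, 1]) / nt
    p2 <- table(tup[, 2]) / nt
    s <- 0
    for (wd in names(joint)) {
      parts <- strsplit(wd, ",")[[1]]
      s <- s + joint[[wd]] *
        log(joint[[wd]] / (p1[[parts[1]]] * p2[[parts[2]]]))
    }
  } else {
    pij <- table(key(tup[, 1:2])) / nt
    pjk <- table(key(tup[, 2:3])) / nt
    pj <- table(tup[, 2]) / nt
    s <- 0
    for (wd in names(joint)) {
      parts <- strsplit(wd, ",")[[1]]
      s <- s + joint[[wd]] *
        log(joint[[wd]] * pj[[parts[2]]] /
            (pij[[paste(parts[1:2], collapse = ",")]] *
             pjk[[paste(parts[2:3], collapse = ",")]]))
    }
  }
  2 * nt * s
}

# short iid uniform symbol sequence helper
iid_seq <- function(n, L, seed) {
  withr::with_seed(seed, symbol_sequence(sample.int(L, n, TRUE) - 1L, L))
}
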