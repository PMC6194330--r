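# Transition-model estimation, surrogate sampling, the two-state closed
# forms, and the shipped higher-order test processes.

test_that("maximum-likelihood estimation recovers deterministic and known chains", {
  m <- estimate_transition_model(c(0, 1, 0, 1, 0, 1, 0, 1), M = 1)
  expect_equal(unname(m$table), matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_identical(m$order, 1L)

  gm <- sample_hmm(golden_mean_2state(), 1e5, seed = 1)
  mg <- estimate_transition_model(gm, 1)
  expect_equal(unname(mg$table), matrix(c(0.5, 0.5, 1, 0), 2, byrow = TRUE),
               tolerance = 0.01)

  # M = 0 reduces to the iid symbol distribution
  m0 <- estimate_transition_model(gm, 0)
  expect_equal(dim(m0$table), c(1L, 2L))
  expect_equal(as.numeric(m0$table), as.numeric(table(as.integer(gm)) / length(gm)),
               tolerance = 1e-6)
})

test_that("transition tables are recovered from samples of a known model", {
  for (s in 1:5) {
    gen <- random_transition_model(2, 2, seed = 20 + s)
    x <- sample_markov(gen, 1e6, seed = 30 + s)
    est <- estimate_transition_model(x, 2)
    expect_lt(max(abs(est$table - gen$table)), 0.01)
  }
  # recovery error shrinks with sample size
  gen <- random_transition_model(2, 2, seed = 40)
  err <- vapply(c(1e4, 1e6), function(N) {
    x <- sample_markov(gen, N, seed = 41)
    max(abs(estimate_transition_model(x, 2)$table - gen$table))
  }, 0)
  expect_gt(err[1], err[2])
})

test_that("sampling is reproducible and matches the stationary structure", {
  mod <- random_transition_model(3, 1, seed = 50)
  expect_identical(as.integer(sample_markov(mod, 500, seed = 51)),
                   as.integer(sample_markov(mod, 500, seed = 51)))
  expect_false(identical(as.integer(sample_markov(mod, 500, seed = 51)),
                         as.integer(sample_markov(mod, 500, seed = 52))))

  # empirical symbol distribution matches the unit-eigenvalue eigenvector
  # of the estimated transition matrix
  x <- sample_markov(mod, 2e5, seed = 53)
  est <- estimate_transition_model(x, 1)$table
  ev <- eigen(t(est))
  v <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
  v <- v / sum(v)
  emp <- as.numeric(table(factor(as.integer(x), levels = 0:2)) / length(x))
  expect_lt(max(abs(emp - v)), 0.01)

  # iid coin sampled through the machinery stays an iid coin
  y <- sample_markov(two_state_model(0.5, 0.5), 5e4, seed = 54)
  expect_equal(mean(as.integer(y)), 0.5, tolerance = 0.02)
  expect_equal(active_information_storage(y, 1), 0, tolerance = 1e-3)
})

test_that("estimate-then-resample round trips preserve the entropy rate", {
  gm <- sample_hmm(golden_mean_2state(), 2e5, seed = 55)
  mod <- estimate_transition_model(gm, 1)
  hs <- vapply(1:10, function(s)
    entropy_rate(sample_markov(mod, 2e5, seed = 60 + s), 1), 0)
  se <- stats::sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - 2 / 3), 3 * se + 1e-3)
})

test_that("unobserved histories are flagged and trigger the sampling fallback", {
  # history (0,1) never occurs, but sampling reaches it from (1,1)
  m <- estimate_transition_model(c(1, 1, 0, 0, 1), M = 2)
  expect_false(all(m$observed))
  expect_true(any(is.na(m$table)))
  expect_message(y <- sample_markov(m, 200, seed = 70), "restart")
  expect_gt(attr(y, "n_fallback"), 0)
  expect_true(all(as.integer(y) %in% 0:1))
})

test_that("two-state closed forms conserve total entropy exactly", {
  an <- two_state_analytics(0.5, 1)
  expect_equal(an$stationary, c(A = 2 / 3, B = 1 / 3))
  expect_equal(an$H, 0.9182958, tolerance = 1e-7)
  expect_equal(an$h, 2 / 3, tolerance = 1e-12)
  expect_equal(an$a, 0.9182958 - 2 / 3, tolerance = 1e-6)
  expect_equal(an$eigenvalues, c(1, -0.5))

  fair <- two_state_analytics(0.5, 0.5)
  expect_equal(c(fair$H, fair$h, fair$a), c(1, 1, 0))

  for (p in c(0.05, 0.3, 0.8, 1)) for (q in c(0.1, 0.5, 0.95)) {
    an <- two_state_analytics(p, q)
    expect_lt(abs(an$H - an$a - an$h), 1e-15)
    expect_true(all(c(an$H, an$h, an$a) >= 0))
    expect_equal(an$eigenvalues[2], 1 - (p + q))
  }
  expect_error(two_state_analytics(0, 0), "positive")
  expect_error(two_state_analytics(1.2, 0.5), "lie in")
})

test_that("random transition models are seeded simplex draws", {
  m1 <- random_transition_model(3, 2, seed = 80)
  m2 <- random_transition_model(3, 2, seed = 80)
  m3 <- random_transition_model(3, 2, seed = 81)
  expect_identical(m1$table, m2$table)
  expect_false(identical(m1$table, m3$table))
  expect_equal(unname(rowSums(m1$table)), rep(1, 9), tolerance = 1e-12)
  expect_true(all(m1$table >= 0 & m1$table <= 1))
  expect_equal(sum(m1$history_distribution), 1, tolerance = 1e-9)
})

test_that("the lag-skipping model depends only on the skipped history symbol", {
  m <- lag_skipping_model(3, seed = 82)
  expect_identical(m$order, 3L)
  codes <- 0:(3^3 - 1)
  oldest <- codes %/% 9
  for (v in 0:2) {
    rows <- m$table[oldest == v, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-15)
  }
  # the conditionals are well separated in total variation
  cond <- m$table[c(1, 10, 19), ]
  tv <- utils::combn(3, 2, function(ij) sum(abs(cond[ij[1], ] - cond[ij[2], ])) / 2)
  expect_true(all(tv >= 0.2))

  # autoinformation of samples has period 3: the peaks at multiples of
  # 3 are significant and dominate the off-period lags by orders of
  # magnitude (off-period lags sit at iid-band level, so an individual
  # lag can touch the band edge)
  x <- sample_markov(m, 2e5, seed = 83)
  a <- aif(x, 9, n_surrogates = 50, seed = 84)
  expect_true(all(a$value[c(4, 7, 10)] > a$ci_high[c(4, 7, 10)]))
  expect_lt(max(a$value[c(2, 3, 5, 6)]), 0.05 * min(a$value[c(4, 7, 10)]))

  # partial autoinformation peaks at lag 3 only
  p <- paif(x, 6, n_surrogates = 50, seed = 85)
  expect_gt(p$value[4], p$ci_high[4])
  expect_true(all(p$value[c(2, 3, 5, 6, 7)] <= p$ci_high[c(2, 3, 5, 6, 7)]))
})

test_that("transition models serialize to text and back", {
  m <- random_transition_model(2, 3, seed = 86)
  tmp <- withr::local_tempfile()
  write_transition_model(m, tmp)
  back <- read_transition_model(tmp)
  expect_identical(back$order, 3L)
  expect_identical(back$n_symbols, 2L)
  expect_equal(back$table, m$table, tolerance = 1e-12)
  expect_equal(back$history_distribution, m$history_distribution,
               tolerance = 1e-12)

  td <- tidy(m)
  expect_identical(nrow(td), 16L)
  expect_identical(glance(m)$n_histories, 8L)
})
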