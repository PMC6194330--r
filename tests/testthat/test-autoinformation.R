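# Autoinformation and partial autoinformation lag profiles, and their
# permutation-surrogate confidence bands.

test_that("autoinformation starts at H_1, normalizes to one, and vanishes for iid data", {
  x <- iid_seq(20000, 3, seed = 1)
  a <- aif(x, max_lag = 20, n_surrogates = 50, seed = 2)
  expect_equal(a$value[1], joint_entropy(x, 1), tolerance = 1e-12)
  inside <- with(a, value[lag >= 1] <= ci_high[lag >= 1])
  expect_gte(mean(inside), 0.85)   # ~95% calibration by construction

  an <- aif(x, max_lag = 5, normalize = TRUE)
  expect_equal(an$value[1], 1)

  # constant sequence: zero information, band collapses to [0, 0]
  cb <- iid_confidence_band(rep(0L, 200), 4, n_symbols = 2,
                            n_surrogates = 30, seed = 3)
  expect_true(all(cb$ci_low == 0 & cb$ci_high == 0))
  expect_error(aif(x, max_lag = length(x)), "max_lag")
})

test_that("golden-mean autoinformation at lag 1 equals the first-order storage closed form", {
  gm <- sample_hmm(golden_mean_2state(), 2e5, seed = 4)
  a <- aif(gm, 3)
  expect_equal(a$value[2], two_state_analytics(0.5, 1)$a, tolerance = 3e-3)
})

test_that("autoinformation is symmetric under time reversal", {
  x <- sample_markov(random_transition_model(3, 2, seed = 5), 5000, seed = 6)
  a1 <- aif(x, 10)
  a2 <- aif(rev(as.integer(x)), 10, n_symbols = 3)
  expect_equal(a1$value, a2$value, tolerance = 1e-12)
})

test_that("partial autoinformation equals direct conditional-MI summation on tiny instances", {
  for (seed in 1:6) {
    x <- if (seed <= 3) iid_seq(60, 2, seed = seed)
         else sample_markov(two_state_model(0.3, 0.5), 55, seed = seed)
    p <- suppressWarnings(paif(x, 3, mode = "marginal"))
    for (k in 2:3)
      expect_equal(p$value[k + 1], oracle_cmi(as.integer(x), k),
                   tolerance = 1e-12)
  }
})

test_that("partial autoinformation obeys the entropy-rate and storage difference identities", {
  gm <- sample_hmm(golden_mean_2state(), 1e5, seed = 7)
  p <- paif(gm, 6)
  Hs <- vapply(1:7, function(k) joint_entropy(gm, k), 0)
  for (k in 2:6) {
    h_diff <- entropy_rate(gm, k - 1) - entropy_rate(gm, k)
    a_diff <- active_information_storage(gm, k) -
      active_information_storage(gm, k - 1)
    # identical shared estimates cancel: agreement to rounding error
    expect_lt(abs(p$value[k + 1] - h_diff), 1e-12)
    expect_lt(abs(p$value[k + 1] - a_diff), 1e-12)
    # pi_k is minus the second difference of the joint entropy sequence
    expect_lt(abs(p$value[k + 1] + (Hs[k + 1] - 2 * Hs[k] + Hs[k - 1])),
              1e-12)
  }
  # marginal mode: each h_j comes from its own (j+1)-history
  # distribution, so the identity holds up to boundary-window
  # discrepancies of order k/N
  pm <- paif(gm, 6, mode = "marginal")
  for (k in 2:6) {
    h_diff <- entropy_rate(gm, k - 1, mode = "marginal") -
      entropy_rate(gm, k, mode = "marginal")
    expect_lt(abs(pm$value[k + 1] - h_diff), 2e-5)
  }
  # conditional MI is non-negative by construction in marginal mode
  expect_true(all(pm$value >= 0))
})

test_that("partial autoinformation vanishes beyond the Markov order", {
  # sampled order-M chains: all coefficients for M < k <= M+3 fall
  # inside the alpha = 0.05 iid band in >= 18 of 20 seeded runs
  ok <- 0L
  for (i in 1:20) {
    M <- ((i - 1) %% 3) + 1
    mod <- random_transition_model(2, M, seed = 300 + i)
    x <- sample_markov(mod, 1e5, seed = 400 + i)
    p <- paif(x, M + 3, n_surrogates = 50, seed = 500 + i)
    ok <- ok + with(p, all(value[lag > M] <= ci_high[lag > M]))
  }
  expect_gte(ok, 18L)
})

test_that("surrogate band width shrinks as the sample grows", {
  widths <- vapply(c(1e4, 1e5), function(N) {
    gm <- sample_hmm(golden_mean_2state(), N, seed = 8)
    b <- iid_confidence_band(gm, 10, statistic = "aif",
                             n_surrogates = 50, seed = 9)
    stats::median(b$ci_high[-1] - b$ci_low[-1])
  }, 0)
  expect_gt(widths[1], widths[2])
})

test_that("partial autoinformation guards its exponential cost", {
  x <- iid_seq(2000, 4, seed = 10)
  expect_warning(paif(x, 6), "undersampl")
  expect_error(paif(iid_seq(100, 4, seed = 11), 15), "hard cap")
})

test_that("lag profiles export, tidy and plot", {
  gm <- sample_hmm(golden_mean_2state(), 5000, seed = 12)
  p <- paif(gm, 4, n_surrogates = 20, seed = 13)
  tmp <- withr::local_tempfile()
  export_profile(p, tmp)
  back <- utils::read.delim(tmp)
  expect_identical(names(back),
                   c("lag", "value", "ci_low", "ci_high", "kind", "normalized"))
  expect_equal(back$value, p$value, tolerance = 1e-12)
  expect_identical(unique(back$kind), "paif")

  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$kind[1], "paif")
  g <- glance(p)
  expect_identical(g$n_lags, 5L)
  expect_s3_class(autoplot(p), "ggplot")
  expect_s3_class(autoplot(aif(gm, 10), log_scale = TRUE), "ggplot")
})
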