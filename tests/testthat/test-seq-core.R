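# Sequence container, k-history bookkeeping and plug-in entropy
# estimators.

test_that("symbol sequences validate their alphabet and support IO round trips", {
  s <- symbol_sequence(c(0, 1, 0, 2), n_symbols = 3)
  expect_s3_class(s, "painf_seq")
  expect_identical(n_symbols(s), 3L)
  expect_identical(n_symbols(symbol_sequence(c(0, 1, 1))), 2L)
  expect_error(symbol_sequence(integer(0)), "at least one")
  expect_error(symbol_sequence(c(0, 1.5)), "integers")
  expect_error(symbol_sequence(c(0, 3), n_symbols = 2), "lie in")

  tmp <- withr::local_tempfile()
  write_symbol_sequence(symbol_sequence(c(0, 3, 1), n_symbols = 5), tmp)
  back <- read_symbol_sequence(tmp)
  expect_identical(as.integer(back), c(0L, 3L, 1L))
  expect_identical(n_symbols(back), 5L)   # from the "# L=5" header

  # single-line delimited layout is autodetected
  writeLines("0, 1 2,1", tmp)
  expect_identical(as.integer(read_symbol_sequence(tmp)), c(0L, 1L, 2L, 1L))

  writeLines(c("0", "oops", "1"), tmp)
  expect_error(read_symbol_sequence(tmp), "line 2")
  writeLines(character(0), tmp)
  expect_error(read_symbol_sequence(tmp), "no data")

  write_numeric_series(c(-1.25, 3.5), tmp)
  expect_equal(read_numeric_series(tmp), c(-1.25, 3.5))
})

test_that("k-history distributions count every window exactly once", {
  d <- suppressWarnings(khistory_distribution(c(0, 1, 0, 1, 0, 1), k = 2))
  expect_identical(attr(d, "total"), 5L)
  expect_identical(d$count[d$history == "1,0"], 3L)
  expect_identical(d$count[d$history == "0,1"], 2L)
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)

  # k = 1 reduces to empirical symbol frequencies
  x <- iid_seq(500, 3, seed = 1)
  d1 <- khistory_distribution(x, 1)
  expect_equal(sort(d1$count), sort(as.integer(table(as.integer(x)))))

  # degenerate constant sequence: a single bin with probability one
  dc <- suppressWarnings(khistory_distribution(rep(0L, 40), 3, n_symbols = 2))
  expect_identical(nrow(dc), 1L)
  expect_equal(dc$probability, 1)

  expect_error(khistory_distribution(c(0, 1), k = 5), "exceed")
  expect_error(khistory_distribution(c(0, 1), k = 0), "positive")
})

test_that("shannon entropy matches hand-computed values", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(2 / 3, 1 / 3)), 0.9182958, tolerance = 1e-7)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("joint entropy equals the brute-force enumeration oracle", {
  for (seed in 1:4) {
    L <- if (seed %% 2) 2L else 3L
    x <- iid_seq(150, L, seed = seed)
    for (k in 1:4)
      expect_equal(suppressWarnings(joint_entropy(x, k)),
                   oracle_joint_entropy(as.integer(x), k),
                   tolerance = 1e-12)
  }
  # and on a correlated sequence
  y <- sample_markov(two_state_model(0.2, 0.7), 200, seed = 5)
  for (k in 1:3)
    expect_equal(joint_entropy(y, k), oracle_joint_entropy(as.integer(y), k),
                 tolerance = 1e-12)
})

test_that("entropy rate and information storage behave on canonical sequences", {
  coin <- iid_seq(20000, 2, seed = 2)
  expect_equal(entropy_rate(coin, 1), 1, tolerance = 0.01)
  expect_equal(entropy_rate(coin, 3), 1, tolerance = 0.01)
  expect_equal(active_information_storage(coin, 2), 0, tolerance = 0.01)

  # fully predictable alternation: zero surprise up to the windowed
  # estimator's boundary effect (the two pair types are counted 300 and
  # 299 times)
  per <- symbol_sequence(rep(c(0L, 1L), 300))
  expect_lt(abs(entropy_rate(per, 1)), 1e-5)
  expect_equal(active_information_storage(per, 1), 1, tolerance = 1e-2)
  expect_equal(suppressWarnings(joint_entropy(rep(1L, 100), 4, n_symbols = 2)), 0)
})

test_that("golden-mean estimates converge to the two-state closed forms", {
  gm <- sample_hmm(golden_mean_2state(), 2e5, seed = 3)
  an <- two_state_analytics(0.5, 1)
  expect_equal(joint_entropy(gm, 1), an$H, tolerance = 3e-3)
  expect_equal(entropy_rate(gm, 1), an$h, tolerance = 3e-3)
  expect_equal(active_information_storage(gm, 1), an$a, tolerance = 3e-3)
  # marginal mode agrees with windowed mode on a long sample
  expect_equal(entropy_rate(gm, 3, mode = "marginal"),
               entropy_rate(gm, 3, mode = "windowed"), tolerance = 1e-3)
})

test_that("entropy conservation holds and the rate decreases with history length", {
  gm <- sample_hmm(golden_mean_2state(), 1e5, seed = 4)
  ep <- entropy_profile(gm, 8)
  expect_lt(max(abs(ep$H[1] - ep$h - ep$a)), 1e-12)
  # marginal mode: a_k + h_k equals the single-symbol entropy of the
  # marginalized (k+1)-history distribution, which tracks H_1 closely
  epm <- entropy_profile(gm, 6, mode = "marginal")
  expect_lt(max(abs(epm$h + epm$a - joint_entropy(gm, 1))), 1e-3)
  # conditioning cannot increase surprise (up to estimator tolerance)
  expect_true(all(diff(ep$h) <= 1e-6))
  expect_true(all(ep$h >= 0 & ep$h <= 1 + 1e-9))
})

test_that("sampled two-state chains recover the closed forms within 3 SE", {
  an <- two_state_analytics(0.3, 0.6)
  est <- vapply(1:20, function(s) {
    x <- sample_markov(two_state_model(0.3, 0.6), 3e4, seed = 100 + s)
    ep <- entropy_profile(x, 1)
    c(ep$H[1], ep$h[1], ep$a[1])
  }, numeric(3))
  for (i in 1:3) {
    truth <- c(an$H, an$h, an$a)[i]
    se <- stats::sd(est[i, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[i, ]) - truth), 3 * se + 1e-4)
  }
})

test_that("undersampling is flagged as a warning, not an error", {
  x <- iid_seq(300, 4, seed = 6)
  expect_warning(joint_entropy(x, 5), "undersampl")
  expect_silent(joint_entropy(x, 2))
})
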