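test_that("response distributions are proper, reproducible and lapse-mixed", {
  cfg <- standard_configurations(1)[[1]]
  ob <- test_observer()
  rd <- response_distribution(c(0.5, 0), cfg, ob, n_mc = 5000, seed = 7)
  expect_equal(dim(rd$table), c(3L, 4L))
  expect_equal(sum(rd$table), 1, tolerance = 1e-10)
  expect_true(all(rd$table >= ob$lapse / 12))

  rd2 <- response_distribution(c(0.5, 0), cfg, ob, n_mc = 5000, seed = 7)
  expect_identical(rd$table, rd2$table)

  ob_lapse <- observer_params("difference",
    sigma = 0.5, alpha = 30,
    criteria = c(0.1, 0.3, 0.6), lapse = 1
  )
  rd_l <- response_distribution(c(0.5, 0), cfg, ob_lapse, n_mc = 100, seed = 1)
  expect_equal(as.vector(rd_l$table), rep(1 / 12, 12))

  expect_error(response_distribution(c(0.5, 0), cfg, ob, n_mc = 0), ">= 1")
})

test_that("Monte-Carlo tables converge with the sample size", {
  cfg <- standard_configurations(1)[[1]]
  ob <- test_observer()
  big <- response_distribution(c(0.8, 0), cfg, ob, n_mc = 1e5, seed = 31)$table
  small <- response_distribution(c(0.8, 0), cfg, ob, n_mc = 1e4, seed = 32)$table
  tol <- 4 * sqrt(big * (1 - big) / 1e4) + 1e-3
  expect_true(all(abs(big - small) <= tol))
})

test_that("log-likelihood handles modes, determinism and degenerate cases", {
  cfg1 <- standard_configurations(1)[[1]]
  ob <- test_observer()
  pos <- withr::with_seed(33, {
    tg <- sample_target(cfg1, 60)
    cbind(tg$x, tg$y)
  })
  d <- dataset_from_positions(pos, cfg1, ob, seed = 34)

  ll1 <- log_likelihood(d, ob, "joint", n_mc = 2000, seed = 5)
  ll2 <- log_likelihood(d, ob, "joint", n_mc = 2000, seed = 5)
  expect_identical(ll1, ll2)

  # marginalization: joint probability never exceeds either marginal
  ll_dec <- log_likelihood(d, ob, "decision_only", n_mc = 2000, seed = 5)
  ll_conf <- log_likelihood(d, ob, "confidence_only", n_mc = 2000, seed = 5)
  expect_lte(ll1, ll_dec)
  expect_lte(ll1, ll_conf)

  # a single pure-lapse trial has joint probability 1/12
  ob_lapse <- observer_params("difference",
    sigma = 0.5, alpha = 30,
    criteria = c(0.1, 0.3, 0.6), lapse = 1
  )
  d1 <- conf_dataset(
    data.frame(
      config = 1L, target_x = 0.3, target_y = 0,
      true_category = NA_integer_,
      response_category = 2L, confidence = 3L
    ),
    subject = "L", experiment = 1L
  )
  expect_equal(log_likelihood(d1, ob_lapse, "joint", n_mc = 50, seed = 1),
    log(1 / 12),
    tolerance = 1e-12
  )
  expect_equal(
    log_likelihood(d1, ob_lapse, "confidence_only", n_mc = 50, seed = 1),
    log(1 / 4),
    tolerance = 1e-12
  )

  expect_error(
    conf_dataset(d1[0, ], subject = "E", experiment = 1L),
    "no trials"
  )
})

test_that("the likelihood prefers the generating parameters over gross distortions", {
  cfg <- standard_configurations(1)[[1]]
  ob <- test_observer(sigma = 0.5, alpha = 30)
  wins_sigma <- 0L
  wins_alpha <- 0L
  n_rep <- 5L
  for (r in seq_len(n_rep)) {
    pos <- withr::with_seed(40 + r, {
      tg <- sample_target(cfg, 500)
      cbind(tg$x, tg$y)
    })
    d <- dataset_from_positions(pos, cfg, ob, seed = 50 + r)
    ll_true <- log_likelihood(d, ob, n_mc = 1000, seed = 60 + r)
    ob_s <- observer_params(ob$rule, 2 * ob$sigma, ob$alpha, ob$criteria, ob$lapse)
    ob_a <- observer_params(ob$rule, ob$sigma, ob$alpha / 6, ob$criteria, ob$lapse)
    wins_sigma <- wins_sigma + (ll_true > log_likelihood(d, ob_s, n_mc = 1000, seed = 60 + r))
    wins_alpha <- wins_alpha + (ll_true > log_likelihood(d, ob_a, n_mc = 1000, seed = 60 + r))
  }
  expect_gte(wins_sigma, 4L)
  expect_gte(wins_alpha, 4L)
})

test_that("fitting bookkeeping: free-parameter counts and criteria arithmetic", {
  cfg <- standard_configurations(1)[[1]]
  ob <- test_observer()
  pos <- withr::with_seed(70, {
    tg <- sample_target(cfg, 80)
    cbind(tg$x, tg$y)
  })
  d <- dataset_from_positions(pos, cfg, ob, seed = 71)
  light <- list(
    n_mc = 300, n_mc_search = 200, restarts = 1, n_start = 4,
    maxit = 6, maxit_polish = 3
  )
  f_full <- do.call(fit_subject, c(list(d, "difference", seed = 72), light))
  f_sen <- do.call(fit_subject, c(list(d, "difference", noise = "sensory", seed = 72), light))
  f_dec <- do.call(fit_subject, c(list(d, "difference", noise = "decision", seed = 72), light))
  expect_equal(f_full$k, 6L)
  expect_equal(f_sen$k, 5L)
  expect_equal(f_dec$k, 5L)
  expect_true(is.infinite(f_sen$params$alpha))
  expect_equal(f_dec$params$sigma, 0)
  for (f in list(f_full, f_sen, f_dec)) {
    expect_equal(f$AIC, -2 * f$logL + 2 * f$k)
    expect_equal(f$BIC, -2 * f$logL + f$k * log(f$n))
    b <- f$params$criteria
    expect_true(b[1] < b[2] && b[2] < b[3])
    # reported logL is reproducible through the public likelihood
    expect_equal(
      f$logL,
      log_likelihood(d, f$params, f$mode, n_mc = f$diagnostics$n_mc, seed = 72),
      tolerance = 1e-8
    )
  }
})

test_that("a pure-lapse dataset is fitted with a high lapse rate", {
  cfg <- standard_configurations(1)[[1]]
  ob_lapse <- observer_params("difference",
    sigma = 0.5, alpha = 30,
    criteria = c(0.1, 0.3, 0.6), lapse = 1
  )
  # consistency is asymptotic: with few trials the five structural parameters
  # can soak up sampling noise, so use a session-and-a-half's worth of trials
  pos <- withr::with_seed(80, {
    tg <- sample_target(cfg, 1500)
    cbind(tg$x, tg$y)
  })
  d <- dataset_from_positions(pos, cfg, ob_lapse, seed = 81)
  f <- fit_subject(d, "difference",
    n_mc = 500, n_mc_search = 400,
    restarts = 1, n_start = 6, maxit = 12, maxit_polish = 6, seed = 82
  )
  expect_gte(f$params$lapse, 0.9)
})
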