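test_that("posterior matches direct evaluation and is numerically stable", {
  cfg <- standard_configurations(1)[[1]]
  # at the central mean with sigma = 0: flankers get exp(-9/8)/(1 + 2 exp(-9/8))
  flank <- exp(-9 / 8) / (1 + 2 * exp(-9 / 8))
  p <- compute_posterior(c(0, 0), cfg, sigma = 0)
  expect_equal(p, c(flank, 1 - 2 * flank, flank), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.1968, 0.6063, 0.1968))

  # equidistant from all three means -> uniform posterior
  eq <- category_config(
    2, 1, 2 * cbind(cos(c(90, 210, 330) * pi / 180), sin(c(90, 210, 330) * pi / 180)),
    sd = 2
  )
  expect_equal(compute_posterior(c(0, 0), eq, sigma = 0.7), rep(1 / 3, 3))

  # extreme measurements stay finite and saturate
  p_far <- compute_posterior(c(-100, 0), cfg, sigma = 0)
  expect_true(all(is.finite(p_far)))
  expect_equal(p_far[1], 1, tolerance = 1e-10)

  # vectorized input keeps rows on the simplex
  pm <- compute_posterior(cbind(runif(50, -5, 5), runif(50, -5, 5)), cfg, 0.5)
  expect_equal(rowSums(pm), rep(1, 50))
  expect_true(all(pm >= 0))

  expect_error(compute_posterior(c(NA, 0), cfg, 0.5), "non-finite")
  expect_error(compute_posterior(c(0, 0), cfg, -1), ">= 0")
})

test_that("Dirichlet decision noise has the stated moments and limits", {
  p <- c(0.5, 0.3, 0.2)
  # infinite concentration returns the posterior unchanged
  expect_identical(sample_noisy_posterior(p, Inf), p)
  q <- withr::with_seed(21, sample_noisy_posterior(p, 50, n = 1e5))
  expect_equal(rowSums(q), rep(1, 1e5))
  for (i in 1:3) {
    se_mean <- sqrt(p[i] * (1 - p[i]) / 51 / 1e5)
    expect_lt(abs(mean(q[, i]) - p[i]), 4 * se_mean)
    v_true <- p[i] * (1 - p[i]) / 51
    m4 <- mean((q[, i] - mean(q[, i]))^4)
    se_var <- sqrt(max(m4 - v_true^2, 0) / 1e5)
    expect_lt(abs(var(q[, i]) - v_true), 5 * se_var)
  }
  # degenerate posteriors are clamped, not rejected
  q0 <- withr::with_seed(22, sample_noisy_posterior(c(1, 0, 0), 10, n = 1e4))
  expect_true(all(is.finite(q0)))
  expect_gt(mean(q0[, 1]), 0.99)
  expect_error(sample_noisy_posterior(p, 0), "> 0")
  expect_error(sample_noisy_posterior(c(0.5, 0.5, 0.5), 10), "simplex")
})

test_that("decisions take the argmax with uniform tie-breaking", {
  expect_identical(decide(c(0.2, 0.5, 0.3)), 2L)
  expect_identical(decide(c(0.999, 0.0005, 0.0005)), 1L)
  picks <- withr::with_seed(23, decide(matrix(1 / 3, nrow = 6000, ncol = 3)))
  freq <- tabulate(picks, 3L) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  # two-way tie never picks the excluded category
  two <- withr::with_seed(24, decide(matrix(c(0.4, 0.4, 0.2), 1000, 3, byrow = TRUE)))
  expect_true(all(two %in% 1:2))
  expect_true(all(tabulate(two, 2L) > 400))
})

test_that("confidence variables match their definitions and ranges", {
  q <- c(0.6, 0.3, 0.1)
  expect_equal(confidence_variable(q, rule = "max"), 0.6)
  expect_equal(confidence_variable(q, rule = "difference"), 0.3)
  expect_equal(confidence_variable(q, rule = "entropy"),
    sum(q * log(q)),
    tolerance = 1e-12
  )
  expect_equal(round(confidence_variable(q, rule = "entropy"), 4), -0.8979)
  expect_equal(confidence_variable(q, rule = "ratio"), 0.6 / 0.9)

  # uniform-posterior floor
  u <- rep(1 / 3, 3)
  expect_equal(confidence_variable(u, rule = "max"), 1 / 3)
  expect_equal(confidence_variable(u, rule = "difference"), 0)
  expect_equal(confidence_variable(u, rule = "entropy"), -log(3))

  qs <- random_simplex(500, seed = 25)
  for (rule in c("max", "difference", "entropy", "ratio")) {
    rng <- rule_range(rule)
    cs <- confidence_variable(qs, rule = rule)
    expect_true(all(cs >= rng[1] - 1e-12 & cs <= rng[2] + 1e-12))
  }
  expect_error(confidence_variable(q, rule = "median"), "arg")
})

test_that("averaged balance-of-evidence is affine in the Max variable", {
  # with chosen component A: ((A - B) + (A - C)) / 2 = (3 A - 1) / 2
  qs <- random_simplex(200, seed = 26)
  a <- apply(qs, 1, max)
  boe <- apply(qs, 1, function(q) {
    s <- sort(q, decreasing = TRUE)
    ((s[1] - s[2]) + (s[1] - s[3])) / 2
  })
  expect_equal(boe, (3 * a - 1) / 2, tolerance = 1e-12)
})

test_that("criteria map the confidence variable to ratings monotonically", {
  b <- c(0.4, 0.55, 0.8)
  expect_identical(rate_confidence(0.5, b), 2L)
  expect_identical(rate_confidence(0.2, b), 1L)
  expect_identical(rate_confidence(0.95, b), 4L)
  # boundary equality resolves to the lower rating
  expect_identical(rate_confidence(0.55, b), 2L)
  cs <- sort(runif(200))
  expect_true(all(diff(rate_confidence(cs, b)) >= 0))
  expect_error(rate_confidence(0.5, c(0.5, 0.4, 0.8)), "increasing")
})

test_that("lapse trials are uniform over the 12 response cells", {
  cfg <- standard_configurations(1)[[1]]
  ob <- observer_params("difference",
    sigma = 0.5, alpha = 30,
    criteria = c(0.1, 0.3, 0.6), lapse = 1
  )
  resp <- withr::with_seed(27, simulate_response(
    matrix(c(0.5, 0), 6e4, 2, byrow = TRUE), cfg, ob
  ))
  counts <- table(factor(resp$category, 1:3), factor(resp$rating, 1:4))
  gof <- stats::chisq.test(as.vector(counts), p = rep(1 / 12, 12))
  expect_gt(gof$p.value, 0.001)
})

test_that("the noiseless observer responds deterministically", {
  cfg <- standard_configurations(1)[[1]]
  ob <- observer_params("max",
    sigma = 0, alpha = Inf,
    criteria = c(0.4, 0.5, 0.6), lapse = 0
  )
  resp <- withr::with_seed(28, simulate_response(
    matrix(c(-6, 0), 50, 2, byrow = TRUE), cfg, ob
  ))
  expect_true(all(resp$category == 1L))
  expect_true(all(resp$rating == 4L)) # posterior of category 1 is ~1 out there
})

test_that("decision noise alone makes repeated responses stochastic", {
  cfg <- standard_configurations(1)[[1]]
  ob <- observer_params("difference",
    sigma = 0, alpha = 5,
    criteria = c(0.1, 0.3, 0.6), lapse = 0, noise = "decision"
  )
  resp <- withr::with_seed(29, simulate_response(
    matrix(c(1.5, 0), 500, 2, byrow = TRUE), cfg, ob
  ))
  expect_gt(length(unique(resp$category)), 1L)
  expect_gt(length(unique(resp$rating)), 1L)
})
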