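# Shared fixtures and independent oracles for the test suite.

# Standard test observer: criteria calibrated at quartiles of the simulated
# confidence-variable distribution (seeded so fixtures are reproducible).
test_observer <- function(rule = "difference", sigma = 0.5, alpha = 30,
                          lapse = 0.02, experiment = 1L, crit_seed = 1L,
                          noise = "both") {
  crit <- withr::with_seed(crit_seed, calibrate_criteria(rule, sigma, alpha, experiment))
  observer_params(
    rule = rule, sigma = sigma, alpha = alpha,
    criteria = crit, lapse = lapse, noise = noise
  )
}

# Independent random simplex points (for range/identity properties).
random_simplex <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(3L * n, shape = 1), ncol = 3L)
    g / rowSums(g)
  })
}

# Quadrature oracle for the no-decision-noise, no-lapse response
# distribution: integrates the deterministic readout over the Gaussian
# measurement density on a fine 1-D grid (valid for designs whose category
# centers share one vertical position, where the vertical measurement
# coordinate cancels in the posterior).
#
# Implemented from the model definition directly -- it shares no code with
# the package's Monte-Carlo path.
quadrature_response_dist <- function(s, config, sigma, rule, criteria,
                                     step = 0.002, halfwidth = 8) {
  stopifnot(all(config$means[, 2] == config$means[1, 2]))
  v <- config$sd^2 + sigma^2
  xg <- seq(s[1] - halfwidth * sigma, s[1] + halfwidth * sigma, by = step)
  w <- stats::dnorm(xg, s[1], sigma)
  w <- w / sum(w)
  tab <- matrix(0, 3, 4)
  lik <- sapply(1:3, function(k) stats::dnorm(xg, config$means[k, 1], sqrt(v)))
  post <- lik / rowSums(lik)
  for (i in seq_along(xg)) {
    p <- post[i, ]
    chat <- which.max(p)
    ps <- sort(p, decreasing = TRUE)
    cstar <- switch(rule,
      max = ps[1],
      difference = ps[1] - ps[2],
      entropy = sum(ifelse(p > 0, p * log(p), 0)),
      ratio = ps[1] / (ps[1] + ps[2])
    )
    rating <- 1L + sum(cstar > criteria)
    tab[chat, rating] <- tab[chat, rating] + w[i]
  }
  tab
}

# Trials at externally chosen positions wrapped as a conf_dataset.
dataset_from_positions <- function(pos, config, params, subject = "T01",
                                   experiment = 1L, seed = 1L) {
  resp <- withr::with_seed(seed, simulate_response(pos, config, params))
  conf_dataset(
    data.frame(
      config = config$config,
      target_x = pos[, 1], target_y = pos[, 2],
      true_category = NA_integer_,
      response_category = resp$category,
      confidence = resp$rating
    ),
    subject = subject, experiment = experiment
  )
}
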