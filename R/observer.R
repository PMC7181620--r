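# The generative observer: sensory measurement, posterior over categories,
# Dirichlet decision noise, MAP decision, confidence read-out, rating, lapse.

.rules <- c("max", "difference", "entropy", "ratio")
.noise_variants <- c("both", "sensory", "decision")

# Smallest lapse rate allowed during fitting: keeps every response cell's
# probability >= lapse/12 > 0 so the log-likelihood is always finite.
.lapse_min <- 1e-4

# Components of the true posterior below this are clamped (then renormalized)
# before Dirichlet sampling, keeping every concentration parameter positive.
.posterior_clamp <- 1e-6

#' Native range of a confidence rule's internal variable
#'
#' The internal confidence variable c* of each read-out rule lives on its
#' own scale: Max on \[1/3, 1\], Difference on \[0, 1\], Entropy (negative
#' entropy, natural log) on \[-log 3, 0\], Ratio (top-two renormalized
#' posterior) on \[1/2, 1\]. Confidence criteria are placed on this native
#' scale.
#'
#' @param rule one of `"max"`, `"difference"`, `"entropy"`, `"ratio"`.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
rule_range <- function(rule) {
  rule <- match.arg(rule, .rules)
  switch(rule,
    max = c(1 / 3, 1),
    difference = c(0, 1),
    entropy = c(-log(3), 0),
    ratio = c(0.5, 1)
  )
}

#' Observer parameters
#'
#' Bundles the parameters of one observer model: sensory noise SD `sigma`
#' (degrees), Dirichlet concentration `alpha` (larger = less decision
#' noise; `Inf` = none), three ordered confidence criteria on the rule's
#' native c* scale, a lapse rate, the confidence read-out rule, and the
#' noise variant. The `"sensory"` variant fixes `alpha = Inf`; the
#' `"decision"` variant fixes `sigma = 0`.
#'
#' @param rule confidence read-out rule: `"max"`, `"difference"`,
#'   `"entropy"` or `"ratio"`.
#' @param sigma sensory noise SD in degrees, >= 0.
#' @param alpha Dirichlet concentration parameter, > 0 or `Inf`.
#' @param criteria numeric length-3, strictly increasing, on the rule's
#'   native scale (see [rule_range()]).
#' @param lapse lapse rate in \[0, 1\]: probability of a trial on which both
#'   the category button and the rating are pressed uniformly at random.
#' @param noise noise variant: `"both"`, `"sensory"` (no decision noise) or
#'   `"decision"` (no sensory noise).
#'
#' @return An object of class `conf_observer`.
#' @export
observer_params <- function(rule, sigma = 0.5, alpha = 30, criteria,
                            lapse = 0.02,
                            noise = c("both", "sensory", "decision")) {
  rule <- match.arg(rule, .rules)
  noise <- match.arg(noise)
  if (noise == "sensory") alpha <- Inf
  if (noise == "decision") sigma <- 0
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop_triconf("`sigma` must be a single number >= 0")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop_triconf("`alpha` must be > 0 (possibly Inf)")
  }
  if (noise == "both" && !is.finite(alpha)) noise <- "sensory"
  criteria <- as.numeric(criteria)
  if (length(criteria) != 3L || any(!is.finite(criteria)) ||
      any(diff(criteria) <= 0)) {
    stop_triconf("`criteria` must be three finite, strictly increasing values")
  }
  if (!is_scalar_number(lapse) || lapse < 0 || lapse > 1) {
    stop_triconf("`lapse` must be in [0, 1]")
  }
  structure(
    list(
      rule = rule, noise = noise,
      sigma = as.numeric(sigma), alpha = as.numeric(alpha),
      criteria = criteria, lapse = as.numeric(lapse)
    ),
    class = "conf_observer"
  )
}

#' @export
print.conf_observer <- function(x, ...) {
  cat(sprintf(
    "<conf_observer> %s rule, %s noise\n  sigma = %g deg, alpha = %g, lapse = %g\n  criteria = (%s)\n",
    x$rule, x$noise, x$sigma, x$alpha, x$lapse,
    paste(signif(x$criteria, 4), collapse = ", ")
  ))
  invisible(x)
}

# Number of free parameters under fitting: 6 for the full model, 5 when one
# noise source is removed.
n_free_params <- function(noise) if (noise == "both") 6L else 5L

#' Posterior over the three categories given a measurement
#'
#' Computes p(C | x) for measurement point(s) x under equal category priors:
#' p(C | x) is proportional to exp(-||x - m_C||^2 / (2 (sigma_s^2 +
#' sigma^2))), normalized over the three categories (log-sum-exp, stable for
#' arbitrarily distant measurements).
#'
#' @param x a length-2 (x, y) point or an n x 2 matrix of points (degrees).
#' @param config a [category_config()].
#' @param sigma sensory noise SD in degrees, >= 0.
#'
#' @return A length-3 probability vector for a single point, otherwise an
#'   n x 3 matrix with rows on the simplex.
#' @export
#'
#' @examples
#' cfg <- standard_configurations(1)[[1]]
#' compute_posterior(c(0, 0), cfg, sigma = 0)
compute_posterior <- function(x, config, sigma) {
  stopifnot(inherits(config, "conf_config"))
  if (!is_scalar_number(sigma) || sigma < 0) {
    stop_triconf("`sigma` must be a single number >= 0")
  }
  single <- is.null(dim(x)) && !is.data.frame(x)
  xm <- as_position_matrix(x)
  v <- config$sd^2 + sigma^2
  d2 <- vapply(1:3, function(k) {
    (xm[, 1] - config$means[k, 1])^2 + (xm[, 2] - config$means[k, 2])^2
  }, numeric(nrow(xm)))
  d2 <- matrix(d2, ncol = 3L)
  loglik <- -d2 / (2 * v)
  m <- apply(loglik, 1L, max)
  w <- exp(loglik - m)
  p <- w / rowSums(w)
  if (single) p[1L, ] else p
}

#' Draw noisy posteriors from a Dirichlet around the true posterior
#'
#' Decision ("late") noise corrupts the true posterior p into q ~
#' Dirichlet(alpha * p), whose expected value is p and whose component
#' variances are p_i (1 - p_i) / (alpha + 1). `alpha = Inf` returns p
#' unchanged. Components of p below 1e-6 are clamped to 1e-6 (and p
#' renormalized) so every Dirichlet shape parameter stays positive.
#' Uses the current RNG state.
#'
#' @param p a length-3 probability vector on the simplex.
#' @param alpha Dirichlet concentration, > 0 or `Inf`.
#' @param n number of draws.
#'
#' @return A length-3 vector if `n = 1`, otherwise an n x 3 matrix.
#' @export
sample_noisy_posterior <- function(p, alpha, n = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop_triconf("`alpha` must be > 0 (possibly Inf)")
  }
  p <- drop(check_simplex(p))
  if (!is.null(dim(p))) stop_triconf("`p` must be a single posterior triple")
  n <- as.integer(n)
  if (!is.finite(alpha)) {
    out <- matrix(p, nrow = n, ncol = 3L, byrow = TRUE)
    return(if (n == 1L) out[1L, ] else out)
  }
  pc <- pmax(p, .posterior_clamp)
  pc <- pc / sum(pc)
  g <- matrix(rgamma(3L * n, shape = rep(alpha * pc, each = n), rate = 1),
    nrow = n
  )
  s <- rowSums(g)
  bad <- s <= 0 | !is.finite(s)
  if (any(bad)) {
    # all-zero underflow (possible only for minuscule shapes): fall back to p
    g[bad, ] <- matrix(pc, nrow = sum(bad), ncol = 3L, byrow = TRUE)
    s[bad] <- 1
  }
  q <- g / s
  if (n == 1L) q[1L, ] else q
}

#' Category decision from a (noisy) posterior
#'
#' The observer reports the category with the highest posterior component.
#' Exact ties are broken uniformly at random (they have measure zero once
#' any noise is present, but occur in noiseless reduced models).
#'
#' @param q a length-3 posterior or an n x 3 matrix of posteriors.
#' @return Integer vector of chosen categories in 1--3.
#' @export
decide <- function(q) {
  q <- as_posterior_matrix(q)
  n <- nrow(q)
  mx <- pmax(q[, 1], q[, 2], q[, 3])
  tied <- (q == mx)
  ntied <- rowSums(tied)
  out <- max.col(q, ties.method = "first")
  multi <- which(ntied > 1L)
  for (i in multi) {
    cand <- which(tied[i, ])
    out[i] <- cand[sample.int(length(cand), 1L)]
  }
  out
}

#' Internal confidence variable read out from a posterior
#'
#' Maps a posterior q (with chosen category, by default its argmax) to the
#' scalar confidence variable of the given rule: the largest component
#' (Max); the gap between the largest and second-largest components
#' (Difference); the negative entropy sum q log q, natural log, with
#' 0 log 0 = 0 (Entropy); or the two-way renormalized top-two posterior
#' q(1) / (q(1) + q(2)) (Ratio), a strictly monotone transform of the
#' likelihood ratio between the top two options.
#'
#' @param q a length-3 posterior or an n x 3 matrix.
#' @param chosen chosen category per row (defaults to the argmax; ties
#'   resolved as in [decide()]).
#' @param rule confidence rule name.
#' @return Numeric vector of c* values on the rule's native scale.
#' @export
#'
#' @examples
#' confidence_variable(c(0.6, 0.3, 0.1), rule = "difference")  # 0.3
confidence_variable <- function(q, chosen = NULL, rule) {
  rule <- match.arg(rule, .rules)
  q <- as_posterior_matrix(q)
  if (rule == "entropy") {
    lq <- ifelse(q > 0, log(q), 0)
    return(rowSums(q * lq))
  }
  q1 <- pmax(q[, 1], q[, 2], q[, 3])
  q3 <- pmin(q[, 1], q[, 2], q[, 3])
  q2 <- rowSums(q) - q1 - q3
  switch(rule,
    max = q1,
    difference = q1 - q2,
    ratio = q1 / (q1 + q2)
  )
}

#' Map a confidence variable to a four-point rating
#'
#' Applies the three ordered criteria: the rating is `1 + #\{i : c* > b_i\}`,
#' so e.g. a c* strictly between b2 and b3 yields rating 3. Equality with a
#' criterion resolves to the lower rating (a measure-zero event under
#' noise).
#'
#' @param c_star numeric vector of confidence-variable values.
#' @param criteria three strictly increasing criteria on the same scale.
#' @return Integer ratings in 1--4.
#' @export
rate_confidence <- function(c_star, criteria) {
  criteria <- as.numeric(criteria)
  if (length(criteria) != 3L || any(diff(criteria) <= 0)) {
    stop_triconf("`criteria` must be three strictly increasing values")
  }
  1L + (c_star > criteria[1]) + (c_star > criteria[2]) + (c_star > criteria[3])
}

#' Simulate behavioral responses at given target positions
#'
#' Runs the full generative observer once per target: with probability
#' `lapse` the trial is a lapse (category and rating both uniform,
#' independent); otherwise a measurement x ~ Normal(s, sigma^2 I) is drawn
#' (x = s when sigma = 0), the posterior computed, Dirichlet decision noise
#' applied, the MAP category chosen, and the confidence variable rated
#' against the criteria. Uses the current RNG state.
#'
#' @param s a length-2 target position or an n x 2 matrix of positions.
#' @param config a [category_config()].
#' @param params an [observer_params()].
#'
#' @return A data frame with columns `category` (1--3) and `rating` (1--4),
#'   one row per target.
#' @export
simulate_response <- function(s, config, params) {
  stopifnot(inherits(config, "conf_config"), inherits(params, "conf_observer"))
  s <- as_position_matrix(s, "s")
  n <- nrow(s)
  category <- integer(n)
  rating <- integer(n)

  is_lapse <- runif(n) < params$lapse
  n_lapse <- sum(is_lapse)
  if (n_lapse > 0L) {
    category[is_lapse] <- sample.int(3L, n_lapse, replace = TRUE)
    rating[is_lapse] <- sample.int(4L, n_lapse, replace = TRUE)
  }
  idx <- which(!is_lapse)
  if (length(idx) > 0L) {
    x <- s[idx, , drop = FALSE]
    if (params$sigma > 0) {
      x <- x + matrix(rnorm(2L * length(idx), 0, params$sigma), ncol = 2L)
    }
    p <- compute_posterior(x, config, params$sigma)
    p <- matrix(p, ncol = 3L)
    if (is.finite(params$alpha)) {
      pc <- pmax(p, .posterior_clamp)
      pc <- pc / rowSums(pc)
      g <- matrix(
        rgamma(3L * length(idx), shape = as.vector(params$alpha * pc), rate = 1),
        ncol = 3L
      )
      ssum <- rowSums(g)
      bad <- ssum <= 0 | !is.finite(ssum)
      if (any(bad)) {
        g[bad, ] <- pc[bad, , drop = FALSE]
        ssum[bad] <- 1
      }
      q <- g / ssum
    } else {
      q <- p
    }
    chat <- decide(q)
    cstar <- confidence_variable(q, chat, params$rule)
    category[idx] <- chat
    rating[idx] <- rate_confidence(cstar, params$criteria)
  }
  data.frame(category = category, rating = rating)
}

#' Place confidence criteria at quartiles of the simulated c* distribution
#'
#' Simulates the observer's confidence variable on targets drawn from the
#' experiment design and returns its 25/50/75% quantiles. Used by the
#' synthetic-data generator so that all four ratings occur with nonzero
#' frequency regardless of rule and noise level.
#'
#' @param rule,sigma,alpha observer settings (see [observer_params()]).
#' @param experiment experiment id whose designs supply target positions.
#' @param n number of simulated trials used for calibration.
#' @return Numeric length-3 criteria on the rule's native scale.
#' @export
calibrate_criteria <- function(rule, sigma, alpha, experiment = 1L, n = 2000L) {
  rule <- match.arg(rule, .rules)
  configs <- standard_configurations(experiment)
  per <- ceiling(n / length(configs))
  cstar <- unlist(lapply(configs, function(cfg) {
    s <- sample_target(cfg, per)
    x <- cbind(s$x, s$y)
    if (sigma > 0) x <- x + matrix(rnorm(2L * per, 0, sigma), ncol = 2L)
    p <- compute_posterior(x, cfg, sigma)
    q <- if (is.finite(alpha)) {
      t(apply(p, 1L, function(pi) sample_noisy_posterior(pi, alpha)))
    } else {
      p
    }
    confidence_variable(q, rule = rule)
  }))
  b <- unname(quantile(cstar, c(0.25, 0.5, 0.75), type = 8))
  # guard against degenerate quantiles (e.g. noiseless observers)
  rng <- rule_range(rule)
  eps <- 1e-6 * diff(rng)
  for (k in 2:3) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + eps
  b
}
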