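# Monte-Carlo response probabilities and the dataset log-likelihood.

#' Monte-Carlo response distribution at one target position
#'
#' Estimates the joint distribution p(category, rating | s) of the observer's
#' responses at target position `s` by simulating `n_mc` measurements (each
#' passed through posterior, Dirichlet decision noise, MAP decision and
#' confidence rating) and then mixing in the lapse distribution:
#' `(1 - lapse) * table + lapse / 12`. A fixed seed makes the table
#' bit-reproducible. With `sigma = 0` the measurement stage collapses to
#' x = s (Dirichlet draws still vary); with `alpha = Inf` and `sigma = 0`
#' the table is deterministic.
#'
#' @param s target position, length-2 (x, y) in degrees.
#' @param config a [category_config()].
#' @param params an [observer_params()].
#' @param n_mc number of simulated measurements (default 10,000).
#' @param seed RNG seed for the simulation.
#'
#' @return An object of class `conf_response_dist` with elements `table`
#'   (3 x 4 matrix over categories x ratings), `s`, `n_mc`, `seed`, `params`.
#' @export
response_distribution <- function(s, config, params, n_mc = 10000L, seed = 1L) {
  stopifnot(inherits(config, "conf_config"), inherits(params, "conf_observer"))
  n_mc <- as.integer(n_mc)
  if (n_mc < 1L) stop_triconf("`n_mc` must be >= 1")
  pos <- as_position_matrix(s, "s")
  if (nrow(pos) != 1L) stop_triconf("`s` must be a single position")
  raw <- with_seed(seed, response_tables_cpp(
    pos, config$means, config$sd, params$sigma, params$alpha,
    rule_code(params$rule), params$criteria, n_mc
  ))
  tab <- (1 - params$lapse) * matrix(raw[1L, ], nrow = 3L) + params$lapse / 12
  dimnames(tab) <- list(
    category = as.character(1:3),
    rating = as.character(1:4)
  )
  structure(
    list(table = tab, s = drop(pos), n_mc = n_mc, seed = seed, params = params),
    class = "conf_response_dist"
  )
}

#' @export
print.conf_response_dist <- function(x, ...) {
  cat(sprintf(
    "<conf_response_dist> at s = (%.3f, %.3f), n_mc = %d, seed = %d\n",
    x$s[1], x$s[2], x$n_mc, x$seed
  ))
  print(round(x$table, 4))
  invisible(x)
}

rule_code <- function(rule) {
  match(match.arg(rule, .rules), .rules)
}

# Non-lapse response tables for a block of positions belonging to one
# configuration, as a k x 12 matrix with cell column (rating - 1) * 3 +
# category. Reseeded per call so identical (theta, seed) give identical
# tables (common random numbers for the sensory stage).
config_tables <- function(pos, config, params, n_mc, seed) {
  raw <- with_seed(seed, response_tables_cpp(
    pos, config$means, config$sd, params$sigma, params$alpha,
    rule_code(params$rule), params$criteria, as.integer(n_mc)
  ))
  (1 - params$lapse) * raw + params$lapse / 12
}

#' Log-likelihood of a dataset under an observer model
#'
#' Sums, over conditionally independent trials, the log response probability
#' obtained from the Monte-Carlo response distribution at that trial's
#' target position. `mode = "joint"` uses the joint cell p(category, rating);
#' `"confidence_only"` uses the rating marginal; `"decision_only"` uses the
#' category marginal. The Monte-Carlo tables are reseeded identically on
#' every call, so the log-likelihood is a deterministic function of the
#' parameters given `seed` -- the property the derivative-free optimizer in
#' [fit_subject()] relies on.
#'
#' @param dataset a [conf_dataset()].
#' @param params an [observer_params()]; its lapse is floored at 1e-4 here so
#'   every response cell has positive probability.
#' @param mode `"joint"`, `"confidence_only"` or `"decision_only"`.
#' @param n_mc Monte-Carlo measurements per target position (default 10,000).
#' @param seed base RNG seed (one derived seed per configuration).
#'
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params,
                           mode = c("joint", "confidence_only", "decision_only"),
                           n_mc = 10000L, seed = 1L) {
  stopifnot(inherits(dataset, "conf_dataset"), inherits(params, "conf_observer"))
  mode <- match.arg(mode)
  if (nrow(dataset) == 0L) stop_triconf("empty dataset")
  experiment <- dataset$experiment[1]
  configs <- standard_configurations(experiment)
  if (!all(dataset$config %in% seq_along(configs))) {
    stop_triconf("dataset references an unknown configuration")
  }
  if (params$lapse < .lapse_min) params$lapse <- .lapse_min
  ll <- 0
  for (cid in sort(unique(dataset$config))) {
    rows <- dataset$config == cid
    pos <- cbind(dataset$target_x[rows], dataset$target_y[rows])
    tab <- config_tables(pos, configs[[cid]], params, n_mc, seed + cid)
    cat_i <- dataset$response_category[rows]
    conf_i <- dataset$confidence[rows]
    pr <- switch(mode,
      joint = tab[cbind(seq_len(nrow(tab)), (conf_i - 1L) * 3L + cat_i)],
      confidence_only = {
        # rating marginal: sum over the 3 categories of that rating
        idx0 <- (conf_i - 1L) * 3L
        tab[cbind(seq_len(nrow(tab)), idx0 + 1L)] +
          tab[cbind(seq_len(nrow(tab)), idx0 + 2L)] +
          tab[cbind(seq_len(nrow(tab)), idx0 + 3L)]
      },
      decision_only = {
        # category marginal: sum over the 4 ratings of that category
        tab[cbind(seq_len(nrow(tab)), cat_i)] +
          tab[cbind(seq_len(nrow(tab)), 3L + cat_i)] +
          tab[cbind(seq_len(nrow(tab)), 6L + cat_i)] +
          tab[cbind(seq_len(nrow(tab)), 9L + cat_i)]
      }
    )
    ll <- ll + sum(log(pr))
  }
  ll
}
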