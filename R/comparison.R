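# Model comparison: information criteria, bootstrapped group-summed AIC
# differences, and the model-recovery analysis.

#' AIC and BIC of a fit
#'
#' Computes `AIC = -2 logL + 2 k` and `BIC = -2 logL + k log n` from a fit's
#' maximized log-likelihood, free-parameter count and trial count.
#'
#' @param fit a `conf_fit` from [fit_subject()], or any list carrying
#'   `logL`, `k` and `n`.
#' @return Named numeric vector `c(AIC = ..., BIC = ...)`.
#' @export
information_criteria <- function(fit) {
  if (!all(c("logL", "k", "n") %in% names(fit))) {
    stop_triconf("`fit` must carry logL, k and n")
  }
  if (fit$n <= 0) stop_triconf("`n` must be positive")
  c(AIC = -2 * fit$logL + 2 * fit$k, BIC = -2 * fit$logL + fit$k * log(fit$n))
}

# Normalize a list of conf_fit objects or a data.frame(subject, aic) to a
# data frame with columns subject, aic.
as_aic_frame <- function(fits, arg) {
  if (is.data.frame(fits)) {
    names(fits) <- tolower(names(fits))
    if (!all(c("subject", "aic") %in% names(fits))) {
      stop_triconf(sprintf("`%s` data frame needs columns subject and aic", arg))
    }
    return(data.frame(
      subject = as.character(fits$subject),
      aic = as.numeric(fits$aic)
    ))
  }
  if (!is.list(fits) || length(fits) == 0L) {
    stop_triconf(sprintf("`%s` must be a non-empty list of fits or a data frame", arg))
  }
  data.frame(
    subject = vapply(fits, function(f) as.character(f$subject), character(1)),
    aic = vapply(fits, function(f) as.numeric(f$AIC), numeric(1))
  )
}

#' Group-summed AIC difference with a bootstrapped confidence interval
#'
#' Computes the AIC difference between an alternative and a reference model,
#' summed over subjects (`sum(AIC_alt - AIC_ref)`), and a 95% percentile
#' bootstrap confidence interval obtained by resampling subjects with
#' replacement. Positive values favor the reference model.
#'
#' @param fits_ref,fits_alt per-subject fits of the reference and
#'   alternative models: lists of `conf_fit` objects (one per subject), or
#'   data frames with columns `subject` and `aic`. Both must cover the same
#'   subjects.
#' @param n_boot number of bootstrap resamples (default 10,000).
#' @param seed RNG seed for the bootstrap.
#' @param level confidence level (default 0.95).
#'
#' @return An object of class `conf_group_delta` with elements `delta`
#'   (the group-summed difference), `ci` (percentile interval),
#'   `per_subject` and `n_boot`.
#' @export
group_delta <- function(fits_ref, fits_alt, n_boot = 10000L, seed = 1L,
                        level = 0.95) {
  ref <- as_aic_frame(fits_ref, "fits_ref")
  alt <- as_aic_frame(fits_alt, "fits_alt")
  if (n_boot < 1L) stop_triconf("`n_boot` must be >= 1")
  if (nrow(ref) != nrow(alt) || !setequal(ref$subject, alt$subject) ||
      anyDuplicated(ref$subject) || anyDuplicated(alt$subject)) {
    stop_triconf("`fits_ref` and `fits_alt` must cover the same subjects exactly once")
  }
  alt <- alt[match(ref$subject, alt$subject), ]
  d <- alt$aic - ref$aic
  ns <- length(d)
  sums <- with_seed(seed, {
    idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), nrow = ns)
    colSums(matrix(d[idx], nrow = ns))
  })
  a <- (1 - level) / 2
  structure(
    list(
      delta = sum(d),
      ci = unname(quantile(sums, c(a, 1 - a), type = 7)),
      level = level,
      per_subject = data.frame(subject = ref$subject, delta_aic = d),
      n_boot = as.integer(n_boot)
    ),
    class = "conf_group_delta"
  )
}

#' @export
print.conf_group_delta <- function(x, ...) {
  cat(sprintf(
    "<conf_group_delta> summed delta-AIC = %.1f, %g%% bootstrap CI [%.1f, %.1f] (%d subjects, %d resamples)\n",
    x$delta, 100 * x$level, x$ci[1], x$ci[2], nrow(x$per_subject), x$n_boot
  ))
  invisible(x)
}

#' Model-recovery analysis
#'
#' For each generator model, synthesizes one dataset per subject from that
#' model's parameters using the experiment design, fits every model in
#' `model_set` to each dataset, and accumulates group-summed AIC per
#' (generator, fitted) cell. If the comparison procedure is sound, the
#' generating model attains the lowest group-summed AIC within its row.
#'
#' @param experiment experiment id whose design (configurations, target
#'   sampling, trial counts) is simulated.
#' @param generators named list: one entry per generator rule, each a list
#'   of [observer_params()] (one per synthetic subject).
#' @param model_set character vector of rules to fit (default: the
#'   generator names).
#' @param noise noise variant used for the fitted models.
#' @param trials_per_config trials per configuration (default: the
#'   experiment's standard count).
#' @param seed master seed; per-dataset seeds are derived from it.
#' @param fit_args list of extra arguments passed to [fit_subject()]
#'   (e.g. `n_mc`, `restarts`).
#'
#' @return An object of class `conf_recovery`: `aic` (generator x fitted
#'   matrix of group-summed AIC), `wins` (per-subject win counts of each
#'   fitted model within each generator row), and `subject_aic` (the full
#'   generator x fitted x subject array).
#' @export
model_recovery <- function(experiment, generators, model_set = names(generators),
                           noise = "both", trials_per_config = NULL,
                           seed = 1L, fit_args = list()) {
  if (is.null(names(generators)) || any(names(generators) == "")) {
    stop_triconf("`generators` must be a named list (one entry per generator rule)")
  }
  n_sub <- unique(vapply(generators, length, integer(1)))
  if (length(n_sub) != 1L || n_sub < 1L) {
    stop_triconf("every generator needs the same, positive number of subjects")
  }
  gnames <- names(generators)
  aic <- array(NA_real_, dim = c(length(gnames), length(model_set), n_sub),
    dimnames = list(generator = gnames, fitted = model_set, subject = NULL)
  )
  failed <- matrix(0L, length(gnames), length(model_set),
    dimnames = list(generator = gnames, fitted = model_set)
  )
  seeds <- derive_seeds(seed, length(gnames) * n_sub)
  si <- 0L
  for (g in seq_along(gnames)) {
    for (j in seq_len(n_sub)) {
      si <- si + 1L
      dat <- generate_session(experiment, generators[[g]][[j]],
        trials_per_config = trials_per_config,
        seed = seeds[si], subject = sprintf("%s_%02d", gnames[g], j)
      )
      for (m in seq_along(model_set)) {
        fit <- tryCatch(
          do.call(fit_subject, c(
            list(
              dataset = dat, rule = model_set[m], noise = noise,
              seed = seeds[si] + m
            ),
            fit_args
          )),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          failed[g, m] <- failed[g, m] + 1L
        } else {
          aic[g, m, j] <- fit$AIC
        }
      }
    }
  }
  summed <- apply(aic, c(1, 2), sum)
  wins <- matrix(0L, length(gnames), length(model_set),
    dimnames = dimnames(failed)
  )
  for (g in seq_along(gnames)) {
    for (j in seq_len(n_sub)) {
      row <- aic[g, , j]
      if (all(is.finite(row))) {
        w <- which.min(row)
        wins[g, w] <- wins[g, w] + 1L
      }
    }
  }
  structure(
    list(aic = summed, wins = wins, subject_aic = aic, failed = failed),
    class = "conf_recovery"
  )
}

#' @export
print.conf_recovery <- function(x, ...) {
  cat("<conf_recovery> group-summed AIC (rows: generator, cols: fitted)\n")
  print(round(x$aic, 1))
  cat("per-subject wins:\n")
  print(x$wins)
  if (any(x$failed > 0)) {
    cat("fit failures per cell:\n")
    print(x$failed)
  }
  invisible(x)
}
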