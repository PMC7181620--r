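# Synthetic experiments: complete sessions and cohorts generated from
# observers with known ground-truth parameters.

# Standard session sizes: trials per configuration in each experiment.
.trials_per_config <- c(`1` = 84L, `2` = 120L, `3` = 120L)
.n_blocks <- 8L

#' Simulate one experimental session for one synthetic subject
#'
#' Draws `trials_per_config` targets from each of the experiment's four
#' configurations (84 in experiment 1, 120 in experiments 2 and 3 by
#' default), simulates the observer's category and confidence responses,
#' randomly interleaves the configurations, and splits the session into 8
#' equal blocks (block bookkeeping is recorded but ignored by the models,
#' which treat trials as independent). If the trial count is not divisible
#' into 8 equal blocks, blocking is disabled with a warning.
#'
#' @param experiment experiment id, 1, 2 or 3.
#' @param params an [observer_params()] describing the generating observer.
#' @param trials_per_config trials per configuration; `NULL` uses the
#'   experiment's standard count.
#' @param seed RNG seed; the same seed reproduces the session exactly.
#' @param subject subject identifier stored in the dataset.
#'
#' @return A [conf_dataset()] with an additional `block` column.
#' @export
generate_session <- function(experiment, params, trials_per_config = NULL,
                             seed = 1L, subject = "S01") {
  stopifnot(inherits(params, "conf_observer"))
  experiment <- as.integer(experiment)
  configs <- standard_configurations(experiment)
  if (is.null(trials_per_config)) {
    trials_per_config <- .trials_per_config[[as.character(experiment)]]
  }
  trials_per_config <- as.integer(trials_per_config)
  if (trials_per_config < 1L) stop_triconf("`trials_per_config` must be >= 1")
  total <- 4L * trials_per_config

  trials <- with_seed(seed, {
    per_config <- lapply(configs, function(cfg) {
      tg <- sample_target(cfg, trials_per_config)
      resp <- simulate_response(cbind(tg$x, tg$y), cfg, params)
      data.frame(
        config = cfg$config,
        target_x = tg$x, target_y = tg$y,
        true_category = tg$true_category,
        response_category = resp$category,
        confidence = resp$rating
      )
    })
    all <- do.call(rbind, per_config)
    all <- all[sample.int(total), ]
    if (total %% .n_blocks == 0L) {
      all$block <- rep(seq_len(.n_blocks), each = total %/% .n_blocks)
    } else {
      warning("trial count not divisible into 8 equal blocks; blocking disabled")
      all$block <- NA_integer_
    }
    rownames(all) <- NULL
    all
  })
  out <- conf_dataset(trials, subject = subject, experiment = experiment)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "generator") <- params
  out
}

#' Simulate a cohort of synthetic subjects with known parameters
#'
#' Generates one session per subject, with per-subject parameters drawn from
#' package-default ranges (sensory noise sigma uniform on \[0.1, 1\] deg,
#' concentration alpha log-uniform on \[5, 200\], lapse uniform on
#' \[0.005, 0.05\]) or supplied explicitly. Each subject's confidence
#' criteria are placed at the quartiles of that subject's simulated
#' confidence-variable distribution, so all four ratings occur. Every
#' drawn parameter set and per-subject seed is recorded in the ground-truth
#' ledger, from which the cohort can be regenerated exactly.
#'
#' @param experiment experiment id, 1, 2 or 3.
#' @param n_subjects number of synthetic subjects, >= 1.
#' @param rule generating confidence rule.
#' @param noise generating noise variant.
#' @param trials_per_config trials per configuration (`NULL`: standard).
#' @param seed master seed; all per-subject randomness derives from it.
#' @param sigma_range,alpha_range,lapse_range sampling ranges of the
#'   per-subject parameters (alpha is sampled log-uniformly).
#' @param params optional list of [observer_params()], one per subject,
#'   overriding the random draws.
#'
#' @return A list with `datasets` (list of [conf_dataset()]) and `truth`
#'   (data frame of per-subject generating parameters and seeds).
#' @export
generate_cohort <- function(experiment, n_subjects, rule = "difference",
                            noise = "both", trials_per_config = NULL,
                            seed = 1L,
                            sigma_range = c(0.1, 1),
                            alpha_range = c(5, 200),
                            lapse_range = c(0.005, 0.05),
                            params = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop_triconf("`n_subjects` must be >= 1")
  rule <- match.arg(rule, .rules)
  noise <- match.arg(noise, .noise_variants)
  if (!is.null(params) && length(params) != n_subjects) {
    stop_triconf("`params` must supply one observer per subject")
  }
  seeds <- derive_seeds(seed, 2L * n_subjects)
  param_seeds <- seeds[seq_len(n_subjects)]
  data_seeds <- seeds[n_subjects + seq_len(n_subjects)]

  subjects <- sprintf("S%02d", seq_len(n_subjects))
  obs <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    if (!is.null(params)) {
      obs[[j]] <- params[[j]]
    } else {
      obs[[j]] <- with_seed(param_seeds[j], {
        sigma <- if (noise == "decision") 0 else runif(1, sigma_range[1], sigma_range[2])
        alpha <- if (noise == "sensory") {
          Inf
        } else {
          exp(runif(1, log(alpha_range[1]), log(alpha_range[2])))
        }
        lapse <- runif(1, lapse_range[1], lapse_range[2])
        b <- calibrate_criteria(rule, sigma, alpha, experiment)
        observer_params(
          rule = rule, sigma = sigma, alpha = alpha,
          criteria = b, lapse = lapse, noise = noise
        )
      })
    }
  }
  datasets <- lapply(seq_len(n_subjects), function(j) {
    generate_session(experiment, obs[[j]],
      trials_per_config = trials_per_config,
      seed = data_seeds[j], subject = subjects[j]
    )
  })
  truth <- do.call(rbind, lapply(seq_len(n_subjects), function(j) {
    o <- obs[[j]]
    data.frame(
      subject = subjects[j], rule = o$rule, noise = o$noise,
      sigma = o$sigma, alpha = o$alpha, lapse = o$lapse,
      b1 = o$criteria[1], b2 = o$criteria[2], b3 = o$criteria[3],
      seed = data_seeds[j]
    )
  }))
  list(datasets = datasets, truth = truth, params = obs)
}
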