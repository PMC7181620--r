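# Experiment designs: category configurations, target sampling, exemplar dots.
# All geometry is in degrees of visual angle, screen-centered Cartesian
# coordinates (x positive rightward, y positive upward).

# Horizontal/vertical category centers of the four configurations tested in
# each experiment. Experiment 3 reuses the configurations of experiment 1.
.design_constants <- list(
  `1` = list(
    x = list(c(-3, 0, 3), c(-4, 0, 4), c(-3, -2, 3), c(-3, 2, 3)),
    y = list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  ),
  `2` = list(
    x = list(c(-2, 0, 2), c(-1.59, 0, 1.59), c(-2, -2, 2), c(-2, 2, 2)),
    y = list(
      c(1.16, -2.31, 1.16), c(0.94, -1.84, 0.94),
      c(1.16, 0, 1.16), c(1.16, 0, 1.16)
    )
  )
)

# Category-distribution SD (deg), common to all categories and both axes.
.category_sd <- 2

# Target-sampling constants: horizontal extension beyond the outer category
# centers (experiment 1), vertical target SD (experiment 1), disc radius
# (experiment 2).
.exp1_extension <- 0.2
.exp1_vertical_sd <- 2
.exp2_disc_radius <- 2.6

#' Category configuration for one condition of one experiment
#'
#' A configuration holds the centers of the three Gaussian categories and
#' their common standard deviation, in degrees of visual angle.
#'
#' @param experiment experiment id, 1, 2 or 3.
#' @param config configuration id within the experiment, 1--4.
#' @param means numeric 3 x 2 matrix of category centers (x, y).
#' @param sd common category standard deviation (degrees), > 0.
#'
#' @return An object of class `conf_config`.
#' @export
category_config <- function(experiment, config, means, sd) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) {
    stop_triconf("`experiment` must be 1, 2 or 3")
  }
  config <- as.integer(config)
  means <- as.matrix(means)
  if (!all(dim(means) == c(3L, 2L))) {
    stop_triconf("`means` must be a 3 x 2 matrix of category centers")
  }
  if (!is_scalar_number(sd) || sd <= 0) {
    stop_triconf("`sd` must be a positive number (degrees)")
  }
  if (experiment %in% c(1L, 3L) && any(means[, 2] != means[1, 2])) {
    stop_triconf("experiments 1 and 3 require vertically aligned category centers")
  }
  structure(
    list(
      experiment = experiment, config = config,
      means = unname(means), sd = as.numeric(sd)
    ),
    class = "conf_config"
  )
}

#' @export
print.conf_config <- function(x, ...) {
  cat(sprintf(
    "<conf_config> experiment %d, configuration %d (category sd = %g deg)\n",
    x$experiment, x$config, x$sd
  ))
  m <- x$means
  for (i in 1:3) cat(sprintf("  category %d: (%+.2f, %+.2f)\n", i, m[i, 1], m[i, 2]))
  invisible(x)
}

#' Standard stimulus configurations of the three experiments
#'
#' Returns the four category configurations used in the given experiment.
#' In experiments 1 and 3 the three category centers are vertically aligned
#' at y = 0 and only their horizontal positions differ across configurations;
#' experiment 3 reuses the configurations of experiment 1. In experiment 2
#' the centers vary in both dimensions. The category SD is 2 degrees
#' throughout.
#'
#' @param experiment experiment id, 1, 2 or 3.
#'
#' @return A list of 4 [category_config()] objects.
#' @export
#'
#' @examples
#' standard_configurations(1)[[2]]$means  # x = (-4, 0, 4)
standard_configurations <- function(experiment) {
  experiment <- as.integer(experiment)
  if (length(experiment) != 1L || !experiment %in% 1:3) {
    stop_triconf("unknown experiment id; `experiment` must be 1, 2 or 3")
  }
  base <- if (experiment == 2L) .design_constants[["2"]] else .design_constants[["1"]]
  lapply(1:4, function(k) {
    category_config(
      experiment = experiment, config = k,
      means = cbind(base$x[[k]], base$y[[k]]),
      sd = .category_sd
    )
  })
}

#' Read an experiment-design JSON file
#'
#' Parses a design file of the schema shipped under `inst/extdata`
#' (one record per configuration with fields `experiment`, `config`,
#' `means` and `sd`).
#'
#' @param path path to a design JSON file.
#' @return A list of [category_config()] objects.
#' @export
read_design_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    means <- if (is.list(r$means)) do.call(rbind, r$means) else r$means
    category_config(
      experiment = r$experiment, config = r$config,
      means = means, sd = r$sd
    )
  })
}

#' Sample target-dot positions for one configuration
#'
#' Draws targets according to the experiment's sampling rule:
#' \describe{
#'   \item{Experiment 1}{horizontal position uniform between the outer
#'     category centers extended by 0.2 degrees on each side; vertical
#'     position Normal(0, 2 deg).}
#'   \item{Experiment 2}{uniform over a disc of radius 2.6 degrees centered
#'     on the screen.}
#'   \item{Experiment 3}{a true category is drawn uniformly from \{1, 2, 3\}
#'     and the position from that category's Gaussian.}
#' }
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param config a [category_config()].
#' @param n number of targets to draw.
#'
#' @return A data frame with columns `x`, `y` and `true_category`
#'   (`NA` except in experiment 3).
#' @export
sample_target <- function(config, n = 1L) {
  stopifnot(inherits(config, "conf_config"))
  n <- as.integer(n)
  if (n < 1L) stop_triconf("`n` must be >= 1")
  true_category <- rep(NA_integer_, n)
  if (config$experiment == 1L) {
    lo <- min(config$means[, 1]) - .exp1_extension
    hi <- max(config$means[, 1]) + .exp1_extension
    x <- runif(n, lo, hi)
    y <- rnorm(n, 0, .exp1_vertical_sd)
  } else if (config$experiment == 2L) {
    r <- .exp2_disc_radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    x <- r * cos(th)
    y <- r * sin(th)
  } else {
    true_category <- sample.int(3L, n, replace = TRUE)
    x <- rnorm(n, config$means[true_category, 1], config$sd)
    y <- rnorm(n, config$means[true_category, 2], config$sd)
  }
  data.frame(x = x, y = y, true_category = true_category)
}

#' Generate exemplar-dot clouds for a configuration
#'
#' Each category's exemplar dots are i.i.d. draws from that category's
#' isotropic Gaussian. The default of 375 dots per category matches the
#' stimulus displays; the observer model itself consumes only the category
#' means and SD.
#'
#' @param config a [category_config()].
#' @param n_per_category dots per category (default 375).
#'
#' @return A data frame with columns `category`, `x`, `y`.
#' @export
render_exemplar_dots <- function(config, n_per_category = 375L) {
  stopifnot(inherits(config, "conf_config"))
  n_per_category <- as.integer(n_per_category)
  if (n_per_category < 1L) stop_triconf("`n_per_category` must be >= 1")
  category <- rep(1:3, each = n_per_category)
  data.frame(
    category = category,
    x = rnorm(3L * n_per_category, config$means[category, 1], config$sd),
    y = rnorm(3L * n_per_category, config$means[category, 2], config$sd)
  )
}
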