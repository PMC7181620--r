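# Descriptive surfaces: sliding-window psychometric curves, hexagonal-bin
# confidence maps, and model-prediction overlays. The data path and the
# model path share one windowing/binning implementation.

# Sliding-window mean of `value` against coordinate `x`: at each center,
# the mean over points with x in [center - width/2, center + width/2]
# (closed interval, with a 1e-9 degree guard against floating-point drift
# of the window-center grid).
sliding_window_stat <- function(x, value, centers, width) {
  half <- width / 2 + 1e-9
  vapply(centers, function(ctr) {
    inside <- x >= ctr - half & x <= ctr + half
    n <- sum(inside)
    c(mean = if (n > 0L) mean(value[inside]) else NA_real_, n = n)
  }, numeric(2))
}

# Assign points to non-overlapping flat-top hexagons of circumradius
# `radius` on a lattice with one hexagon centered at the origin. Returns
# axial coordinates (q, r) and the hexagon centers.
hex_assign <- function(x, y, radius) {
  qf <- (2 / 3) * x / radius
  rf <- (-x / 3 + sqrt(3) / 3 * y) / radius
  # cube rounding
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  fix_z <- !fix_x & !fix_y
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  q <- rx
  r <- rz
  data.frame(
    q = q, r = r,
    hx = 1.5 * radius * q,
    hy = sqrt(3) * radius * (r + q / 2)
  )
}

default_x_range <- function(experiment) {
  switch(as.character(experiment),
    `1` = c(-3.5, 3.5),
    `3` = c(-5, 5),
    c(-3, 3)
  )
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "conf_dataset")) datasets <- list(datasets)
  if (!is.list(datasets) || length(datasets) == 0L ||
      !all(vapply(datasets, inherits, logical(1), "conf_dataset"))) {
    stop_triconf("`datasets` must be a conf_dataset or a non-empty list of them")
  }
  datasets
}

#' Sliding-window psychometric curve of mean confidence
#'
#' Mean confidence rating as a function of the horizontal target position,
#' computed with a sliding window (default width 0.6 deg, step 0.1 deg):
#' the window statistic is computed per subject first and then averaged
#' across subjects, with the between-subject s.e.m. Windows containing no
#' trials for any subject are reported as missing, not zero. Default ranges
#' are -3.5 to 3.5 deg (experiment 1) and -5 to 5 deg (experiment 3).
#'
#' @param datasets a [conf_dataset()] or list of them (one per subject);
#'   subset by configuration beforehand to reproduce per-condition curves.
#' @param width sliding-window width in degrees.
#' @param step window step in degrees.
#' @param x_range range of window centers; `NULL` picks the experiment
#'   default.
#'
#' @return A data frame of class `conf_psychometric` with columns `center`,
#'   `mean_confidence`, `sem`, `n_subjects`, `n_trials`; the per-subject
#'   curves are attached as attribute `"per_subject"`.
#' @export
psychometric_curve <- function(datasets, width = 0.6, step = 0.1,
                               x_range = NULL) {
  datasets <- as_dataset_list(datasets)
  if (is.null(x_range)) {
    x_range <- default_x_range(datasets[[1]]$experiment[1])
  }
  centers <- seq(x_range[1], x_range[2], by = step)
  per <- vapply(datasets, function(d) {
    sliding_window_stat(d$target_x, d$confidence, centers, width)
  }, matrix(0, 2L, length(centers)))
  means <- matrix(per[1L, , ], nrow = length(centers))
  counts <- matrix(per[2L, , ], nrow = length(centers))
  n_subj <- rowSums(!is.na(means))
  avg <- ifelse(n_subj > 0L, rowMeans(means, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_len(nrow(means)), function(i) {
    v <- means[i, !is.na(means[i, ])]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  out <- data.frame(
    center = centers,
    mean_confidence = avg,
    sem = sem,
    n_subjects = n_subj,
    n_trials = rowSums(counts)
  )
  attr(out, "per_subject") <- means
  attr(out, "width") <- width
  class(out) <- c("conf_psychometric", "data.frame")
  out
}

#' Hexagonal-bin map of mean confidence
#'
#' Tiles the plane with non-overlapping flat-top hexagons (circumradius
#' `radius`, default 0.25 deg, one hexagon centered at the origin), assigns
#' every trial to exactly one hexagon, computes the mean confidence per
#' hexagon per subject, and averages across subjects. Hexagons whose
#' centers lie in the `extent` square but contain no trials from any
#' subject are kept, flagged empty (mean `NA`). Windows with fewer than
#' five trials are flagged via the `low_occupancy` column, not dropped.
#'
#' @param datasets a [conf_dataset()] or list of them.
#' @param radius hexagon center-to-vertex distance, degrees.
#' @param extent range (applied to both axes) of hexagon centers reported.
#'
#' @return A data frame of class `conf_hexmap` with hexagon axial
#'   coordinates `q`, `r`, centers `hx`, `hy`, `mean_confidence`,
#'   `n_trials`, `n_subjects`, `in_extent` and `low_occupancy`.
#' @export
hex_map <- function(datasets, radius = 0.25, extent = c(-3, 3)) {
  datasets <- as_dataset_list(datasets)
  per_subject <- lapply(datasets, function(d) {
    hx <- hex_assign(d$target_x, d$target_y, radius)
    key <- paste(hx$q, hx$r)
    agg <- aggregate(
      list(total = d$confidence, n = rep(1L, nrow(d))),
      by = list(key = key, q = hx$q, r = hx$r), FUN = sum
    )
    agg$mean <- agg$total / agg$n
    agg
  })
  occupied <- unique(do.call(rbind, lapply(per_subject, `[`, c("key", "q", "r"))))
  # full lattice of hexagon centers inside the extent square
  qmax <- ceiling(extent[2] / (1.5 * radius)) + 1L
  rmax <- ceiling(extent[2] / (sqrt(3) * radius)) + qmax
  lattice <- expand.grid(q = seq(-qmax, qmax), r = seq(-rmax, rmax))
  lattice$hx <- 1.5 * radius * lattice$q
  lattice$hy <- sqrt(3) * radius * (lattice$r + lattice$q / 2)
  lattice <- lattice[
    lattice$hx >= extent[1] & lattice$hx <= extent[2] &
      lattice$hy >= extent[1] & lattice$hy <= extent[2],
  ]
  lattice$key <- paste(lattice$q, lattice$r)
  extra <- occupied[!occupied$key %in% lattice$key, , drop = FALSE]
  cells <- rbind(
    data.frame(
      key = lattice$key, q = lattice$q, r = lattice$r, in_extent = TRUE
    ),
    if (nrow(extra) > 0L) {
      data.frame(key = extra$key, q = extra$q, r = extra$r, in_extent = FALSE)
    }
  )
  sum_mean <- stats::setNames(numeric(nrow(cells)), cells$key)
  n_subj <- stats::setNames(integer(nrow(cells)), cells$key)
  n_tot <- stats::setNames(integer(nrow(cells)), cells$key)
  for (agg in per_subject) {
    hit <- agg$key %in% cells$key
    sum_mean[agg$key[hit]] <- sum_mean[agg$key[hit]] + agg$mean[hit]
    n_subj[agg$key[hit]] <- n_subj[agg$key[hit]] + 1L
    n_tot[agg$key[hit]] <- n_tot[agg$key[hit]] + agg$n[hit]
  }
  out <- data.frame(
    q = cells$q, r = cells$r,
    hx = 1.5 * radius * cells$q,
    hy = sqrt(3) * radius * (cells$r + cells$q / 2),
    mean_confidence = ifelse(n_subj > 0L, sum_mean / n_subj, NA_real_),
    n_trials = as.integer(n_tot),
    n_subjects = as.integer(n_subj),
    in_extent = cells$in_extent
  )
  out$low_occupancy <- out$n_trials < 5L
  attr(out, "radius") <- radius
  class(out) <- c("conf_hexmap", "data.frame")
  out
}

#' Model-predicted confidence surface
#'
#' Computes the expected confidence rating E\[c | s\] of an observer model on
#' an evenly spaced grid of target positions (step 0.1 deg by default) from
#' its Monte-Carlo response distribution, then summarizes the grid through
#' the identical sliding-window (`kind = "curve"`, along the horizontal
#' axis) or hexagonal-binning (`kind = "hexmap"`, 2-D grid) code as the
#' data path.
#'
#' @param config a [category_config()].
#' @param params an [observer_params()] (e.g. from a fit).
#' @param kind `"curve"` for experiments 1/3 summaries, `"hexmap"` for
#'   experiment 2.
#' @param grid_step spacing of the evaluation grid, degrees.
#' @param n_mc Monte-Carlo measurements per grid point.
#' @param seed RNG seed of the simulation.
#' @param width,step,x_range sliding-window settings (`kind = "curve"`).
#' @param radius,extent hexagon settings (`kind = "hexmap"`).
#'
#' @return A `conf_psychometric` or `conf_hexmap` data frame (with
#'   `n_subjects` set to `NA`, since the surface is a model prediction).
#' @export
model_prediction_surface <- function(config, params,
                                     kind = c("curve", "hexmap"),
                                     grid_step = 0.1, n_mc = 2000L, seed = 1L,
                                     width = 0.6, step = 0.1, x_range = NULL,
                                     radius = 0.25, extent = c(-3, 3)) {
  stopifnot(inherits(config, "conf_config"), inherits(params, "conf_observer"))
  kind <- match.arg(kind)
  if (kind == "curve") {
    if (is.null(x_range)) x_range <- default_x_range(config$experiment)
    gx <- seq(x_range[1] - width / 2, x_range[2] + width / 2, by = grid_step)
    pos <- cbind(gx, 0)
  } else {
    gx <- seq(extent[1], extent[2], by = grid_step)
    pos <- as.matrix(expand.grid(x = gx, y = gx))
  }
  tab <- config_tables(pos, config, params, n_mc, seed)
  expected <- as.numeric(tab %*% rep(1:4, each = 3L))

  if (kind == "curve") {
    centers <- seq(x_range[1], x_range[2], by = step)
    stat <- sliding_window_stat(pos[, 1], expected, centers, width)
    out <- data.frame(
      center = centers,
      mean_confidence = stat[1L, ],
      sem = NA_real_,
      n_subjects = NA_integer_,
      n_trials = as.integer(stat[2L, ])
    )
    attr(out, "width") <- width
    class(out) <- c("conf_psychometric", "data.frame")
  } else {
    hx <- hex_assign(pos[, 1], pos[, 2], radius)
    key <- paste(hx$q, hx$r)
    agg <- aggregate(
      list(total = expected, n = rep(1L, nrow(pos))),
      by = list(key = key, q = hx$q, r = hx$r), FUN = sum
    )
    out <- data.frame(
      q = agg$q, r = agg$r,
      hx = 1.5 * radius * agg$q,
      hy = sqrt(3) * radius * (agg$r + agg$q / 2),
      mean_confidence = agg$total / agg$n,
      n_trials = as.integer(agg$n),
      n_subjects = NA_integer_,
      in_extent = TRUE
    )
    out$low_occupancy <- FALSE
    attr(out, "radius") <- radius
    class(out) <- c("conf_hexmap", "data.frame")
  }
  attr(out, "source") <- "model"
  out
}

#' @export
plot.conf_psychometric <- function(x, add = FALSE, col = "black", ...) {
  ok <- !is.na(x$mean_confidence)
  if (!add) {
    plot(x$center[ok], x$mean_confidence[ok],
      type = "l", col = col, ylim = c(1, 4),
      xlab = "target x (deg)", ylab = "mean confidence", ...
    )
  } else {
    graphics::lines(x$center[ok], x$mean_confidence[ok], col = col, ...)
  }
  if (any(!is.na(x$sem))) {
    graphics::arrows(x$center[ok], x$mean_confidence[ok] - x$sem[ok],
      x$center[ok], x$mean_confidence[ok] + x$sem[ok],
      length = 0, col = grDevices::adjustcolor(col, 0.4)
    )
  }
  invisible(x)
}
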