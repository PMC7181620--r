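make_curve_dataset <- function(x, rating, subject = "A") {
  conf_dataset(
    data.frame(
      config = 1L, target_x = x, target_y = 0,
      true_category = NA_integer_,
      response_category = 2L, confidence = rating
    ),
    subject = subject, experiment = 1L
  )
}

test_that("psychometric curves window correctly and flag empty windows", {
  # constant ratings give a flat curve at that rating
  d <- make_curve_dataset(runif(200, -3, 3), 4L)
  pc <- psychometric_curve(d)
  expect_s3_class(pc, "conf_psychometric")
  expect_equal(pc$center, seq(-3.5, 3.5, by = 0.1))
  filled <- !is.na(pc$mean_confidence)
  expect_true(all(pc$mean_confidence[filled] == 4))

  # a single trial fills exactly the windows containing it
  d1 <- make_curve_dataset(0, 2L)
  pc1 <- psychometric_curve(d1)
  hit <- abs(pc1$center) <= 0.3 + 1e-9
  expect_true(all(pc1$mean_confidence[hit] == 2))
  expect_true(all(is.na(pc1$mean_confidence[!hit])))
  expect_equal(sum(pc1$n_trials > 0), sum(hit))
})

test_that("across-subject averaging happens after per-subject windowing", {
  # subject A: one trial rating 1; subject B: three trials rating 3.
  # pooling would give 2.5; per-subject-then-average gives 2.
  dA <- make_curve_dataset(0, 1L, subject = "A")
  dB <- make_curve_dataset(c(0, 0.01, -0.01), 3L, subject = "B")
  pc <- psychometric_curve(list(dA, dB))
  at0 <- which.min(abs(pc$center))
  expect_equal(pc$mean_confidence[at0], 2)
  expect_equal(pc$n_subjects[at0], 2L)
  expect_gte(pc$sem[at0], 0)
  expect_true(all(
    pc$mean_confidence[!is.na(pc$mean_confidence)] >= 1 &
      pc$mean_confidence[!is.na(pc$mean_confidence)] <= 4
  ))
})

test_that("hexagonal binning partitions trials and respects geometry", {
  cfg2 <- standard_configurations(2)[[1]]
  ob <- test_observer(experiment = 2, crit_seed = 51)
  d <- generate_session(2, ob, seed = 52)
  hm <- hex_map(d)
  expect_s3_class(hm, "conf_hexmap")
  # every trial lands in exactly one hexagon
  expect_equal(sum(hm$n_trials), nrow(d))
  # disc targets of radius 2.6 only occupy hexagons near the disc
  occ <- hm[hm$n_trials > 0, ]
  expect_true(all(sqrt(occ$hx^2 + occ$hy^2) <= 2.6 + 2 * 0.25))
  # empty in-extent hexagons are flagged missing, not zero
  empty <- hm[hm$n_trials == 0 & hm$in_extent, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$mean_confidence)))
  expect_true(all(hm$low_occupancy == (hm$n_trials < 5)))

  # a trial at the origin lands in the origin-centered hexagon
  d0 <- make_curve_dataset(0, 3L)
  hm0 <- hex_map(d0, extent = c(-1, 1))
  expect_equal(hm0$n_trials[hm0$q == 0 & hm0$r == 0], 1L)

  # assignment is to the nearest hexagon center
  pts <- withr::with_seed(53, cbind(runif(300, -2, 2), runif(300, -2, 2)))
  asg <- triconf:::hex_assign(pts[, 1], pts[, 2], 0.25)
  d_own <- sqrt((pts[, 1] - asg$hx)^2 + (pts[, 2] - asg$hy)^2)
  # distance to the assigned center never exceeds the circumradius
  expect_true(all(d_own <= 0.25 + 1e-9))
})

test_that("model prediction surfaces share the data path's summaries", {
  cfg <- standard_configurations(1)[[1]]
  # a pure-lapse observer predicts flat expected confidence of 2.5
  ob_lapse <- observer_params("difference",
    sigma = 0.5, alpha = 30,
    criteria = c(0.1, 0.3, 0.6), lapse = 1
  )
  pred <- model_prediction_surface(cfg, ob_lapse, n_mc = 200, seed = 61)
  expect_equal(
    pred$mean_confidence[!is.na(pred$mean_confidence)],
    rep(2.5, sum(!is.na(pred$mean_confidence)))
  )

  # the noiseless Max observer is least confident at the category boundaries
  ob_max <- observer_params("max",
    sigma = 0, alpha = Inf,
    criteria = c(0.45, 0.55, 0.65), lapse = 0
  )
  pred_max <- model_prediction_surface(cfg, ob_max, n_mc = 1, seed = 62)
  v <- pred_max$mean_confidence
  ctr <- pred_max$center
  # the minimum forms a plateau; its midpoint sits at the likelihood-equality
  # boundaries between neighboring categories, +/- 1.5 deg
  left_min <- ctr < 0 & v <= min(v[ctr < 0]) + 1e-9
  right_min <- ctr > 0 & v <= min(v[ctr > 0]) + 1e-9
  expect_lt(abs(mean(ctr[left_min]) - (-1.5)), 0.15)
  expect_lt(abs(mean(ctr[right_min]) - 1.5), 0.15)

  # hexmap prediction covers the extent grid
  cfg2 <- standard_configurations(2)[[1]]
  ob <- test_observer(experiment = 2, crit_seed = 63)
  hm_pred <- model_prediction_surface(cfg2, ob,
    kind = "hexmap",
    grid_step = 0.25, n_mc = 100, seed = 64
  )
  expect_true(all(is.finite(hm_pred$mean_confidence)))
  expect_true(all(hm_pred$mean_confidence >= 1 & hm_pred$mean_confidence <= 4))
})

test_that("data and model summaries agree on self-generated data", {
  cfg <- standard_configurations(1)[[1]]
  ob <- test_observer(crit_seed = 71)
  n <- 3e4
  pos <- withr::with_seed(72, {
    tg <- sample_target(cfg, n)
    cbind(tg$x, tg$y)
  })
  d <- dataset_from_positions(pos, cfg, ob, seed = 73)
  data_curve <- psychometric_curve(d, x_range = c(-3, 3))
  model_curve <- model_prediction_surface(cfg, ob,
    n_mc = 3000, seed = 74,
    x_range = c(-3, 3)
  )
  both <- !is.na(data_curve$mean_confidence) & !is.na(model_curve$mean_confidence)
  expect_gt(sum(both), 50)
  expect_lt(max(abs(
    data_curve$mean_confidence[both] - model_curve$mean_confidence[both]
  )), 0.1)
})
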