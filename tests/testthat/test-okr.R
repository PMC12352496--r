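# Eye tracking: circle fits, referencing, calibration, segmentation, gain.

test_that("Coope circle fit is exact on noiseless circles", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  px <- 5 + 2 * cos(ang)
  py <- 5 + 2 * sin(ang)
  f8 <- fit_pupil_circle(px, py, rep(1, 8))
  expect_equal(f8$center, c(5, 5), tolerance = 1e-9)
  expect_equal(f8$radius, 2, tolerance = 1e-9)
  # three points determine it just as well
  f3 <- fit_pupil_circle(px[c(1, 4, 6)], py[c(1, 4, 6)], rep(1, 3))
  expect_equal(f3$center, c(5, 5), tolerance = 1e-9)
  expect_equal(f3$radius, 2, tolerance = 1e-9)

  # agrees with the geometric (nonlinear) fit oracle on random circles
  set.seed(61)
  for (k in 1:25) {
    c0 <- stats::runif(2, -50, 50)
    r0 <- stats::runif(1, 1, 30)
    a <- sort(stats::runif(8, 0, 2 * pi))
    x <- c0[1] + r0 * cos(a)
    y <- c0[2] + r0 * sin(a)
    fit <- fit_pupil_circle(x, y, rep(1, 8))
    geo <- geometric_circle_fit(x, y)
    expect_equal(fit$center, geo$center, tolerance = 1e-6)
    expect_equal(fit$radius, geo$radius, tolerance = 1e-6)
  }
})

test_that("Coope center error shrinks with marker noise as O(sigma)", {
  set.seed(62)
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  err_at <- function(sigma) {
    mean(replicate(200, {
      x <- 10 * cos(ang) + stats::rnorm(8, sd = sigma)
      y <- 10 * sin(ang) + stats::rnorm(8, sd = sigma)
      sqrt(sum(fit_pupil_circle(x, y, rep(1, 8))$center^2))
    }))
  }
  expect_lt(err_at(0.01), 0.02)
  expect_lt(err_at(0.1), 0.2)
})

test_that("frames with fewer than three confident markers are imputed", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  px <- 5 + 2 * cos(ang)
  py <- 5 + 2 * sin(ang)
  prev <- fit_pupil_circle(px, py, rep(1, 8))
  low <- fit_pupil_circle(px, py, c(1, 1, rep(0.1, 6)),
                          previous = prev)
  expect_true(low$imputed)
  expect_equal(low$center, c(5, 5), tolerance = 1e-9)
  expect_equal(low$n_markers_used, 2)
  expect_error(fit_pupil_circle(px, py, rep(0, 8)), "unrecoverable")
})

test_that("corneal referencing subtracts the reflection centroid", {
  r <- reference_to_cornea(c(10, 10), c(0, 2, 1), c(0, 0, 3), rep(1, 3))
  expect_equal(r$reference, c(1, 1))
  expect_equal(r$relative, c(9, 9))
  simple <- reference_to_cornea(c(10, 10), c(4, 4, 4), c(4, 4, 4),
                                rep(1, 3))
  expect_equal(simple$relative, c(6, 6))
  # translation invariance
  shifted <- reference_to_cornea(c(10, 10) + c(7, -3),
                                 c(4, 4, 4) + 7, c(4, 4, 4) - 3, rep(1, 3))
  expect_equal(shifted$relative, simple$relative)
  # carry-forward when no reflection is confident
  cf <- reference_to_cornea(c(10, 10), c(4, 4, 4), c(4, 4, 4), rep(0, 3),
                            previous_reference = c(2, 2))
  expect_true(cf$imputed_reference)
  expect_equal(cf$relative, c(8, 8))
})

test_that("scale calibration inverts the camera separation", {
  a <- cbind(rep(0, 50), rep(0, 50))
  expect_equal(calibrate_scale(a, a + cbind(rep(24, 50), 0)), 0.5)
  expect_equal(calibrate_scale(a, a + cbind(rep(12, 50), 0)), 1.0)
  expect_error(calibrate_scale(a, a), "zero mean")
  # generator round trip recovers the rendering scale within 1%
  sim <- gen_eye_markers(eye_sim_spec(duration = 5, dropout_prob = 0),
                         seed = 71)
  fa <- fit_pupil_circles(sim$camera_a)
  fb <- fit_pupil_circles(sim$camera_b)
  sc <- calibrate_scale(cbind(fa$cx, fa$cy), cbind(fb$cx, fb$cy))
  expect_equal(sc, sim$ground_truth$scale_deg_per_px, tolerance = 0.01)
})

test_that("eye-trace velocity is the position gradient times frame rate", {
  n <- 100
  tr <- build_eye_trace(cbind(0.02 * (seq_len(n) - 1), 0),
                        rep(FALSE, n), scale = 1, fps = 100,
                        gaussian_sigma = 0)
  expect_equal(tr$vx[2:(n - 1)], rep(2, n - 2), tolerance = 1e-9)
  expect_equal(tr$v_total[10], 2, tolerance = 1e-9)
  const <- build_eye_trace(cbind(rep(3, n), rep(4, n)), rep(FALSE, n),
                           1, 100)
  expect_true(all(const$v_total == 0))
  # impulse noise is attenuated by the smoothing
  imp <- cbind(c(rep(0, 50), 5, rep(0, 49)), rep(0, n))
  v_smooth <- max(build_eye_trace(imp, rep(FALSE, n), 1, 100,
                                  gaussian_sigma = 2)$v_total)
  v_raw <- max(build_eye_trace(imp, rep(FALSE, n), 1, 100,
                               gaussian_sigma = 0)$v_total)
  expect_lt(v_smooth, v_raw)
})

test_that("classification splits exactly at the velocity threshold", {
  lab29 <- classify_frames(constant_velocity_trace(29))
  expect_true(all(lab29 == "slow"))
  lab31 <- classify_frames(constant_velocity_trace(31))
  # interior frames are all saccade (edges see one-sided gradients)
  expect_true(all(lab31[5:195] == "saccade"))
  # imputed frames override to low_confidence
  tr <- constant_velocity_trace(5)
  tr$imputed[7] <- TRUE
  expect_equal(as.character(classify_frames(tr)[7]), "low_confidence")

  # bisection over constant-velocity traces converges to the threshold
  is_sacc <- function(v) {
    classify_frames(constant_velocity_trace(v))[100] == "saccade"
  }
  lo <- 0; hi <- 60
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (is_sacc(mid)) hi <- mid else lo <- mid
  }
  expect_equal(round((lo + hi) / 2, 1), 30)
})

test_that("slow-pursuit integration follows the sign and axis rules", {
  n <- 4501
  fps <- 100
  tt <- (seq_len(n) - 1) / fps
  # perfect tracking of a 2 deg/s, 45 s posterior stimulus: +90 degrees
  tr <- build_eye_trace(cbind(-2 * tt, 0), rep(FALSE, n), 1, fps)
  lab <- classify_frames(tr)
  cum <- cumulative_slow_pursuit(tr, lab, "posterior")
  expect_equal(cum, 90, tolerance = 0.1)
  # motion opposite the stimulus is negative
  expect_lt(cumulative_slow_pursuit(tr, lab, "anterior"), 0)
  # pure vertical motion does not project onto a horizontal stimulus
  trv <- build_eye_trace(cbind(rep(0, n), 2 * tt), rep(FALSE, n), 1, fps)
  expect_equal(cumulative_slow_pursuit(trv, classify_frames(trv),
                                       "posterior"), 0, tolerance = 1e-9)
  expect_warning(
    z <- cumulative_slow_pursuit(tr, factor(rep("saccade", n),
                                            levels = levels(lab)),
                                 "posterior"),
    "no slow")
  expect_equal(z, 0)
})

test_that("gain is cumulative displacement over stimulus displacement", {
  g <- okr_gain(90, 2, 45, "horizontal")
  expect_equal(g$gain, 1)
  expect_equal(g$stimulus_deg, 90)
  expect_equal(okr_gain(0, 2, 45)$gain, 0)
  expect_equal(okr_gain(-45, 2, 45)$gain, -0.5)
  expect_error(okr_gain(10, 0, 45), "positive")
})

test_that("classifier saccade frames track the generator's intervals", {
  es <- eye_sim_spec(gain_true = 0.5, saccade_rate = 0.4,
                     position_noise_sd = 0, dropout_prob = 0,
                     duration = 20)
  sim <- gen_eye_markers(es, seed = 81)
  res <- okr_pipeline(sim$camera_a, sim$camera_b, es$stim_direction,
                      stim_velocity = es$stim_velocity,
                      stim_duration = es$duration)
  sac_frames <- which(res$labels == "saccade")
  ivals <- sim$ground_truth$saccade_intervals
  expect_gt(nrow(ivals), 0)
  # every true saccade core frame is labeled saccade
  for (i in seq_len(nrow(ivals))) {
    core <- which(sim$ground_truth$t > ivals[i, 1] &
                    sim$ground_truth$t < ivals[i, 2])
    expect_true(all(core %in% sac_frames))
  }
  # every labeled frame is within the smoothing support of a true saccade
  near <- unlist(lapply(seq_len(nrow(ivals)), function(i) {
    which(sim$ground_truth$t > ivals[i, 1] - 0.06 &
            sim$ground_truth$t < ivals[i, 2] + 0.06)
  }))
  expect_true(all(sac_frames %in% near))
})

test_that("the full pipeline recovers the simulated gain", {
  es <- eye_sim_spec(gain_true = 0.7)
  sim <- gen_eye_markers(es, seed = 91)
  res <- okr_pipeline(sim$camera_a, sim$camera_b, es$stim_direction,
                      stim_velocity = es$stim_velocity,
                      stim_duration = es$duration)
  expect_equal(res$gain_result$gain, 0.7, tolerance = 0.05)
  expect_equal(res$gain_result$axis, "horizontal")
  expect_equal(res$scale_deg_per_px, es$scale_deg_per_px, tolerance = 0.01)
  # vertical stimulus routes to the vertical axis
  esv <- eye_sim_spec(gain_true = 0.6, stim_direction = "superior",
                      duration = 20)
  simv <- gen_eye_markers(esv, seed = 92)
  resv <- okr_pipeline(simv$camera_a, simv$camera_b, "superior",
                       stim_velocity = esv$stim_velocity,
                       stim_duration = esv$duration)
  expect_equal(resv$gain_result$axis, "vertical")
  expect_equal(resv$gain_result$gain, 0.6, tolerance = 0.07)
})
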