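# Generators: tuning law, determinism, ground-truth sufficiency.

test_that("PSC generator obeys the tuning law at its endpoints", {
  # flat tuning: identical noiseless peaks everywhere
  flat <- tuning_spec(peak_pd = 100, peak_nd = 100, noise_sd = 0,
                      sampling_rate = 1000)
  sw <- gen_psc_sweeps(flat, seed = 1)
  peaks <- vapply(sw$traces, function(m) max(m[, 1]), 1)
  # tolerance covers the ~2e-5 overlap of the ON and OFF alpha tails
  expect_equal(unname(peaks), rep(100, 8), tolerance = 1e-4)

  # kernel endpoints: 1 at PD, 0 at PD + 180
  tuned <- tuning_spec(preferred_direction = 180, peak_pd = 250,
                       peak_nd = 0, noise_sd = 0, sampling_rate = 1000)
  sw2 <- gen_psc_sweeps(tuned, seed = 1)
  expect_equal(max(sw2$traces[["dir180"]][, 1]), 250, tolerance = 1e-4)
  expect_equal(max(abs(sw2$traces[["dir000"]][, 1])), 0, tolerance = 1e-9)
})

test_that("tuning law is symmetric about the preferred direction", {
  spec <- tuning_spec(preferred_direction = 90, tuning_width = 45,
                      peak_pd = 10, peak_nd = 2)
  th <- seq(0, 350, by = 10)
  pk <- tuning_law(spec, th)
  expect_equal(which.max(pk), which(th == 90))
  expect_equal(which.min(pk), which(th == 270))
  # f(90 + d) == f(90 - d)
  expect_equal(tuning_law(spec, 90 + c(10, 45, 120)),
               tuning_law(spec, 90 - c(10, 45, 120)), tolerance = 1e-12)
  # half-width calibration: f at the half-width is exactly half way
  expect_equal(tuning_law(spec, 90 + 45), 2 + (10 - 2) * 0.5,
               tolerance = 1e-6)
})

test_that("generators are bit-identical under a repeated seed", {
  spec <- tuning_spec(sampling_rate = 1000, duration = 2)
  expect_identical(gen_psc_sweeps(spec, seed = 7),
                   gen_psc_sweeps(spec, seed = 7))
  sspec <- tuning_spec(peak_pd = 80, peak_nd = 10, sampling_rate = 1000,
                       duration = 2)
  expect_identical(gen_spike_sweeps(sspec, seed = 7),
                   gen_spike_sweeps(sspec, seed = 7))
  expect_identical(gen_iv_currents(iv_sim_spec(), seed = 7),
                   gen_iv_currents(iv_sim_spec(), seed = 7))
  es <- eye_sim_spec(duration = 2)
  expect_identical(gen_eye_markers(es, seed = 7),
                   gen_eye_markers(es, seed = 7))
  expect_identical(gen_dendrite_fields(0.4, seed = 7),
                   gen_dendrite_fields(0.4, seed = 7))
})

test_that("spike generator: zero rate means zero spikes, PD rate is unbiased", {
  silent <- tuning_spec(peak_pd = 0, peak_nd = 0, noise_sd = 0,
                        sampling_rate = 1000)
  sw <- gen_spike_sweeps(silent, directions = c(0, 90), seed = 2)
  expect_true(all(vapply(sw$traces, function(m) all(m == 0), TRUE)))
  expect_equal(sum(lengths(unlist(sw$ground_truth$spike_times,
                                  recursive = FALSE))), 0)

  # empirical PD rate within 3 s.e. of the nominal 100 Hz over many trials
  spec <- tuning_spec(peak_pd = 100, peak_nd = 0, preferred_direction = 0,
                      noise_sd = 0, n_trials = 1000,
                      sampling_rate = 500, duration = 4.5)
  sw2 <- gen_spike_sweeps(spec, directions = 0, seed = 3)
  counts <- lengths(sw2$ground_truth$spike_times[[1]])
  rates <- counts / 3.0            # two 1.5 s windows per sweep
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 100), 3 * se)
})

test_that("IV generator reproduces Ohm's law exactly at zero noise", {
  expect_error(iv_sim_spec(holds = -80), "2 distinct holds")
  iv <- gen_iv_currents(iv_sim_spec(g_true = 2, e_rev_true = -60,
                                    noise_sd = 0), seed = 1)
  expect_equal(iv$peaks[, 1], stats::setNames(2 * (iv$holds + 60),
                                              rownames(iv$peaks)))
  expect_equal(iv$peaks["-80", 1], -40, ignore_attr = TRUE)
  iv0 <- gen_iv_currents(iv_sim_spec(g_true = 0, noise_sd = 0), seed = 1)
  expect_true(all(iv0$peaks == 0))
})

test_that("eye generator: latent trace, markers and saccade truth are consistent", {
  # no saccades, no noise: latent position is a line of slope gain * velocity
  es <- eye_sim_spec(gain_true = 1, saccade_rate = 0, position_noise_sd = 0,
                     dropout_prob = 0, duration = 5)
  sim <- gen_eye_markers(es, seed = 1)
  gt <- sim$ground_truth
  slopes <- diff(gt$pos_x) / diff(gt$t)
  expect_equal(slopes, rep(-es$stim_velocity, length(slopes)),
               tolerance = 1e-9)  # posterior = -x axis
  # every frame has 8 high-likelihood pupil markers when dropout is off
  expect_true(all(rowSums(sim$camera_a$pupil_lik >= 0.9) == 8))
  # markers lie exactly on the rendered circle
  k <- 17
  cx <- mean(sim$camera_a$pupil_x[k, ])
  cy <- mean(sim$camera_a$pupil_y[k, ])
  rr <- sqrt((sim$camera_a$pupil_x[k, ] - cx)^2 +
               (sim$camera_a$pupil_y[k, ] - cy)^2)
  expect_equal(rr, rep(es$pupil_radius_px, 8), tolerance = 1e-9)

  # with saccades: ground-truth intervals line up with supra-threshold
  # latent velocity
  es2 <- eye_sim_spec(gain_true = 0.5, saccade_rate = 0.5,
                      position_noise_sd = 0, dropout_prob = 0,
                      duration = 20)
  sim2 <- gen_eye_markers(es2, seed = 5)
  gt2 <- sim2$ground_truth
  expect_gt(nrow(gt2$saccade_intervals), 0)
  v <- abs(c(diff(gt2$pos_x), 0)) * es2$fps
  for (i in seq_len(nrow(gt2$saccade_intervals))) {
    mid <- mean(gt2$saccade_intervals[i, ])
    expect_gt(v[which.min(abs(gt2$t - mid))], 30)
  }
})

test_that("dendrite-field generator hits the requested overlap exactly", {
  expect_equal(gen_dendrite_fields(0)$true_overlap_area, 0)
  f1 <- gen_dendrite_fields(1, width = 50, height = 40)
  expect_equal(f1$true_overlap_area, 2000)
  f5 <- gen_dendrite_fields(0.5, width = 1, height = 1)
  expect_equal(f5$true_overlap_area, 0.5)
  # measured via the geometry module
  ov <- hull_overlap(convex_hull(f5$points_a), convex_hull(f5$points_b))
  expect_equal(ov$area_intersection, 0.5, tolerance = 1e-9)
  ov0 <- hull_overlap(convex_hull(gen_dendrite_fields(0)$points_a),
                      convex_hull(gen_dendrite_fields(0)$points_b))
  expect_equal(ov0$area_intersection, 0)
})

test_that("generator argument validation rejects malformed specs", {
  expect_error(gen_psc_sweeps(tuning_spec(), directions = numeric(0)),
               "non-empty")
  expect_error(gen_psc_sweeps(tuning_spec(), directions = c(0, 400)),
               "\\[0, 360\\)")
  expect_error(tuning_spec(noise_sd = -1), "noise_sd")
  expect_error(tuning_spec(peak_pd = 1, peak_nd = 2), "peak_pd")
  expect_error(eye_sim_spec(dropout_prob = 1), "dropout_prob")
  expect_error(gen_eye_markers(eye_sim_spec(duration = 0.01), seed = 1),
               "2 frames")
  expect_error(gen_dendrite_fields(1.2), "overlap_frac")
})

test_that("sweep-set and marker-table CSV round trips preserve the data", {
  spec <- tuning_spec(sampling_rate = 500, duration = 1, n_trials = 2)
  sw <- gen_psc_sweeps(spec, directions = c(0, 90, 180), seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_sweep_set(sw, csv)
  back <- read_sweep_set(csv)
  expect_equal(back$directions, sw$directions)
  expect_equal(back$sampling_rate, sw$sampling_rate)
  for (d in names(sw$traces)) {
    expect_equal(unname(back$traces[[d]]), unname(sw$traces[[d]]),
                 tolerance = 1e-9)
  }

  sim <- gen_eye_markers(eye_sim_spec(duration = 1), seed = 3)
  mcsv <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(sim$camera_a, mcsv)
  mback <- read_marker_table(mcsv, fps = 100, camera_id = "A")
  expect_equal(mback$pupil_x, sim$camera_a$pupil_x, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mback$refl_lik, sim$camera_a$refl_lik, tolerance = 1e-9,
               ignore_attr = TRUE)
})
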