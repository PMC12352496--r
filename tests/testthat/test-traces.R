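# Trial averaging, baselines, spike detection, window peaks.

test_that("trial averaging is the pointwise mean and shrinks noise as 1/sqrt(n)", {
  sw <- gen_psc_sweeps(tuning_spec(sampling_rate = 500, duration = 1,
                                   noise_sd = 0, n_trials = 3),
                       directions = c(0, 180), seed = 1)
  mt <- average_trials(sw)
  # identical trials: mean equals any single trial
  expect_equal(mt$traces[[1]], sw$traces[[1]][, 2], tolerance = 1e-12)
  expect_equal(mt$n_trials, 3)

  # constant trials 0 and 2 average to 1
  sw2 <- sw
  sw2$traces <- list(matrix(c(rep(0, 500), rep(2, 500)), ncol = 2),
                     sw$traces[[2]])
  expect_equal(average_trials(sw2)$traces[[1]], rep(1, 500))

  # residual noise of an n-trial mean is ~ sigma / sqrt(n)
  spec <- tuning_spec(peak_pd = 0, peak_nd = 0, noise_sd = 8,
                      n_trials = 16, sampling_rate = 2000, duration = 2)
  mt3 <- average_trials(gen_psc_sweeps(spec, directions = 0, seed = 4))
  expect_equal(stats::sd(mt3$traces[[1]]), 8 / sqrt(16), tolerance = 0.1)
})

test_that("baseline subtraction zeroes the baseline window and is idempotent", {
  t <- seq(0, 2, by = 1e-3)
  w <- response_windows(on_start = 0.6, off_start = 2.2)
  expect_equal(baseline_subtract(rep(5, length(t)), t, w),
               rep(0, length(t)))
  stepped <- ifelse(t < 1, 2, 12)
  out <- baseline_subtract(stepped, t, w)
  expect_equal(unique(out), c(0, 10))
  expect_equal(baseline_subtract(out, t, w), out, tolerance = 1e-12)
  expect_error(baseline_subtract(1:3, c(0, 0.1, 0.2),
                                 response_windows(baseline_width = 5)),
               "baseline window")
})

test_that("spike detection recovers noiseless synthetic trains exactly", {
  spec <- tuning_spec(peak_pd = 80, peak_nd = 20, noise_sd = 0,
                      n_trials = 3)
  sw <- gen_spike_sweeps(spec, directions = c(0, 180), seed = 4)
  for (d in seq_along(sw$directions)) {
    for (tr in seq_len(3)) {
      det <- detect_spikes(sw$traces[[d]][, tr], sw$sampling_rate,
                           threshold = 10)
      gt <- sw$ground_truth$spike_times[[d]][[tr]]
      expect_length(det, length(gt))
      if (length(gt)) {
        expect_lt(max(abs(det - gt)), 1 / sw$sampling_rate)
      }
    }
  }
  # flat trace: nothing to detect
  expect_length(detect_spikes(rep(0, 5000), 10000, threshold = 10), 0)
})

test_that("two crossings inside one refractory window yield one event", {
  fs <- 10000
  tr <- numeric(fs)
  wf <- dsokr:::spike_waveform(fs)
  for (ts in c(0.5, 0.5005)) {   # 0.5 ms apart
    idx <- round(ts * fs) + 1L - (wf$center - 1L)
    sel <- seq_along(wf$w) + idx - 1L
    tr[sel] <- tr[sel] + 50 * wf$w
  }
  expect_length(detect_spikes(tr, fs, threshold = 10, refractory = 1e-3), 1)
})

test_that("sliding-window maximum firing rate matches hand counts", {
  expect_equal(max_firing_rate(numeric(0), 0), 0)
  # spikes every 10 ms throughout: 10 per 100 ms window
  expect_equal(max_firing_rate(seq(0, 1.49, by = 0.01), 0), 100)
  # a single spike in a 100 ms window
  expect_equal(max_firing_rate(0.7, 0), 10)
  # spikes outside the response window are ignored
  expect_equal(max_firing_rate(c(0.1, 0.2), window_start = 1), 0)
  expect_error(max_firing_rate(0.5, 0, window_width = 0.05,
                               slide_width = 0.1), "slide_width")
})

test_that("peak extraction respects the window, mode and tie rule", {
  t <- seq(0, 4.5, by = 1e-3)
  w <- response_windows()
  bump <- function(center, h) h * exp(-(t - center)^2 / (2 * 0.05^2))
  ipsc <- bump(1.2, 600)
  pk <- peak_current(ipsc, t, w, "on", "IPSC")
  expect_equal(pk$magnitude, 600, tolerance = 1e-3)
  expect_equal(pk$time, 1.2, tolerance = 1e-2)
  expect_false(pk$low_amplitude)

  epsc <- -bump(1.2, 300)
  pk2 <- peak_current(epsc, t, w, "on", "EPSC")
  expect_equal(pk2$peak, -300, tolerance = 1e-3)
  expect_equal(pk2$magnitude, 300, tolerance = 1e-3)

  # bump outside the window: only noise remains, flagged low-amplitude
  set.seed(11)
  far <- bump(4.4, 600) + stats::rnorm(length(t), sd = 2)
  pk3 <- peak_current(far, t, w, "on", "IPSC")
  expect_lt(pk3$magnitude, 12)
  expect_true(pk3$low_amplitude)

  # ties go to the earliest sample
  flat2 <- ifelse(t >= 1 & t <= 2, 7, 0)
  expect_equal(peak_current(flat2, t, w, "on", "IPSC")$time, 1)
})

test_that("low-pass spike removal preserves the slow depolarization", {
  fs <- 2000
  t <- seq(0, 4.5 - 1 / fs, by = 1 / fs)
  w <- response_windows()
  slow <- 12 * alpha_shape(t, 0.9, 0.3)
  # spike-free: the filter passes the depolarization through
  out <- remove_spikes_and_peak_vm(slow, t, fs, w, "on")
  expect_equal(out$peak_mv, 12, tolerance = 0.1)
  # 1 ms spikes riding on top are attenuated away by a 50 Hz cutoff
  spiky <- slow
  for (ts in seq(1.0, 1.6, by = 0.05)) {
    spiky <- spiky + 60 * exp(-(t - ts)^2 / (2 * 0.0004^2))
  }
  out2 <- remove_spikes_and_peak_vm(spiky, t, fs, w, "on")
  expect_equal(out2$peak_mv, 12, tolerance = 1.2)   # within 10%
  # flat trace gives zero
  expect_equal(remove_spikes_and_peak_vm(rep(0, length(t)), t, fs, w,
                                         "on")$peak_mv, 0)
  expect_error(remove_spikes_and_peak_vm(slow, t, fs, w, "on",
                                         lowpass_cutoff = 2000), "Nyquist")
})

test_that("windowing and averaging commute with baseline subtraction", {
  spec <- tuning_spec(sampling_rate = 1000, duration = 4.5, noise_sd = 5,
                      n_trials = 3)
  sw <- gen_psc_sweeps(spec, directions = c(0, 90), seed = 6)
  w <- response_windows()
  mt <- average_trials(sw)
  a <- baseline_subtract(mt$traces[[1]], mt$t, w)
  # subtract per trial first, then average
  per_trial <- sapply(seq_len(3), function(k) {
    baseline_subtract(sw$traces[[1]][, k], sw$t, w)
  })
  expect_equal(a, rowMeans(per_trial), tolerance = 1e-12)
})
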