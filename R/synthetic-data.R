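#' Specification of a synthetic direction-tuned cell
#'
#' Describes the ground-truth tuning and kinetics used by [gen_psc_sweeps()]
#' and [gen_spike_sweeps()]. The tuning law is a von-Mises-shaped kernel
#' rescaled to 1 at the preferred direction and 0 at its opposite, so the
#' noiseless response peak at stimulus direction `theta` is
#' `peak_nd + (peak_pd - peak_nd) * f(theta - preferred_direction)`.
#'
#' @param preferred_direction Direction of maximal response, degrees in
#'   `[0, 360)`. For inhibitory currents this is the cell's null direction.
#' @param tuning_width Kernel half-width in degrees (angle at which the kernel
#'   falls to 0.5), in `(0, 180)`.
#' @param peak_pd,peak_nd Response amplitude at the preferred and opposite
#'   direction (pA for currents, Hz for spike rates, mV for potentials);
#'   `peak_pd >= peak_nd >= 0`.
#' @param on_latency,off_latency Onset of the ON and OFF transients, s.
#' @param kernel_tau Alpha-function time constant of the transients, s.
#' @param noise_sd Additive white-noise SD, same units as the peaks.
#' @param n_trials Trials per direction.
#' @param sampling_rate Sampling rate, Hz.
#' @param duration Sweep duration, s.
#' @return A `tuning_spec` list.
#' @export
tuning_spec <- function(preferred_direction = 0, tuning_width = 60,
                        peak_pd = 600, peak_nd = 100,
                        on_latency = 1.0, off_latency = 3.0,
                        kernel_tau = 0.15, noise_sd = 10, n_trials = 3,
                        sampling_rate = 10000, duration = 4.5) {
  if (tuning_width <= 0 || tuning_width >= 180) {
    stop_invalid("tuning_width must be in (0, 180), got %g", tuning_width)
  }
  if (peak_nd < 0 || peak_pd < peak_nd) {
    stop_invalid("need peak_pd >= peak_nd >= 0")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  structure(list(
    preferred_direction = wrap360(preferred_direction),
    tuning_width = tuning_width, peak_pd = peak_pd, peak_nd = peak_nd,
    on_latency = on_latency, off_latency = off_latency,
    kernel_tau = kernel_tau, noise_sd = noise_sd, n_trials = n_trials,
    sampling_rate = sampling_rate, duration = duration
  ), class = "tuning_spec")
}

#' Noiseless tuning-law peak at given stimulus directions
#'
#' @param spec A [tuning_spec()].
#' @param directions Stimulus directions, degrees.
#' @return Numeric vector of noiseless peak responses.
#' @export
tuning_law <- function(spec, directions) {
  kappa <- kappa_from_half_width(spec$tuning_width)
  f <- vm_kernel(circ_diff_deg(directions, spec$preferred_direction), kappa)
  spec$peak_nd + (spec$peak_pd - spec$peak_nd) * f
}

check_directions <- function(directions) {
  if (length(directions) == 0) stop_invalid("directions must be non-empty")
  if (any(directions < 0 | directions >= 360)) {
    stop_invalid("directions must lie in [0, 360)")
  }
  if (anyDuplicated(directions)) stop_invalid("directions must be unique")
  invisible(directions)
}

new_sweep_set <- function(directions, traces, t, sampling_rate,
                          recording_mode, units, holding_mv = NA_real_,
                          ground_truth = NULL) {
  structure(list(
    directions = directions, traces = traces, t = t,
    sampling_rate = sampling_rate, recording_mode = recording_mode,
    units = units, holding_mv = holding_mv, ground_truth = ground_truth
  ), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %d directions x %d trials, %d samples @ %g Hz (%s, %s)\n",
    length(x$directions), ncol(x$traces[[1]]), length(x$t),
    x$sampling_rate, x$recording_mode, x$units
  ))
  invisible(x)
}

#' Generate direction-tuned postsynaptic-current sweeps
#'
#' Emulates voltage-clamp recordings of moving-bar responses: per direction
#' and trial, an ON and an OFF alpha-function transient whose noiseless peak
#' follows the tuning law of `spec`, plus additive white noise. The stimulus
#' protocol mirrors the standard design of eight directions separated by 45
#' degrees with three repetitions each.
#'
#' @param spec A [tuning_spec()]; peaks in pA.
#' @param directions Stimulus directions, degrees in `[0, 360)`.
#' @param seed Integer seed; identical `(spec, directions, seed)` give
#'   bit-identical output.
#' @param recording_mode One of `"voltage_clamp"`, `"current_clamp"`.
#' @param holding_mv Holding potential recorded in the metadata, mV.
#' @return A `sweep_set`: per-direction `samples x trials` matrices, a time
#'   axis, sampling metadata, and a `ground_truth` element with the noiseless
#'   per-direction peaks and transient onsets.
#' @export
gen_psc_sweeps <- function(spec, directions = seq(0, 315, by = 45), seed = 1,
                           recording_mode = "voltage_clamp",
                           holding_mv = 0) {
  check_directions(directions)
  if (spec$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  t <- seq(0, spec$duration - 1 / spec$sampling_rate,
           by = 1 / spec$sampling_rate)
  peaks <- tuning_law(spec, directions)
  shape <- alpha_kernel(t, spec$on_latency, spec$kernel_tau) +
    alpha_kernel(t, spec$off_latency, spec$kernel_tau)
  traces <- with_seed(seed, {
    lapply(seq_along(directions), function(i) {
      clean <- peaks[i] * shape
      m <- matrix(
        clean + stats::rnorm(length(t) * spec$n_trials, sd = spec$noise_sd),
        nrow = length(t), ncol = spec$n_trials
      )
      colnames(m) <- paste0("trial", seq_len(spec$n_trials))
      m
    })
  })
  names(traces) <- sprintf("dir%03d", round(directions))
  units <- if (recording_mode == "current_clamp") "mV" else "pA"
  new_sweep_set(
    directions, traces, t, spec$sampling_rate, recording_mode, units,
    holding_mv,
    ground_truth = list(
      peaks = stats::setNames(peaks, names(traces)),
      on_latency = spec$on_latency, off_latency = spec$off_latency,
      kernel_tau = spec$kernel_tau, spec = spec
    )
  )
}

# Smooth unit-peak spike waveform: dominant positive lobe peaking exactly at
# the nominal spike time, followed by a shallower negative lobe.
spike_waveform <- function(sampling_rate, width_s = 2e-4) {
  half <- ceiling(4 * width_s * sampling_rate)
  tt <- seq(-half, half) / sampling_rate
  w <- exp(-tt^2 / (2 * width_s^2)) -
    0.6 * exp(-(tt - 2 * width_s)^2 / (2 * width_s^2))
  list(w = w, center = half + 1L)
}

#' Generate direction-tuned cell-attached spike sweeps
#'
#' Spike times are drawn from a dead-time-corrected Poisson (renewal)
#' process confined to the ON and OFF response windows (1.5 s each, starting
#' at the spec's latencies): inter-spike intervals are an absolute
#' refractory period plus an exponential interval at the compensated rate,
#' so the window-mean rate equals the tuning-law rate while no two spikes
#' fall closer than the refractory period (as in real trains). Each spike is
#' rendered as a smooth biphasic waveform whose positive peak sits at the
#' nominal spike time. Ground-truth spike times are returned alongside the
#' traces.
#'
#' @inheritParams gen_psc_sweeps
#' @param window_width Response-window width, s.
#' @param spike_amp Rendered spike amplitude, pA.
#' @param refractory_s Absolute refractory period, s (default 2 ms); rates
#'   must stay below `1 / refractory_s`.
#' @return A `sweep_set` (`recording_mode = "cell_attached"`); its
#'   `ground_truth$spike_times[[direction]][[trial]]` holds the sorted times.
#' @export
gen_spike_sweeps <- function(spec, directions = seq(0, 315, by = 45),
                             seed = 1, window_width = 1.5,
                             spike_amp = 50, refractory_s = 2e-3) {
  check_directions(directions)
  t <- seq(0, spec$duration - 1 / spec$sampling_rate,
           by = 1 / spec$sampling_rate)
  rates <- tuning_law(spec, directions)     # Hz within each window
  if (any(rates >= 1 / refractory_s)) {
    stop_invalid("rates must be below 1/refractory_s = %g Hz",
                 1 / refractory_s)
  }
  wf <- spike_waveform(spec$sampling_rate)
  windows <- rbind(
    c(spec$on_latency, spec$on_latency + window_width),
    c(spec$off_latency, spec$off_latency + window_width)
  )
  draw_window <- function(rate, w0, w1) {
    if (rate <= 0) return(numeric(0))
    lambda <- 1 / (1 / rate - refractory_s)  # compensated intensity
    times <- numeric(0)
    # equilibrium start: first wait is a plain exponential
    tt <- w0 + stats::rexp(1, lambda)
    while (tt < w1) {
      times <- c(times, tt)
      tt <- tt + refractory_s + stats::rexp(1, lambda)
    }
    times
  }
  out <- with_seed(seed, {
    lapply(seq_along(directions), function(i) {
      trial_times <- vector("list", spec$n_trials)
      m <- matrix(0, nrow = length(t), ncol = spec$n_trials)
      for (tr in seq_len(spec$n_trials)) {
        times <- numeric(0)
        for (w in seq_len(nrow(windows))) {
          times <- c(times, draw_window(rates[i], windows[w, 1],
                                        windows[w, 2]))
        }
        times <- sort(times)
        trial_times[[tr]] <- times
        for (ts in times) {
          idx <- round(ts * spec$sampling_rate) + 1L - (wf$center - 1L)
          sel <- seq_along(wf$w) + idx - 1L
          ok <- sel >= 1L & sel <= length(t)
          m[sel[ok], tr] <- m[sel[ok], tr] + spike_amp * wf$w[ok]
        }
        if (spec$noise_sd > 0) {
          m[, tr] <- m[, tr] + stats::rnorm(length(t), sd = spec$noise_sd)
        }
      }
      list(m = m, times = trial_times)
    })
  })
  traces <- lapply(out, `[[`, "m")
  names(traces) <- sprintf("dir%03d", round(directions))
  spike_times <- lapply(out, `[[`, "times")
  names(spike_times) <- names(traces)
  new_sweep_set(
    directions, traces, t, spec$sampling_rate, "cell_attached", "pA",
    ground_truth = list(
      rates = stats::setNames(rates, names(traces)),
      spike_times = spike_times,
      windows = windows, spec = spec
    )
  )
}

#' Specification of a synthetic IV dataset
#'
#' @param g_true Ground-truth conductance, nS (>= 0).
#' @param e_rev_true Ground-truth reversal potential, mV.
#' @param holds Holding potentials, mV (at least two distinct values).
#' @param noise_sd Peak-current noise SD, pA.
#' @param n_trials Trials per holding potential.
#' @return An `iv_sim_spec` list.
#' @export
iv_sim_spec <- function(g_true = 2, e_rev_true = -60,
                        holds = seq(-80, -40, by = 10),
                        noise_sd = 5, n_trials = 3) {
  if (length(unique(holds)) < 2) stop_invalid("need >= 2 distinct holds")
  if (g_true < 0) stop_invalid("g_true must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(
    g_true = g_true, e_rev_true = e_rev_true, holds = sort(holds),
    noise_sd = noise_sd, n_trials = n_trials
  ), class = "iv_sim_spec")
}

#' Generate trial-replicated IV peak currents
#'
#' Emulates the peak evoked currents of a connected pair held at a series of
#' potentials: `I = g_true * (V - e_rev_true) + noise`, per trial.
#'
#' @param spec An [iv_sim_spec()].
#' @param seed Integer seed.
#' @return List with `holds` (mV), `peaks` (holds x trials matrix, pA) and
#'   the ground-truth parameters.
#' @export
gen_iv_currents <- function(spec, seed = 1) {
  if (!inherits(spec, "iv_sim_spec")) stop_invalid("spec must be iv_sim_spec")
  clean <- spec$g_true * (spec$holds - spec$e_rev_true)
  peaks <- with_seed(seed, {
    matrix(
      rep(clean, spec$n_trials) +
        stats::rnorm(length(spec$holds) * spec$n_trials, sd = spec$noise_sd),
      nrow = length(spec$holds), ncol = spec$n_trials
    )
  })
  rownames(peaks) <- sprintf("%g", spec$holds)
  list(holds = spec$holds, peaks = peaks,
       ground_truth = list(g_true = spec$g_true,
                           e_rev_true = spec$e_rev_true,
                           clean = clean))
}

#' Specification of a synthetic eye-tracking session
#'
#' The latent eye follows the stimulus at `gain_true` (angular position
#' `gain_true * stim_velocity * t` along the stimulus axis), interrupted by
#' resetting saccades in the opposite direction with a minimum-jerk
#' displacement profile.
#'
#' @param gain_true Ground-truth slow-pursuit gain (dimensionless).
#' @param stim_direction One of `"anterior"` (0 deg), `"superior"` (90),
#'   `"posterior"` (180), `"inferior"` (270).
#' @param stim_velocity Stimulus speed, degrees/s.
#' @param duration Presentation duration, s.
#' @param fps Camera frame rate, frames/s.
#' @param saccade_rate Resetting-saccade rate, events/s.
#' @param saccade_amplitude Saccade amplitude, degrees.
#' @param saccade_peak_velocity Saccade peak velocity, degrees/s; must exceed
#'   the 30 deg/s classification threshold whenever `saccade_rate > 0`.
#' @param position_noise_sd Per-frame, per-camera tracking noise, degrees.
#' @param dropout_prob Probability that a frame's pupil markers all fall
#'   below the likelihood threshold.
#' @param scale_deg_per_px Rendering scale, degrees per pixel.
#' @param camera_sep_deg Angular separation of the two cameras, degrees.
#' @param pupil_radius_px Rendered pupil radius, pixels.
#' @return An `eye_sim_spec` list.
#' @export
eye_sim_spec <- function(gain_true = 0.7, stim_direction = "posterior",
                         stim_velocity = 2, duration = 45, fps = 100,
                         saccade_rate = 0.3, saccade_amplitude = 5,
                         saccade_peak_velocity = 200,
                         position_noise_sd = 0.05, dropout_prob = 0.05,
                         scale_deg_per_px = 0.1, camera_sep_deg = 12,
                         pupil_radius_px = 20) {
  stim_direction <- match.arg(stim_direction,
                              c("anterior", "superior", "posterior",
                                "inferior"))
  if (fps <= 0) stop_invalid("fps must be > 0")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop_invalid("dropout_prob must be in [0, 1)")
  }
  if (saccade_rate > 0 && saccade_peak_velocity <= 30) {
    stop_invalid("saccade_peak_velocity must exceed 30 deg/s")
  }
  structure(list(
    gain_true = gain_true, stim_direction = stim_direction,
    stim_velocity = stim_velocity, duration = duration, fps = fps,
    saccade_rate = saccade_rate, saccade_amplitude = saccade_amplitude,
    saccade_peak_velocity = saccade_peak_velocity,
    position_noise_sd = position_noise_sd, dropout_prob = dropout_prob,
    scale_deg_per_px = scale_deg_per_px, camera_sep_deg = camera_sep_deg,
    pupil_radius_px = pupil_radius_px
  ), class = "eye_sim_spec")
}

stim_axis_unit <- function(stim_direction) {
  theta <- c(anterior = 0, superior = 90, posterior = 180, inferior = 270)
  th <- deg2rad(theta[[stim_direction]])
  c(cos(th), sin(th))
}

# Minimum-jerk displacement profile on [0, 1], from 0 to 1.
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

new_marker_table <- function(pupil_x, pupil_y, pupil_lik,
                             refl_x, refl_y, refl_lik, fps, camera_id) {
  structure(list(
    pupil_x = pupil_x, pupil_y = pupil_y, pupil_lik = pupil_lik,
    refl_x = refl_x, refl_y = refl_y, refl_lik = refl_lik,
    fps = fps, camera_id = camera_id, n_frames = nrow(pupil_x)
  ), class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("<marker_table> camera %s: %d frames @ %g fps, 8+3 markers\n",
              x$camera_id, x$n_frames, x$fps))
  invisible(x)
}

#' Generate two-camera pupil-marker streams with ground truth
#'
#' Renders the latent angular eye trajectory of `spec` into two orthographic
#' camera pixel frames at a known degrees-per-pixel scale. Each frame carries
#' 8 pupil-boundary markers placed exactly on a circle around the latent
#' pupil center and 3 corneal-reflection markers at fixed pixel positions;
#' the two views' pupil centers are offset by the pixel distance equivalent
#' to the configured camera separation. Dropout frames carry pupil
#' likelihoods below any sensible threshold.
#'
#' @param spec An [eye_sim_spec()].
#' @param seed Integer seed.
#' @return List with `camera_a` and `camera_b` (`marker_table`s) and
#'   `ground_truth`: frame times, latent x/y position (degrees), saccade
#'   intervals (s), dropout frame indices, and the rendering scale.
#' @export
gen_eye_markers <- function(spec, seed = 1) {
  if (!inherits(spec, "eye_sim_spec")) stop_invalid("spec must be eye_sim_spec")
  n <- floor(spec$duration * spec$fps)
  if (n < 2) stop_invalid("duration * fps must give at least 2 frames")
  t <- (seq_len(n) - 1L) / spec$fps
  u <- stim_axis_unit(spec$stim_direction)

  sac_dur <- 1.875 * spec$saccade_amplitude / spec$saccade_peak_velocity
  with_seed(seed, {
    # saccade onsets: Poisson arrivals, non-overlapping
    onsets <- numeric(0)
    if (spec$saccade_rate > 0) {
      tt <- stats::rexp(1, spec$saccade_rate)
      while (tt + sac_dur < spec$duration) {
        onsets <- c(onsets, tt)
        tt <- tt + sac_dur + stats::rexp(1, spec$saccade_rate)
      }
    }
    # latent displacement along the stimulus axis: slow pursuit advances at
    # gain * stimulus velocity and is interrupted (paused) while a resetting
    # saccade executes in the opposite direction
    t_eff <- t
    for (on in onsets) {
      t_eff <- t_eff - pmin(pmax(t - on, 0), sac_dur)
    }
    s <- spec$gain_true * spec$stim_velocity * t_eff
    for (on in onsets) {
      s <- s - spec$saccade_amplitude * min_jerk((t - on) / sac_dur)
    }
    pos_x <- s * u[1]
    pos_y <- s * u[2]

    dropout <- which(stats::runif(n) < spec$dropout_prob)
    render <- function(camera_id, center_offset_px) {
      noise_x <- stats::rnorm(n, sd = spec$position_noise_sd)
      noise_y <- stats::rnorm(n, sd = spec$position_noise_sd)
      cx <- (pos_x + noise_x) / spec$scale_deg_per_px + center_offset_px[1]
      cy <- (pos_y + noise_y) / spec$scale_deg_per_px + center_offset_px[2]
      ang <- deg2rad(seq(0, 315, by = 45))
      pupil_x <- outer(cx, cos(ang), function(c, a) c + spec$pupil_radius_px * a)
      pupil_y <- outer(cy, sin(ang), function(c, a) c + spec$pupil_radius_px * a)
      pupil_lik <- matrix(stats::runif(n * 8, 0.95, 1), n, 8)
      pupil_lik[dropout, ] <- stats::runif(length(dropout) * 8, 0, 0.3)
      refl_pos <- rbind(c(40, 40), c(80, 40), c(60, 75)) +
        matrix(center_offset_px, 3, 2, byrow = TRUE)
      refl_x <- matrix(refl_pos[, 1], n, 3, byrow = TRUE)
      refl_y <- matrix(refl_pos[, 2], n, 3, byrow = TRUE)
      refl_lik <- matrix(stats::runif(n * 3, 0.95, 1), n, 3)
      new_marker_table(pupil_x, pupil_y, pupil_lik,
                       refl_x, refl_y, refl_lik, spec$fps, camera_id)
    }
    sep_px <- spec$camera_sep_deg / spec$scale_deg_per_px
    cam_a <- render("A", c(320, 240))
    cam_b <- render("B", c(320 + sep_px, 240))
    list(
      camera_a = cam_a, camera_b = cam_b,
      ground_truth = list(
        t = t, pos_x = pos_x, pos_y = pos_y,
        saccade_intervals = if (length(onsets)) {
          cbind(start = onsets, end = onsets + sac_dur)
        } else {
          matrix(numeric(0), 0, 2,
                 dimnames = list(NULL, c("start", "end")))
        },
        dropout_frames = dropout,
        scale_deg_per_px = spec$scale_deg_per_px,
        spec = spec
      )
    )
  })
}

#' Generate paired dendritic point fields with known hull overlap
#'
#' Two planar point clouds whose convex hulls are axis-aligned rectangles of
#' known area, horizontally offset so the hulls intersect in exactly
#' `overlap_frac` of the first rectangle's area.
#'
#' @param overlap_frac Fraction of hull A's area shared with hull B, `[0, 1]`.
#' @param seed Integer seed for the interior points.
#' @param width,height Rectangle dimensions, micrometres.
#' @param n_interior Interior points per cloud.
#' @return List with `points_a`, `points_b` (n x 2 matrices, micrometres) and
#'   `true_overlap_area` (square micrometres).
#' @export
gen_dendrite_fields <- function(overlap_frac, seed = 1,
                                width = 100, height = 80, n_interior = 200) {
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop_invalid("overlap_frac must be in [0, 1]")
  }
  shift <- width * (1 - overlap_frac) + if (overlap_frac == 0) width * 0.1 else 0
  with_seed(seed, {
    cloud <- function(x0) {
      corners <- cbind(x0 + c(0, width, width, 0), c(0, 0, height, height))
      inner <- cbind(x0 + stats::runif(n_interior, 0, width),
                     stats::runif(n_interior, 0, height))
      pts <- rbind(corners, inner)
      colnames(pts) <- c("x_um", "y_um")
      pts
    }
    list(points_a = cloud(0), points_b = cloud(shift),
         true_overlap_area = overlap_frac * width * height)
  })
}
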