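# Coope linear least-squares circle fit: solve x^2 + y^2 = 2ax + 2by + c.
coope_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  bb <- x^2 + y^2
  theta <- tryCatch(solve(crossprod(A), crossprod(A, bb)),
                    error = function(e) NULL)
  if (is.null(theta)) return(NULL)
  a <- theta[1]
  b <- theta[2]
  r2 <- theta[3] + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = c(a, b), radius = sqrt(r2))
}

#' Fit the pupil circle of one frame (Coope method)
#'
#' Markers below the likelihood threshold are discarded; the survivors are
#' fitted by the linear least-squares (Coope) circle via the substitution
#' `x^2 + y^2 = 2ax + 2by + c`, giving center `(a, b)` and radius
#' `sqrt(c + a^2 + b^2)`. Frames with fewer than three high-confidence
#' markers (the minimum defining a circle) are imputed: the previous
#' high-confidence center is carried forward.
#'
#' @param px,py,lik Length-8 pupil-marker coordinates (px) and likelihoods.
#' @param likelihood_threshold Minimum likelihood to keep a marker
#'   (default 0.9).
#' @param previous Previous non-imputed fit (for carry-forward), or `NULL`.
#' @return A `pupil_fit`: `center`, `radius` (px; `NA` when imputed),
#'   `n_markers_used`, `imputed`. With no usable markers and no previous
#'   fit, an unrecoverable-trace error is raised.
#' @export
fit_pupil_circle <- function(px, py, lik, likelihood_threshold = 0.9,
                             previous = NULL) {
  keep <- which(lik >= likelihood_threshold)
  if (length(keep) >= 3) {
    fit <- coope_fit(px[keep], py[keep])
    if (!is.null(fit)) {
      return(structure(list(center = fit$center, radius = fit$radius,
                            n_markers_used = length(keep), imputed = FALSE),
                       class = "pupil_fit"))
    }
  }
  if (is.null(previous)) {
    stop_invalid("unrecoverable trace: no prior high-confidence pupil fit")
  }
  structure(list(center = previous$center, radius = NA_real_,
                 n_markers_used = length(keep), imputed = TRUE),
            class = "pupil_fit")
}

#' Fit pupil circles for every frame of a marker table
#'
#' Applies [fit_pupil_circle()] per frame with last-known-position
#' imputation; leading frames before the first valid fit are back-filled
#' from it.
#'
#' @param markers A `marker_table`.
#' @param likelihood_threshold Minimum marker likelihood (default 0.9).
#' @return Data frame: `frame`, `cx`, `cy`, `radius`, `n_markers`,
#'   `imputed`.
#' @export
fit_pupil_circles <- function(markers, likelihood_threshold = 0.9) {
  n <- markers$n_frames
  cx <- cy <- radius <- rep(NA_real_, n)
  n_used <- integer(n)
  imputed <- rep(TRUE, n)
  prev <- NULL
  for (k in seq_len(n)) {
    keep <- which(markers$pupil_lik[k, ] >= likelihood_threshold)
    n_used[k] <- length(keep)
    fit <- NULL
    if (length(keep) >= 3) {
      fit <- coope_fit(markers$pupil_x[k, keep], markers$pupil_y[k, keep])
    }
    if (!is.null(fit)) {
      cx[k] <- fit$center[1]
      cy[k] <- fit$center[2]
      radius[k] <- fit$radius
      imputed[k] <- FALSE
      prev <- fit
    } else if (!is.null(prev)) {
      cx[k] <- prev$center[1]
      cy[k] <- prev$center[2]
    }
  }
  if (all(imputed)) {
    stop_invalid("unrecoverable trace: no frame has >= 3 usable markers")
  }
  first <- which(!imputed)[1]
  if (first > 1) {
    cx[1:(first - 1)] <- cx[first]
    cy[1:(first - 1)] <- cy[first]
  }
  data.frame(frame = seq_len(n), cx = cx, cy = cy, radius = radius,
             n_markers = n_used, imputed = imputed)
}

#' Reference a pupil center to the corneal-reflection point
#'
#' The corneal reference is the mean of the high-confidence reflection
#' markers; subtracting it makes the pupil position invariant to global
#' translation of the frame (head/camera shifts).
#'
#' @param center Pupil center `c(x, y)`, px.
#' @param rx,ry,lik Reflection-marker coordinates and likelihoods (length 3).
#' @param likelihood_threshold Minimum likelihood (default 0.9).
#' @param previous_reference Carry-forward reference when no reflection is
#'   high-confidence, or `NULL`.
#' @return List: `relative` (center minus reference, px), `reference`,
#'   `imputed_reference`.
#' @export
reference_to_cornea <- function(center, rx, ry, lik,
                                likelihood_threshold = 0.9,
                                previous_reference = NULL) {
  keep <- which(lik >= likelihood_threshold)
  if (length(keep) >= 1) {
    ref <- c(mean(rx[keep]), mean(ry[keep]))
    imput <- FALSE
  } else if (!is.null(previous_reference)) {
    ref <- previous_reference
    imput <- TRUE
  } else {
    stop_invalid("no high-confidence corneal reflection and no prior reference")
  }
  list(relative = center - ref, reference = ref, imputed_reference = imput)
}

reference_centers <- function(fits, markers, likelihood_threshold = 0.9) {
  n <- nrow(fits)
  rel <- matrix(NA_real_, n, 2)
  prev_ref <- NULL
  for (k in seq_len(n)) {
    r <- reference_to_cornea(
      c(fits$cx[k], fits$cy[k]),
      markers$refl_x[k, ], markers$refl_y[k, ], markers$refl_lik[k, ],
      likelihood_threshold, previous_reference = prev_ref
    )
    rel[k, ] <- r$relative
    prev_ref <- r$reference
  }
  rel
}

#' Calibrate the degrees-per-pixel scale from two cameras
#'
#' The two cameras view the eye from directions a known angular separation
#' apart (12 degrees by default), so the mean pixel distance between the
#' pupil centers seen by the two cameras corresponds to that separation:
#' `scale = separation_deg / mean(distance_px)`. Calibration is repeated per
#' stimulus presentation.
#'
#' @param centers_a,centers_b `n x 2` matrices of pupil centers, px, on the
#'   same frame grid.
#' @param separation_deg Known angular camera separation, degrees
#'   (default 12).
#' @param valid Optional logical vector marking frames usable in both
#'   cameras.
#' @return Scale, degrees per pixel.
#' @export
calibrate_scale <- function(centers_a, centers_b, separation_deg = 12,
                            valid = NULL) {
  if (nrow(centers_a) != nrow(centers_b)) {
    stop_invalid("camera streams must share a frame grid")
  }
  if (is.null(valid)) valid <- rep(TRUE, nrow(centers_a))
  if (!any(valid)) stop_invalid("no overlapping high-confidence frames")
  d <- sqrt(rowSums((centers_a[valid, , drop = FALSE] -
                       centers_b[valid, , drop = FALSE])^2))
  md <- mean(d)
  if (!is.finite(md) || md <= 0) {
    stop_invalid("invalid calibration: zero mean inter-camera distance")
  }
  separation_deg / md
}

#' Build a calibrated, smoothed angular eye trace
#'
#' Corneal-referenced pixel centers are scaled to degrees, low-confidence
#' frames are last-value imputed (already handled upstream by the circle
#' fitter), positions are Gaussian-smoothed, and velocity is the per-frame
#' gradient (central differences) times the frame rate.
#'
#' @param rel_centers `n x 2` matrix of corneal-referenced centers, px.
#' @param imputed Logical per frame: pupil position carried forward.
#' @param scale Degrees per pixel.
#' @param fps Frames/s.
#' @param gaussian_sigma Smoothing SD in frames (default 2; 20 ms at
#'   100 fps); applied to position, not velocity.
#' @return An `eye_trace` data frame: `t`, `x_deg`, `y_deg`, `vx`, `vy`,
#'   `v_total` (degrees/s), `imputed`.
#' @export
build_eye_trace <- function(rel_centers, imputed, scale, fps,
                            gaussian_sigma = 2) {
  n <- nrow(rel_centers)
  if (n < 2) stop_invalid("need >= 2 frames")
  x_raw <- rel_centers[, 1] * scale
  y_raw <- rel_centers[, 2] * scale
  x <- gaussian_smooth(x_raw, gaussian_sigma)
  y <- gaussian_smooth(y_raw, gaussian_sigma)
  vx <- gradient1(x) * fps
  vy <- gradient1(y) * fps
  out <- data.frame(
    t = (seq_len(n) - 1L) / fps, x_deg = x, y_deg = y,
    x_raw = x_raw, y_raw = y_raw,
    vx = vx, vy = vy, v_total = sqrt(vx^2 + vy^2),
    imputed = imputed
  )
  class(out) <- c("eye_trace", "data.frame")
  out
}

#' Classify frames as slow pursuit, saccade, or low-confidence
#'
#' Frames whose total pupil velocity exceeds the threshold are saccades or
#' fast movements; frames whose pupil position was imputed are
#' low-confidence; the rest are slow pursuit.
#'
#' @param trace An `eye_trace`.
#' @param threshold Saccade velocity threshold, degrees/s (default 30).
#' @return Factor of labels `slow` / `saccade` / `low_confidence`.
#' @export
classify_frames <- function(trace, threshold = 30) {
  lab <- ifelse(trace$imputed, "low_confidence",
                ifelse(trace$v_total > threshold, "saccade", "slow"))
  factor(lab, levels = c("slow", "saccade", "low_confidence"))
}

#' Cumulative slow-pursuit displacement along the stimulus axis
#'
#' Sums per-frame displacement components along the stimulus axis after
#' excluding saccadic frames plus a one-frame margin on each side of every
#' saccade run. Classification uses the Gaussian-smoothed velocity, but the
#' integral is taken over the unsmoothed (imputed) positions: smoothing
#' redistributes saccadic displacement into neighbouring slow frames,
#' whereas on the raw trace the saccade's displacement is confined to the
#' frames the classifier already labels, so excluding those frames removes
#' exactly the saccadic component. Low-confidence frames carry no raw
#' displacement of their own under last-value imputation — the tracking
#' catch-up lands on the next high-confidence frame — so by default only
#' saccadic displacement is dropped; set `include_low_confidence = FALSE`
#' to drop low-confidence frames from the integral as well. Positive values
#' mean pursuit in the stimulus direction.
#'
#' @param trace An `eye_trace`.
#' @param labels Labels from [classify_frames()].
#' @param stim_direction `"anterior"`, `"superior"`, `"posterior"` or
#'   `"inferior"`.
#' @param saccade_margin Frames excluded on each side of a saccade run
#'   (default 1).
#' @param include_low_confidence Keep low-confidence frames' (zero, imputed)
#'   displacement in the integral (default TRUE).
#' @return Signed cumulative displacement, degrees. Zero usable frames give
#'   0 with a warning.
#' @export
cumulative_slow_pursuit <- function(trace, labels, stim_direction,
                                    saccade_margin = 1,
                                    include_low_confidence = TRUE) {
  u <- stim_axis_unit(stim_direction)
  n <- nrow(trace)
  bad <- labels == "saccade"
  if (!include_low_confidence) bad <- bad | labels == "low_confidence"
  if (saccade_margin > 0) {
    sac <- which(labels == "saccade")
    for (m in seq_len(saccade_margin)) {
      bad[pmax(sac - m, 1L)] <- TRUE
      bad[pmin(sac + m, n)] <- TRUE
    }
  }
  keep <- which(!bad)
  if (!length(keep)) {
    warning("no slow-pursuit frames")
    return(0)
  }
  x <- if ("x_raw" %in% names(trace)) trace$x_raw else trace$x_deg
  y <- if ("y_raw" %in% names(trace)) trace$y_raw else trace$y_deg
  dx <- c(0, diff(x))
  dy <- c(0, diff(y))
  sum(dx[keep] * u[1] + dy[keep] * u[2])
}

#' Optokinetic reflex gain
#'
#' Gain is the cumulative slow-pursuit displacement divided by the total
#' stimulus displacement (`velocity x duration`); positive when the eye
#' follows the stimulus, negative when net slow movement opposes it.
#'
#' @param cumulative_deg Signed slow-pursuit displacement, degrees.
#' @param stim_velocity Stimulus speed, degrees/s (> 0).
#' @param stim_duration Presentation duration, s (> 0).
#' @param axis `"horizontal"` or `"vertical"` label carried through.
#' @return A `gain_result`: `axis`, `cumulative_slow_deg`, `stimulus_deg`,
#'   `gain`.
#' @export
okr_gain <- function(cumulative_deg, stim_velocity, stim_duration,
                     axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stim_deg <- stim_velocity * stim_duration
  if (!is.finite(stim_deg) || stim_deg <= 0) {
    stop_invalid("stimulus displacement must be positive")
  }
  structure(list(axis = axis, cumulative_slow_deg = cumulative_deg,
                 stimulus_deg = stim_deg,
                 gain = cumulative_deg / stim_deg),
            class = "gain_result")
}

#' Full eye-tracking pipeline: markers to OKR gain
#'
#' Fits pupil circles in both cameras, references them to the corneal
#' reflections, calibrates the angular scale from the known inter-camera
#' separation, builds the smoothed eye trace from whichever camera offers
#' more high-confidence frames, segments saccades, and computes the gain.
#'
#' @param camera_a,camera_b `marker_table`s for the two cameras.
#' @param stim_direction Stimulus direction label.
#' @param stim_velocity Stimulus speed, degrees/s.
#' @param stim_duration Presentation duration, s (default: trace length).
#' @param likelihood_threshold Marker likelihood cutoff (default 0.9).
#' @param separation_deg Camera separation, degrees (default 12).
#' @param gaussian_sigma Position-smoothing SD, frames (default 2).
#' @param saccade_threshold Degrees/s (default 30).
#' @param camera Force `"A"` or `"B"`, or `"auto"` (default).
#' @return List: `gain_result`, `trace`, `labels`, `scale_deg_per_px`,
#'   `camera_used`, `pct_saccade`, `pct_low_confidence`.
#' @export
okr_pipeline <- function(camera_a, camera_b, stim_direction,
                         stim_velocity = 2, stim_duration = NULL,
                         likelihood_threshold = 0.9, separation_deg = 12,
                         gaussian_sigma = 2, saccade_threshold = 30,
                         camera = c("auto", "A", "B")) {
  camera <- match.arg(camera)
  fits_a <- fit_pupil_circles(camera_a, likelihood_threshold)
  fits_b <- fit_pupil_circles(camera_b, likelihood_threshold)
  rel_a <- reference_centers(fits_a, camera_a, likelihood_threshold)
  rel_b <- reference_centers(fits_b, camera_b, likelihood_threshold)
  raw_a <- cbind(fits_a$cx, fits_a$cy)
  raw_b <- cbind(fits_b$cx, fits_b$cy)
  valid <- !fits_a$imputed & !fits_b$imputed
  scale <- calibrate_scale(raw_a, raw_b, separation_deg, valid = valid)
  use_a <- switch(camera,
                  auto = sum(!fits_a$imputed) >= sum(!fits_b$imputed),
                  A = TRUE, B = FALSE)
  fits <- if (use_a) fits_a else fits_b
  rel <- if (use_a) rel_a else rel_b
  fps <- if (use_a) camera_a$fps else camera_b$fps
  trace <- build_eye_trace(rel, fits$imputed, scale, fps, gaussian_sigma)
  labels <- classify_frames(trace, saccade_threshold)
  if (is.null(stim_duration)) stim_duration <- nrow(trace) / fps
  cum <- cumulative_slow_pursuit(trace, labels, stim_direction)
  axis <- if (stim_direction %in% c("anterior", "posterior")) {
    "horizontal"
  } else {
    "vertical"
  }
  gr <- okr_gain(cum, stim_velocity, stim_duration, axis)
  list(gain_result = gr, trace = trace, labels = labels,
       scale_deg_per_px = scale,
       camera_used = if (use_a) "A" else "B",
       pct_saccade = 100 * mean(labels == "saccade"),
       pct_low_confidence = 100 * mean(labels == "low_confidence"))
}
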