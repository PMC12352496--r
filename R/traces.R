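#' ON/OFF response windows
#'
#' The stimulus evokes an ON response as the bar enters the receptive field
#' and an OFF response as it leaves; each is analysed within its own 1.5 s
#' window, with the baseline taken from the first 500 ms of the sweep.
#'
#' @param on_start,off_start Window onsets, s; the windows must not overlap.
#' @param width Window width, s (default 1.5).
#' @param baseline_width Baseline interval `[0, baseline_width]`, s
#'   (default 0.5).
#' @return A `response_windows` list.
#' @export
response_windows <- function(on_start = 0.75, off_start = 2.75,
                             width = 1.5, baseline_width = 0.5) {
  if (on_start + width > off_start && off_start + width > on_start) {
    stop_invalid("ON and OFF windows must be disjoint")
  }
  structure(list(on_start = on_start, off_start = off_start,
                 width = width, baseline_width = baseline_width),
            class = "response_windows")
}

window_bounds <- function(windows, pathway = c("on", "off")) {
  pathway <- match.arg(pathway)
  start <- if (pathway == "on") windows$on_start else windows$off_start
  c(start, start + windows$width)
}

#' Average sweeps across trials, per direction
#'
#' @param sweeps A `sweep_set`.
#' @return A `mean_traces` list: per-direction mean trace vectors, the time
#'   axis, and the trial count.
#' @export
average_trials <- function(sweeps) {
  lens <- unique(vapply(sweeps$traces, nrow, 1L))
  if (length(lens) != 1L) stop_invalid("ragged trace lengths")
  means <- lapply(sweeps$traces, rowMeans)
  structure(list(
    directions = sweeps$directions, traces = means, t = sweeps$t,
    sampling_rate = sweeps$sampling_rate, units = sweeps$units,
    recording_mode = sweeps$recording_mode,
    n_trials = ncol(sweeps$traces[[1]])
  ), class = "mean_traces")
}

#' Subtract the baseline estimated from the start of a trace
#'
#' @param trace Numeric trace.
#' @param t Time axis, s (same length as `trace`).
#' @param windows A [response_windows()]; the mean over
#'   `[0, baseline_width]` is removed.
#' @return Baseline-subtracted trace; its mean over the baseline interval is
#'   zero to float precision, so the operation is idempotent.
#' @export
baseline_subtract <- function(trace, t, windows = response_windows()) {
  sel <- t <= windows$baseline_width
  if (!any(sel) || all(sel)) {
    stop_invalid("baseline window must cover part (not all) of the trace")
  }
  trace - mean(trace[sel])
}

#' Detect spikes on a band-pass filtered trace
#'
#' The trace is zero-phase band-pass filtered (Butterworth, forward-backward)
#' and threshold crossings are reduced to one event per refractory window;
#' each event is timed at the local extremum of the filtered trace.
#'
#' @param trace Cell-attached current trace.
#' @param sampling_rate Hz; must exceed twice `band[2]`.
#' @param band Pass band, Hz (default `c(80, 2000)`).
#' @param threshold Detection threshold on the filtered trace; `NULL` uses
#'   5 x MAD of the filtered trace (falling back to half the maximum
#'   absolute value when the MAD is zero, as on noiseless data).
#' @param polarity `"positive"` or `"negative"` crossings.
#' @param refractory Minimum event separation, s.
#' @return Sorted spike times, s.
#' @export
detect_spikes <- function(trace, sampling_rate, band = c(80, 2000),
                          threshold = NULL,
                          polarity = c("positive", "negative"),
                          refractory = 1e-3) {
  polarity <- match.arg(polarity)
  if (sampling_rate <= 2 * band[2]) {
    stop_invalid("sampling_rate must exceed twice the upper band edge")
  }
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "pass")
  f <- signal::filtfilt(bf, trace)
  if (polarity == "negative") f <- -f
  if (is.null(threshold)) {
    threshold <- 5 * stats::mad(f)
    if (threshold == 0) threshold <- max(abs(f)) / 2
  }
  if (threshold <= 0) return(numeric(0))
  above <- f > threshold
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rises)) return(numeric(0))
  ref_n <- max(1L, round(refractory * sampling_rate))
  times <- numeric(0)
  last <- -Inf
  for (r in rises) {
    if (r - last < ref_n) next
    seg <- r:min(r + ref_n, length(f))
    pk <- seg[which.max(f[seg])]
    times <- c(times, (pk - 1) / sampling_rate)
    last <- r
  }
  sort(times)
}

#' Maximum firing rate in a response window via a sliding window
#'
#' The maximum over all sliding-window placements (hop of one sample, i.e.
#' all continuous placements) of spike count divided by window width,
#' restricted to the response window.
#'
#' @param spike_times Sorted spike times, s.
#' @param window_start Response-window onset, s.
#' @param window_width Response-window width, s (default 1.5).
#' @param slide_width Sliding-window width, s (default 0.1); must not exceed
#'   `window_width`.
#' @return Maximum rate, Hz; 0 when no spikes fall in the window.
#' @export
max_firing_rate <- function(spike_times, window_start, window_width = 1.5,
                            slide_width = 0.1) {
  if (slide_width > window_width) {
    stop_invalid("slide_width must not exceed window_width")
  }
  s <- sort(spike_times)
  s <- s[s >= window_start & s < window_start + window_width]
  if (!length(s)) return(0)
  # max over continuous placements = max over windows starting at a spike;
  # half-open [t, t + w) with a 1 ns guard against float round-off
  counts <- vapply(seq_along(s), function(i) {
    sum(s >= s[i] & s - s[i] < slide_width - 1e-9)
  }, 1L)
  max(counts) / slide_width
}

#' Peak current within a response window
#'
#' IPSCs (outward at a depolarised hold) are taken as the maximum, EPSCs
#' (inward) as the minimum, within the window of a baseline-subtracted mean
#' trace. Ties go to the earliest sample. A peak smaller than 4 x the robust
#' noise estimate from the baseline interval is flagged `low_amplitude`.
#'
#' @param trace Baseline-subtracted mean trace, pA.
#' @param t Time axis, s.
#' @param windows A [response_windows()].
#' @param pathway `"on"` or `"off"`.
#' @param mode `"IPSC"` (max) or `"EPSC"` (min).
#' @return List: `peak` (signed, pA), `magnitude` (pA), `time` (s),
#'   `low_amplitude` (logical).
#' @export
peak_current <- function(trace, t, windows, pathway = c("on", "off"),
                         mode = c("IPSC", "EPSC")) {
  pathway <- match.arg(pathway)
  mode <- match.arg(mode)
  b <- window_bounds(windows, pathway)
  sel <- which(t >= b[1] & t <= b[2])
  if (!length(sel)) stop_invalid("window lies outside the trace")
  seg <- trace[sel]
  i <- if (mode == "IPSC") which.max(seg) else which.min(seg)
  peak <- seg[i]
  noise <- stats::mad(trace[t <= windows$baseline_width])
  list(peak = peak, magnitude = abs(peak), time = t[sel[i]],
       low_amplitude = abs(peak) < 4 * noise)
}

#' Peak subthreshold depolarization after spike removal
#'
#' Low-pass filters a baseline-subtracted current-clamp trace (zero-phase
#' Butterworth) to remove spikes, then takes the maximum within the window.
#'
#' @param trace Baseline-subtracted membrane-potential trace, mV.
#' @param t Time axis, s.
#' @param sampling_rate Hz.
#' @param windows A [response_windows()].
#' @param pathway `"on"` or `"off"`.
#' @param lowpass_cutoff Hz; must be below the Nyquist frequency.
#' @return List: `peak_mv`, `time`.
#' @export
remove_spikes_and_peak_vm <- function(trace, t, sampling_rate, windows,
                                      pathway = c("on", "off"),
                                      lowpass_cutoff = 50) {
  pathway <- match.arg(pathway)
  if (lowpass_cutoff >= sampling_rate / 2) {
    stop_invalid("lowpass_cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(2, lowpass_cutoff / (sampling_rate / 2), type = "low")
  f <- signal::filtfilt(bf, trace)
  b <- window_bounds(windows, pathway)
  sel <- which(t >= b[1] & t <= b[2])
  if (!length(sel)) stop_invalid("window lies outside the trace")
  i <- which.max(f[sel])
  list(peak_mv = f[sel[i]], time = t[sel[i]])
}

#' Per-direction peak table from a sweep set
#'
#' Composes [average_trials()], [baseline_subtract()] and the per-mode peak
#' extractor into one row per (direction, pathway).
#'
#' @param sweeps A `sweep_set` (voltage clamp).
#' @param windows A [response_windows()].
#' @param mode `"IPSC"` or `"EPSC"`.
#' @return Data frame: `direction_deg`, `pathway`, `peak`, `magnitude`,
#'   `time_s`, `low_amplitude`.
#' @export
peak_table <- function(sweeps, windows = response_windows(),
                       mode = c("IPSC", "EPSC")) {
  mode <- match.arg(mode)
  mt <- average_trials(sweeps)
  rows <- list()
  for (i in seq_along(mt$directions)) {
    tr <- baseline_subtract(mt$traces[[i]], mt$t, windows)
    for (pw in c("on", "off")) {
      pk <- peak_current(tr, mt$t, windows, pathway = pw, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        direction_deg = mt$directions[i], pathway = pw,
        peak = pk$peak, magnitude = pk$magnitude, time_s = pk$time,
        low_amplitude = pk$low_amplitude
      )
    }
  }
  do.call(rbind, rows)
}
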