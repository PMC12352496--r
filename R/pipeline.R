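#' Default pipeline configuration
#'
#' One nested list collecting every tunable parameter of the pipeline with
#' its documented default: response windows, spike detection, sliding-window
#' width, membrane-model constants, IV junction correction and QC gate, and
#' the eye-tracking thresholds. Serialisable to/from JSON with
#' [write_config()] / [read_config()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    windows = list(on_start = 0.75, off_start = 2.75, width = 1.5,
                   baseline_width = 0.5),
    traces = list(band_low_hz = 80, band_high_hz = 2000,
                  spike_threshold = NULL, spike_polarity = "positive",
                  refractory_s = 1e-3, slide_width_s = 0.1,
                  lowpass_cutoff_hz = 50),
    model = list(cm_pf = 80, g_leak_ns = 3.3, e_leak_mv = -55,
                 e_exc_mv = 0, e_inh_mv = -60, dt_ms = 0.1,
                 hold_exc_mv = -60, hold_inh_mv = 0),
    paired = list(junction_mv = -10, r2_gate = 0.80,
                  hold_grid_mv = seq(-80, -40, by = 10)),
    okr = list(likelihood_threshold = 0.9, separation_deg = 12,
               gaussian_sigma_frames = 2, saccade_threshold_dps = 30,
               saccade_margin_frames = 1, fps = 100,
               stim_velocity_dps = 2, stim_duration_s = 45,
               spatial_frequency_cpd = 0.15, contrast = 1.0),
    stimulus = list(n_directions = 8, direction_step_deg = 45, n_trials = 3,
                    sampling_rate_hz = 10000, sweep_duration_s = 4.5)
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config Nested list as from [default_config()].
#' @param path File path.
#' @return `read_config` returns the nested list; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

windows_from_config <- function(config) {
  response_windows(config$windows$on_start, config$windows$off_start,
                   config$windows$width, config$windows$baseline_width)
}

params_from_config <- function(config) {
  m <- config$model
  model_params(cm = m$cm_pf, g_leak = m$g_leak_ns, e_leak = m$e_leak_mv,
               e_exc = m$e_exc_mv, e_inh = m$e_inh_mv, dt = m$dt_ms)
}

# One synthetic cell taken through tuning + conductance simulation.
analyse_cell <- function(ipsc_spec, epsc_spec, seed, config,
                         directions = seq(0, 315, by = 45)) {
  windows <- windows_from_config(config)
  params <- params_from_config(config)
  ipsc <- gen_psc_sweeps(ipsc_spec, directions, seed = seed,
                         holding_mv = config$model$hold_inh_mv)
  epsc_raw <- gen_psc_sweeps(epsc_spec, directions, seed = seed + 1L,
                             holding_mv = config$model$hold_exc_mv)
  # EPSCs are inward (negative) at the chloride reversal
  epsc <- epsc_raw
  epsc$traces <- lapply(epsc_raw$traces, function(m) -m)

  pk_i <- peak_table(ipsc, windows, mode = "IPSC")
  pk_e <- peak_table(epsc, windows, mode = "EPSC")
  on_i <- pk_i[pk_i$pathway == "on", ]
  on_e <- pk_e[pk_e$pathway == "on", ]
  curve_i <- tuning_curve(on_i$direction_deg, on_i$magnitude,
                          pathway = "on", metric = "IPSC")
  nd_pd <- null_and_preferred_from_inhibition(curve_i, "argmax")
  asym <- asymmetric_inhibition(nd_pd$nd_resp, nd_pd$pd_resp)

  # conductance extraction + membrane simulation per direction
  mt_i <- average_trials(ipsc)
  mt_e <- average_trials(epsc)
  dt_s <- config$model$dt_ms / 1000
  keep <- seq(1, length(mt_i$t), by = max(1L, round(dt_s * ipsc$sampling_rate)))
  t_ms <- mt_i$t[keep] * 1000
  sims <- lapply(seq_along(directions), function(i) {
    cond <- extract_conductance(
      baseline_subtract(mt_e$traces[[i]], mt_e$t, windows)[keep],
      baseline_subtract(mt_i$traces[[i]], mt_i$t, windows)[keep],
      t_ms, params,
      hold_exc = config$model$hold_exc_mv,
      hold_inh = config$model$hold_inh_mv,
      direction = directions[i]
    )
    simulate_vm(cond, params)
  })
  vm_curve <- simulated_tuning(sims, windows, pathway = "on")
  vm_nd <- vm_curve$magnitudes[match(nd_pd$nd_angle, vm_curve$angles)]
  vm_pd <- vm_curve$magnitudes[match(wrap360(nd_pd$nd_angle + 180),
                                     vm_curve$angles)]
  sim_dsi <- if (isTRUE(vm_pd + vm_nd > 0)) dsi(vm_pd, vm_nd) else NA_real_
  list(
    ipsc_curve = curve_i, epsc_curve = tuning_curve(
      on_e$direction_deg, on_e$magnitude, pathway = "on", metric = "EPSC"
    ),
    nd_pd = nd_pd, asymmetric_inhibition_pa = asym,
    vm_curve = vm_curve, simulated_dsi = sim_dsi
  )
}

#' End-to-end demonstration on two synthetic cohorts
#'
#' Generates an "intact" cohort (strongly asymmetric inhibition, full
#' excitation) and a "disrupted" cohort (near-symmetric inhibition, reduced
#' excitation), runs each cell through peak extraction, inhibitory tuning,
#' conductance extraction and membrane simulation, and runs the eye-tracking
#' pipeline on matched synthetic sessions in which the disrupted group loses
#' horizontal but retains vertical gain. The report is deterministic given
#' `seed`.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per cohort.
#' @param n_eye_trials Eye presentations per axis and cohort.
#' @param eye_duration Presentation duration, s (default 45).
#' @param config Pipeline configuration (default [default_config()]).
#' @return List of data frames: `cells` (per-cell tuning and simulated DSI)
#'   and `okr` (per-presentation gains), plus the group summary `summary`.
#' @export
end_to_end_demo <- function(seed = 1, n_cells = 3, n_eye_trials = 2,
                            eye_duration = 45, config = default_config()) {
  cohorts <- list(
    intact = list(ipsc = tuning_spec(preferred_direction = 0,
                                     peak_pd = 600, peak_nd = 100),
                  epsc = tuning_spec(preferred_direction = 180,
                                     peak_pd = 320, peak_nd = 260),
                  gain_h = 0.7, gain_v = 0.7),
    disrupted = list(ipsc = tuning_spec(preferred_direction = 0,
                                        peak_pd = 380, peak_nd = 330),
                     epsc = tuning_spec(preferred_direction = 180,
                                        peak_pd = 180, peak_nd = 150),
                     gain_h = 0.05, gain_v = 0.7)
  )
  cells <- list()
  okr <- list()
  for (g in names(cohorts)) {
    co <- cohorts[[g]]
    for (cell in seq_len(n_cells)) {
      cell_seed <- seed + 1000L * match(g, names(cohorts)) + 10L * cell
      res <- analyse_cell(co$ipsc, co$epsc, cell_seed, config)
      cells[[length(cells) + 1L]] <- data.frame(
        cohort = g, cell = cell,
        nd_deg = res$nd_pd$nd_angle, pd_deg = res$nd_pd$pd_angle,
        ipsc_dsi = res$nd_pd$dsi,
        asymmetric_inhibition_pa = res$asymmetric_inhibition_pa,
        simulated_dsi = res$simulated_dsi
      )
    }
    for (axis in c("horizontal", "vertical")) {
      dirn <- if (axis == "horizontal") "posterior" else "superior"
      gt <- if (axis == "horizontal") co$gain_h else co$gain_v
      for (tr in seq_len(n_eye_trials)) {
        eye_seed <- seed + 5000L * match(g, names(cohorts)) +
          100L * match(axis, c("horizontal", "vertical")) + tr
        spec <- eye_sim_spec(gain_true = gt, stim_direction = dirn,
                             duration = eye_duration,
                             fps = config$okr$fps,
                             stim_velocity = config$okr$stim_velocity_dps)
        sim <- gen_eye_markers(spec, seed = eye_seed)
        res <- okr_pipeline(
          sim$camera_a, sim$camera_b, dirn,
          stim_velocity = spec$stim_velocity,
          stim_duration = spec$duration,
          likelihood_threshold = config$okr$likelihood_threshold,
          separation_deg = config$okr$separation_deg,
          gaussian_sigma = config$okr$gaussian_sigma_frames,
          saccade_threshold = config$okr$saccade_threshold_dps
        )
        okr[[length(okr) + 1L]] <- data.frame(
          cohort = g, axis = axis, trial = tr, gain_true = gt,
          gain = res$gain_result$gain,
          cumulative_deg = res$gain_result$cumulative_slow_deg,
          pct_saccade = res$pct_saccade,
          pct_low_confidence = res$pct_low_confidence,
          camera = res$camera_used
        )
      }
    }
  }
  cells <- do.call(rbind, cells)
  okr <- do.call(rbind, okr)
  summary <- merge(
    stats::aggregate(cbind(ipsc_dsi, asymmetric_inhibition_pa,
                           simulated_dsi) ~ cohort, cells, mean),
    stats::aggregate(gain ~ cohort + axis, okr, mean)
  )
  list(cells = cells, okr = okr, summary = summary, seed = seed)
}
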