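#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: two cohorts of direction-selective
# ganglion cells ("intact" vs "disrupted": near-symmetric inhibition and
# reduced excitation), paired-recording IV datasets with dendritic fields,
# and dual-camera eye-tracking sessions per axis. Everything downstream
# reads these files, mirroring a recording day's directory layout.

suppressPackageStartupMessages(library(dsokr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1

set.seed(seed)   # stream for the pair-level draws below
out <- "scratch/analysis-data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohorts <- list(
  intact = list(ipsc = tuning_spec(preferred_direction = 0, peak_pd = 600,
                                   peak_nd = 100),
                epsc = tuning_spec(preferred_direction = 180, peak_pd = 320,
                                   peak_nd = 260),
                spikes = tuning_spec(preferred_direction = 180, peak_pd = 80,
                                     peak_nd = 5),
                gain_h = 0.7, gain_v = 0.7),
  disrupted = list(ipsc = tuning_spec(preferred_direction = 0, peak_pd = 380,
                                      peak_nd = 330),
                   epsc = tuning_spec(preferred_direction = 180,
                                      peak_pd = 180, peak_nd = 150),
                   spikes = tuning_spec(preferred_direction = 180,
                                        peak_pd = 30, peak_nd = 15),
                   gain_h = 0.05, gain_v = 0.7)
)
n_cells <- 3

manifest <- list(seed = seed, n_cells = n_cells, cohorts = list())
for (g in names(cohorts)) {
  co <- cohorts[[g]]
  for (cell in seq_len(n_cells)) {
    s <- seed + 1000L * match(g, names(cohorts)) + 10L * cell
    ipsc <- gen_psc_sweeps(co$ipsc, seed = s, holding_mv = 0)
    epsc_raw <- gen_psc_sweeps(co$epsc, seed = s + 1L, holding_mv = -60)
    epsc <- epsc_raw
    epsc$traces <- lapply(epsc_raw$traces, function(m) -m)  # inward currents
    id <- sprintf("%s_cell%d", g, cell)
    write_sweep_set(ipsc, file.path(out, paste0(id, "_ipsc.csv")))
    write_sweep_set(epsc, file.path(out, paste0(id, "_epsc.csv")))
  }
  for (axis in c("horizontal", "vertical")) {
    dirn <- if (axis == "horizontal") "posterior" else "superior"
    gt <- if (axis == "horizontal") co$gain_h else co$gain_v
    for (tr in 1:2) {
      s <- seed + 5000L * match(g, names(cohorts)) +
        100L * match(axis, c("horizontal", "vertical")) + tr
      sim <- gen_eye_markers(eye_sim_spec(gain_true = gt,
                                          stim_direction = dirn), seed = s)
      id <- sprintf("%s_%s_trial%d", g, axis, tr)
      write_marker_table(sim$camera_a, file.path(out, paste0(id, "_camA.csv")))
      write_marker_table(sim$camera_b, file.path(out, paste0(id, "_camB.csv")))
      jsonlite::write_json(
        list(cohort = g, axis = axis, trial = tr,
             stim_direction = dirn, stim_velocity_dps = 2,
             duration_s = 45, spatial_frequency_cpd = 0.15, contrast = 1.0,
             gain_true = gt, seed = s),
        file.path(out, paste0(id, "_stim.json")), auto_unbox = TRUE,
        digits = NA)
    }
  }
  manifest$cohorts[[g]] <- list(gain_h = co$gain_h, gain_v = co$gain_v,
                                ipsc_pd = co$ipsc$peak_pd,
                                ipsc_nd = co$ipsc$peak_nd)
}

# paired recordings: conductance scales with dendritic overlap, with
# multiplicative biological scatter around the structural relation
pairs <- lapply(1:8, function(k) {
  s <- seed + 42L * k
  frac <- stats::runif(1, 0.1, 0.9)
  fields <- gen_dendrite_fields(frac, seed = s)
  g_true <- 0.004 * fields$true_overlap_area *
    exp(stats::rnorm(1, 0, 0.25))              # ~ nS per um^2
  iv <- gen_iv_currents(iv_sim_spec(g_true = g_true, e_rev_true = -60,
                                    noise_sd = 3), seed = s)
  utils::write.csv(
    data.frame(hold_mv = rep(iv$holds, ncol(iv$peaks)),
               trial = rep(seq_len(ncol(iv$peaks)), each = length(iv$holds)),
               peak_pa = as.vector(iv$peaks)),
    file.path(out, sprintf("pair%02d_iv.csv", k)), row.names = FALSE)
  utils::write.csv(as.data.frame(fields$points_a),
                   file.path(out, sprintf("pair%02d_dsgc.csv", k)),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fields$points_b),
                   file.path(out, sprintf("pair%02d_sac.csv", k)),
                   row.names = FALSE)
  list(pair = k, overlap_frac = frac, g_true = g_true,
       true_overlap = fields$true_overlap_area)
})
manifest$pairs <- pairs
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("wrote synthetic study (seed %d): %d cells x 2 cohorts, %d IV pairs, eye sessions under %s\n",
            seed, n_cells, length(pairs), out))
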