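#!/usr/bin/env Rscript
# Stage 4 — parallel-conductance model: extract GExc/GInh from the mean
# voltage-clamp currents of every cell, integrate the membrane equation by
# forward Euler per direction, and compare simulated depolarization tuning
# between cohorts.

suppressPackageStartupMessages(library(dsokr))
data_dir <- "scratch/analysis-data"
w <- response_windows()
params <- model_params()

ipsc_files <- list.files(data_dir, pattern = "_ipsc\\.csv$",
                         full.names = TRUE)
rows <- lapply(ipsc_files, function(fi) {
  fe <- sub("_ipsc", "_epsc", fi)
  id <- sub("_ipsc\\.csv$", "", basename(fi))
  ipsc <- read_sweep_set(fi)
  epsc <- read_sweep_set(fe)
  mt_i <- average_trials(ipsc)
  mt_e <- average_trials(epsc)
  keep <- seq(1, length(mt_i$t),
              by = max(1L, round(params$dt / 1000 * ipsc$sampling_rate)))
  t_ms <- mt_i$t[keep] * 1000
  sims <- lapply(seq_along(mt_i$directions), function(k) {
    cond <- extract_conductance(
      baseline_subtract(mt_e$traces[[k]], mt_e$t, w)[keep],
      baseline_subtract(mt_i$traces[[k]], mt_i$t, w)[keep],
      t_ms, params, direction = mt_i$directions[k])
    simulate_vm(cond, params)
  })
  curve <- simulated_tuning(sims, w, "on")
  nd <- curve$angles[which.min(curve$magnitudes)]
  pd <- (nd + 180) %% 360
  data.frame(
    cell_id = id, cohort = sub("_cell[0-9]+$", "", id),
    sim_nd_deg = nd,
    vm_nd_mv = curve$magnitudes[curve$angles == nd],
    vm_pd_mv = curve$magnitudes[curve$angles == pd],
    simulated_dsi = dsi(curve$magnitudes[curve$angles == pd],
                        curve$magnitudes[curve$angles == nd])
  )
})
sim_tab <- do.call(rbind, rows)
utils::write.csv(sim_tab, "results/simulated_vm.csv", row.names = FALSE)

agg <- stats::aggregate(simulated_dsi ~ cohort, sim_tab, mean)
cat("mean simulated-Vm DSI per cohort (ON pathway):\n")
print(agg, row.names = FALSE)
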