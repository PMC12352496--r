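#!/usr/bin/env Rscript
# Stage 2 — raw sweeps to per-direction peak responses: trial averaging,
# first-500-ms baseline subtraction, and ON/OFF-window peak extraction for
# every cell and current type written by stage 1.

suppressPackageStartupMessages(library(dsokr))
data_dir <- "scratch/analysis-data"
w <- response_windows()

files <- list.files(data_dir, pattern = "_(ipsc|epsc)\\.csv$",
                    full.names = TRUE)
rows <- lapply(files, function(f) {
  sw <- read_sweep_set(f)
  mode <- if (grepl("_ipsc", f)) "IPSC" else "EPSC"
  pt <- peak_table(sw, w, mode = mode)
  pt$cell_id <- sub("_(ipsc|epsc)\\.csv$", "", basename(f))
  pt$metric <- mode
  pt
})
peaks <- do.call(rbind, rows)
utils::write.csv(peaks, "results/peaks.csv", row.names = FALSE)

on_ipsc <- peaks[peaks$pathway == "on" & peaks$metric == "IPSC", ]
cat(sprintf("extracted %d peaks from %d cells; ON IPSC magnitude %0.0f-%0.0f pA\n",
            nrow(peaks), length(unique(peaks$cell_id)),
            min(on_ipsc$magnitude), max(on_ipsc$magnitude)))
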