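#!/usr/bin/env Rscript
# Stage 5 — paired recordings: IV line fits (conductance, reversal,
# R-squared quality gate at 0.80) per pair, convex-hull overlap of the
# traced dendritic fields, and the conductance-vs-overlap correlation.

suppressPackageStartupMessages(library(dsokr))
data_dir <- "scratch/analysis-data"
manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                simplifyVector = TRUE)

iv_files <- list.files(data_dir, pattern = "pair[0-9]+_iv\\.csv$",
                       full.names = TRUE)
rows <- lapply(iv_files, function(f) {
  k <- as.integer(sub("pair([0-9]+)_iv\\.csv", "\\1", basename(f)))
  d <- utils::read.csv(f)
  peaks <- do.call(cbind, split(d$peak_pa, d$trial))
  holds <- sort(unique(d$hold_mv))
  # holds were stored already corrected by the generator; junction 0 here
  fit <- fit_iv(build_iv(peaks, holds, junction_mv = 0))
  pa <- utils::read.csv(file.path(data_dir, sprintf("pair%02d_dsgc.csv", k)))
  pb <- utils::read.csv(file.path(data_dir, sprintf("pair%02d_sac.csv", k)))
  ov <- hull_overlap(convex_hull(as.matrix(pa)), convex_hull(as.matrix(pb)))
  data.frame(pair = k, g_gaba_ns = fit$slope_ns, e_rev_mv = fit$e_rev_mv,
             r2 = fit$r_squared, qc_pass = fit$passes_qc,
             overlap_um2 = ov$area_intersection,
             hull_dsgc_um2 = ov$area_a, hull_sac_um2 = ov$area_b)
})
paired <- do.call(rbind, rows)
utils::write.csv(paired, "results/paired.csv", row.names = FALSE)

qc <- paired[paired$qc_pass, ]
r2 <- overlap_conductance_relation(qc$g_gaba_ns, qc$overlap_um2)
cat(sprintf("%d/%d pairs pass the R^2 > 0.80 gate\n", nrow(qc), nrow(paired)))
cat(sprintf("reversal potentials: %0.1f to %0.1f mV (chloride, -60 expected)\n",
            min(qc$e_rev_mv), max(qc$e_rev_mv)))
cat(sprintf("conductance vs dendritic overlap: R^2 = %0.2f\n", r2))
writeLines(jsonlite::toJSON(list(n_pass = nrow(qc),
                                 overlap_r2 = r2), auto_unbox = TRUE),
           "results/paired_summary.json")
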