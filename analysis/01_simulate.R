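#!/usr/bin/env Rscript
# Generate the synthetic data sets used by the downstream analysis scripts.
# Ground truths embed the study's reported fit parameters so every later
# stage can be checked against known answers. Run from the repository root:
#   Rscript analysis/01_simulate.R
suppressPackageStartupMessages(library(stimstab))

data_dir <- file.path("results", "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

## Thermal melts: wild-type Ca2+-loaded pair (reducing vs S-nitrosylated)
melts <- list(
  wt_loaded_dtt = gen_melt_curve(melt_truth(tm = 63.2), seed = 101),
  wt_loaded_gsno = gen_melt_curve(melt_truth(tm = 67.3), seed = 102,
                                  condition = "GSNO"),
  wt_depleted_dtt = gen_melt_curve(melt_truth(tm = 51.7), seed = 103,
                                   ca_state = "depleted"),
  wt_depleted_gsno = gen_melt_curve(melt_truth(tm = 53.4), seed = 104,
                                    condition = "GSNO",
                                    ca_state = "depleted"))
for (nm in names(melts))
  write.csv(data.frame(temperature_C = melts[[nm]]$temperature,
                       ellipticity_mdeg = melts[[nm]]$ellipticity),
            file.path(data_dir, paste0("melt_", nm, ".csv")),
            row.names = FALSE)

## Urea denaturation: wild-type pairs, 3 replicates each
denat <- list(
  wt_loaded_dtt = gen_denaturation_replicates(
    denat_truth(dg = 6.87, m = 2.05), seed = 201, ca_state = "loaded"),
  wt_loaded_gsno = gen_denaturation_replicates(
    denat_truth(dg = 7.49, m = 2.00), seed = 202, condition = "GSNO",
    ca_state = "loaded"),
  wt_depleted_dtt = gen_denaturation_replicates(
    denat_truth(dg = 4.82, m = 1.69), seed = 203, ca_state = "depleted"),
  wt_depleted_gsno = gen_denaturation_replicates(
    denat_truth(dg = 5.98, m = 1.92), seed = 204, condition = "GSNO",
    ca_state = "depleted"))
for (nm in names(denat)) {
  df <- do.call(rbind, lapply(denat[[nm]], function(r)
    data.frame(urea_M = r$denaturant, fluorescence_au = r$signal,
               replicate = r$replicate_id)))
  write.csv(df, file.path(data_dir, paste0("denat_", nm, ".csv")),
            row.names = FALSE)
}

## HSQC peak lists: reference vs S-nitrosylated, two perturbed spans
pair <- gen_peaklist_pair(csp_truth(), seed = 301)
for (nm in c("reference", "modified")) {
  pl <- pair[[nm]]
  write.csv(data.frame(residue = pl$residue, h_ppm = pl$h_ppm,
                       n_ppm = pl$n_ppm),
            file.path(data_dir, paste0("hsqc_", nm, ".csv")),
            row.names = FALSE)
}

## Fura-2 traces: control vs STIM2-overexpression-like (2-fold basal)
for (s in 1:6) {
  ft <- gen_fura_trace(fura_truth(basal_nM = 118, noise_sd = 0.05),
                       seed = 400 + s)
  write.csv(data.frame(time_s = ft$trace$time, f340 = ft$trace$f340,
                       f380 = ft$trace$f380),
            file.path(data_dir, sprintf("fura_control_%02d.csv", s)),
            row.names = FALSE)
  write.csv(as.data.frame(ft$calib_segments),
            file.path(data_dir, sprintf("fura_control_%02d_calib.csv", s)),
            row.names = FALSE)
  fe <- gen_fura_trace(fura_truth(basal_nM = 236, noise_sd = 0.05),
                       seed = 500 + s)
  write.csv(data.frame(time_s = fe$trace$time, f340 = fe$trace$f340,
                       f380 = fe$trace$f380),
            file.path(data_dir, sprintf("fura_stim2_%02d.csv", s)),
            row.names = FALSE)
  write.csv(as.data.frame(fe$calib_segments),
            file.path(data_dir, sprintf("fura_stim2_%02d_calib.csv", s)),
            row.names = FALSE)
}

cat("synthetic data written to", data_dir, "\n")
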