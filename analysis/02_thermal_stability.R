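#!/usr/bin/env Rscript
# Fit Boltzmann sigmoids to the simulated CD melts and form the
# S-nitrosylation-induced apparent-Tm shifts with quadrature errors.
# Requires analysis/01_simulate.R to have been run.
suppressPackageStartupMessages(library(stimstab))

data_dir <- file.path("results", "data")
groups <- c("wt_loaded_dtt", "wt_loaded_gsno",
            "wt_depleted_dtt", "wt_depleted_gsno")
melts <- lapply(groups, function(nm)
  read_melt_curve(file.path(data_dir, paste0("melt_", nm, ".csv"))))
names(melts) <- groups

pairs <- data.frame(reference = c("wt_loaded_dtt", "wt_depleted_dtt"),
                    modified = c("wt_loaded_gsno", "wt_depleted_gsno"))
rep <- run_stability_report(melt_groups = melts, pairs = pairs,
                            out_dir = file.path("results", "thermal"))

cat("Apparent Tm fits:\n")
print(rep$thermal[, c("group", "apparent_tm", "se_tm", "status")])
cat("\nGSNO-induced shifts (expected about +4.1 and +1.7 degC):\n")
print(rep$comparisons[, c("reference", "modified", "delta", "error")])
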