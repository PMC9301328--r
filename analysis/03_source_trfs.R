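#!/usr/bin/env Rscript
# Source-space TRFs: reconstruct ROI time series through the sLORETA
# operator, fit per-trial encoder TRFs, and check how well the averaged
# condition-A TRFs recover the planted kernels.

library(trfnet)
dir.create("results", showWarnings = FALSE)

cfg <- study_config(seed = 1)
rep <- run_pipeline(cfg, cache_dir = "scratch/cache", verbose = FALSE)

# recovery of planted kernels is measured on a dedicated 10 dB study by
# analysis/05; here we tabulate the default-study (-5 dB) window statistics
f1w <- rep$f1_windows
cat("TRF window separability (F1, hyperaligned pathway):\n")
print(round(f1w, 3))
write.table(data.frame(window = names(f1w), f1 = as.numeric(f1w)),
            "results/window_f1_default_study.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\nfull-network separability F1: hyperaligned %.3f, single-trial %.3f\n",
            rep$f1_full[["hyperaligned"]], rep$f1_full[["single_trial"]]))
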