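#!/usr/bin/env Rscript

# Step 5: training-frequency / initial-performance analysis of the
# self-learning approach on the encapsulation sequence. Two initial
# levels at ET1 (HP: one supervised recalibration step from Base; LP: one
# self-learning step from Base) x frequency multipliers {1, 2, 4, 8}
# (interpolated intermediate time points) x SNRs {-5, -10, -15} dB. Each
# cell reports the ET1-to-ET2 slope of the self-learning classifier minus
# the slope of a control frozen at ET1 (positive = slower decline).

suppressPackageStartupMessages(library(cuffdrift))
dir.create("results/slopes", showWarnings = FALSE, recursive = TRUE)

cfg <- default_config(1L)
rows <- list()
for (snr in cfg$snr_grid) {
  cat(sprintf("\n== SNR %g dB ==\n", snr))
  seqd <- build_timepoint_sequence(cfg, "encapsulation", snr)
  strat_seed <- derive_seed(cfg$master_seed,
                            sprintf("strategy/encapsulation/%g", snr))
  base_states <- train_base_states(seqd, "linear_baseline", strat_seed)
  levels <- build_initial_levels(seqd, "linear_baseline", strat_seed,
                                 threshold = cfg$strategy$threshold,
                                 base_states = base_states)
  cat(sprintf("initial F1 at ET1: HP %.4f, LP %.4f\n",
              levels$HP$f1, levels$LP$f1))
  grid <- run_slope_grid(seqd$timepoints[["ET1"]],
                         seqd$timepoints[["ET2"]], levels,
                         frequencies = cfg$strategy$frequencies,
                         threshold = cfg$strategy$threshold,
                         min_per_class = cfg$strategy$min_per_class)
  grid$snr_db <- snr
  print(grid, row.names = FALSE)
  rows[[length(rows) + 1L]] <- grid
  rm(seqd); gc(FALSE)
}
slopes <- do.call(rbind, rows)
utils::write.csv(slopes, "results/slopes/slope_grid.csv",
                 row.names = FALSE)
cat("\nwrote results/slopes/slope_grid.csv\n")
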