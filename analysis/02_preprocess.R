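#!/usr/bin/env Rscript
# Timeseries-level preprocessing: framewise displacement, the 0.5 mm
# inclusion rule, discarding the 10 lead-in volumes, motion nuisance
# regression with detrending, and 0.01-0.09 Hz band-pass filtering.

source("analysis/00_config.R")
cfg <- analysis_config()

run_stage(cfg, "prep")

ms <- read.csv(file.path(cfg$out_dir, "prep", "motion_summary.csv"))
excl <- read.csv(file.path(cfg$out_dir, "prep", "excluded.csv"))
for (cond in c("natural", "built")) {
  fd <- ms$mean_fd[ms$condition == cond]
  cat(sprintf("mean FD, %s condition: %.3f +/- %.3f mm\n",
              cond, mean(fd), sd(fd)))
}
cat(sprintf("%d subject(s) excluded by the FD rule\n", nrow(excl)))
cat("preprocessed series in", file.path(cfg$out_dir, "prep"), "\n")
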