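#!/usr/bin/env Rscript
# Build per subject-condition Pearson connectivity matrices (7 x 7 on the
# functional atlas) from the preprocessed ROI timeseries.

source("analysis/00_config.R")
cfg <- analysis_config()

run_stage(cfg, "connectome")

ld <- connstate:::load_stacked(cfg)
nat <- ld$stacked$conditions$natural
blt <- ld$stacked$conditions$built
cat(sprintf("stacked edge arrays: %d subjects x %d edges per condition\n",
            nrow(nat), ncol(nat)))
cat(sprintf("mean edge r: natural %.3f, built %.3f\n",
            mean(nat), mean(blt)))
cat("matrices in", file.path(cfg$out_dir, "connectome"), "\n")
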