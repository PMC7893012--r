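# Shared configuration for the numbered analysis drivers.  Run each
# driver from the repository root:  Rscript analysis/01_simulate.R
#
# The study conditions mirror the emulated design: 24 subjects, two
# conditions (natural / built viewing), 150 volumes at TR = 2 s (first 10
# discarded), 7-network functional atlas, planted between-network
# condition effect and a negative urbanicity covariate effect.

suppressPackageStartupMessages(library(connstate))

analysis_config <- function(out_dir = "results/study", seed = 2026L) {
  pipeline_config(
    out_dir,
    synth = synthetic_config(),    # defaults = study conditions
    fd_threshold = 0.5, discard = 10,
    nbs_threshold = 2.5, nbs_n_perm = 10000, nbs_alpha = 0.05,
    graph_n_perm = 10000,
    seed = seed)
}
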