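#!/usr/bin/env Rscript
# Behavioural and covariate analyses downstream of NBS: paired rating
# t-tests, correlation of mean component connectivity with years of urban
# upbringing (with the gated per-edge follow-up), the <=5 vs >=10 years
# repeated-measures ANOVA, and the GSF confound check.

source("analysis/00_config.R")
cfg <- analysis_config()

run_stage(cfg, "stats")

r <- jsonlite::read_json(file.path(cfg$out_dir, "stats", "results.json"),
                         simplifyVector = TRUE)
cat("paired rating tests (natural vs built):\n")
print(r$ratings, row.names = FALSE)
if (is.character(r$covariate_correlation)) {
  cat(r$covariate_correlation, "\n")
} else {
  cat(sprintf(
    "\nmean component connectivity (natural) vs years urban: r = %.3f (df = %d), p = %.4g\n",
    r$covariate_correlation$r, r$covariate_correlation$df,
    r$covariate_correlation$p))
  if (!is.null(r$per_edge)) {
    cat("per-edge follow-up:\n")
    print(r$per_edge, row.names = FALSE)
  }
  cat("\nurbanicity split ANOVA (<=5 vs >=10 years):\n")
  print(r$urban_split_anova, row.names = FALSE)
  cat(sprintf("\nGSF confound check: r = %.3f, p = %.3f\n",
              r$gsf_confound$r, r$gsf_confound$p))
}
cat("results JSON in", file.path(cfg$out_dir, "stats"), "\n")
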