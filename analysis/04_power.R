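#!/usr/bin/env Rscript
# Power analysis for the one-sample dependency test. The design target
# is the weighted-average published effect size d = 0.86 for immediate
# tests of separately encoded events: analytically, n = 20 gives 95%
# power and n = 45 exceeds 99%. The simulated column runs the full
# generator -> dependency -> t-test pipeline at a mixture calibrated to
# population d ~ 0.86 (config_power_demo) and should agree with the
# analytic curve within Monte-Carlo error. Writes results/power.csv.

suppressPackageStartupMessages(library(eventdep))
dir.create("results", showWarnings = FALSE)

cat("Required n for 95% power at d = 0.86:",
    required_n(d = 0.86, target_power = 0.95), "\n\n")

tab <- run_power(d = 0.86, n_grid = c(10, 15, 20, 30, 45),
                 sim_config = config_power_demo(seed = 7), n_sims = 300)
write.csv(tab, "results/power.csv", row.names = FALSE)
print(as.data.frame(lapply(tab, round, 3)), row.names = FALSE)

cat("\nAnalytic power at the smallest published effect (d = 0.50, n = 45):",
    round(power_one_sample_t(45, 0.50), 3), "\n")
cat("Type-I reference: power at d = 0 equals alpha =",
    round(power_one_sample_t(20, 0), 3), "\n")
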