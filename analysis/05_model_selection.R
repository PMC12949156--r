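#!/usr/bin/env Rscript
# AICc ranking of the model grid on a common complete-case observation
# set, with and without the acute noise exposed group. Requires
# results/analysis_table.csv. Writes results/aicc_all_mice.csv and
# results/aicc_excluding_acute.csv.

suppressPackageStartupMessages(library(synapredict))

tab <- read.csv("results/analysis_table.csv")
grid <- default_model_grid()

all_mice <- compare_models_aicc(grid, tab, scope = "all_mice")
excl <- compare_models_aicc(grid, tab, scope = "excluding_acute")
write.csv(all_mice, "results/aicc_all_mice.csv", row.names = FALSE)
write.csv(excl, "results/aicc_excluding_acute.csv", row.names = FALSE)

cat(sprintf(
  "common complete-case set: %d observations from %d ears\n",
  all_mice$n_obs[1], all_mice$n_ears[1]))
cat(sprintf("best model, all mice: %s (next: %s, delta AICc %0.2f)\n",
            all_mice$model_id[1], all_mice$model_id[2],
            all_mice$delta_aicc[2]))
cat(sprintf("best model, excluding acute: %s\n", excl$model_id[1]))
cat(sprintf(
  "intercept-only delta AICc: %0.2f (all mice), %0.2f (excluding acute)\n",
  all_mice$delta_aicc[all_mice$model_id == "intercept|none"],
  excl$delta_aicc[excl$model_id == "intercept|none"]))
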