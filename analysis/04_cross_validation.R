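#!/usr/bin/env Rscript
# Repeated (10x) ten-fold ear-grouped cross-validation of the synapse
# prediction model grid, with the acute noise exposed group held out as an
# independent focal-synaptopathy test set. Requires
# results/analysis_table.csv. Writes results/cv_summary.csv and
# results/cv_delta_vs_abr80.csv.

suppressPackageStartupMessages(library(synapredict))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

tab <- read.csv("results/analysis_table.csv")
grid <- default_model_grid()
cvc <- cv_config(seed = seed + 300000L)
results <- lapply(grid, repeated_grouped_cv, table = tab, cfg = cvc)

cv_summary <- do.call(rbind, lapply(results, function(r) {
  data.frame(model_id = r$spec$model_id, adjust = r$spec$adjust,
             mean_val = r$mean_val, sem_val = r$sem_val,
             mean_test = r$mean_test, sem_test = r$sem_test,
             n_rows = r$n_rows)
}))
write.csv(cv_summary, "results/cv_summary.csv", row.names = FALSE)
delta <- delta_rmse_vs_reference(results, "abr_80")
write.csv(delta, "results/cv_delta_vs_abr80.csv", row.names = FALSE)

best_val <- cv_summary[which.min(cv_summary$mean_val), ]
best_test <- cv_summary[which.min(cv_summary$mean_test), ]
cat(sprintf(
  "validation (no/broad synaptopathy): best model %s, RMSE %0.2f (SEM %0.2f)\n",
  best_val$model_id, best_val$mean_val, best_val$sem_val))
cat(sprintf(
  "acute test set (focal synaptopathy): best model %s, RMSE %0.2f\n",
  best_test$model_id, best_test$mean_test))
cat(sprintf(
  "intercept-only baseline: validation %0.2f, test %0.2f synapses/IHC\n",
  cv_summary$mean_val[cv_summary$model_id == "intercept|none"],
  cv_summary$mean_test[cv_summary$model_id == "intercept|none"]))
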