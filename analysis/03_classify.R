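#!/usr/bin/env Rscript
# The full supervised grid: {Amide I, fingerprint} x {BC, VN, d1, d1+VN, d2,
# d2+FCBF} x {SVM, Gaussian naive Bayes}, donor-level LOOCV with per-fold
# FCBF, rank AUC, and exact binomial CIs on accuracy.

library(perfusir)

set <- read_spectra_csv("results/cohort_spectra.csv")
report <- run_full_experiment(set, fs_mode = "per_fold", seed = 20260929L)

write.csv(report$grid, "results/evaluation_grid.csv", row.names = FALSE)

ok <- report$grid[is.na(report$grid$error), ]
cat(sprintf("%d/%d grid cells evaluated\n", nrow(ok), nrow(report$grid)))
best <- ok[order(-ok$auc), ][1:5, ]
cat("\ntop cells by AUC:\n")
print(best[, c("region", "pipeline", "model", "auc", "accuracy",
               "ci_lo", "ci_hi")], digits = 2)
fc <- ok[ok$pipeline == "d2+fcbf", ]
cat("\nd2 + FCBF cells:\n")
print(fc[, c("region", "model", "auc", "accuracy", "selected")], digits = 2)
cat("\nThe injected group effect is large, so many full-spectrum pipelines\n")
cat("reach AUC 1.0 in both windows. The FCBF cells are weaker: per-fold\n")
cat("selection collapses to a single marginal wavenumber at n = 10, which\n")
cat("is leakage-safe but unstable (see the methods vignette).\n")
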