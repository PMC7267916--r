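#!/usr/bin/env Rscript
# Stage 6: evaluation.
#
# Cross-subject correlation matrices (raw + row/column normalized), mean
# diagonal prediction accuracy, mixture-model thresholding + Dice overlap,
# repeated-measures ANOVA across the three families with one-sided
# Bonferroni-corrected pairwise tests, and the diagonal-dominance
# permutation test.

library(taskpred)

cohort <- load_cohort("results/cohort")
tasks <- lapply(cohort$subjects, function(s) s$task_maps[[1]])
split <- readRDS("results/split.rds")
predictions <- readRDS("results/predictions.rds")
actual <- tasks[split$test]

acc <- c(); dice_mean <- c(); scores <- NULL
for (kind in names(predictions)) {
  m <- prediction_matrix(predictions[[kind]], actual)
  write.csv(m, sprintf("results/matrix_%s.csv", kind))
  write.csv(normalize_matrix(m), sprintf("results/matrix_%s_normalized.csv", kind))
  acc[kind] <- prediction_accuracy(m)
  scores <- cbind(scores, diag(m))

  dcs <- sapply(split$test, function(id) {
    fa <- suppressWarnings(fit_mixture(tasks[[id]]$z))
    fp <- suppressWarnings(fit_mixture(predictions[[kind]][[id]]))
    dice(threshold_map(tasks[[id]]$z, fa),
         threshold_map(predictions[[kind]][[id]], fp))
  })
  dice_mean[kind] <- mean(dcs)

  dd <- diagonal_dominance(m, n_perm = 999, seed = 2032)
  cat(sprintf("%-6s mean CC %.3f | mean Dice %.3f | diag-dominance stat %.3f (p = %.3f)\n",
              kind, acc[kind], dice_mean[kind], dd$statistic, dd$p))
}

colnames(scores) <- names(predictions)
cmp <- compare_models(scores)
cat(sprintf("\nrepeated-measures ANOVA: F(%d,%d) = %.2f, p = %.4g\n",
            cmp$df[1], cmp$df[2], cmp$F, cmp$p))
print(cmp$pairwise, row.names = FALSE)

report <- data.frame(model = names(acc), mean_cc = as.numeric(acc),
                     mean_dice = as.numeric(dice_mean))
write.csv(report, "results/accuracy.csv", row.names = FALSE)
write.csv(cmp$pairwise, "results/pairwise_tests.csv", row.names = FALSE)
cat("wrote results/accuracy.csv, results/pairwise_tests.csv and matrices\n")
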