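#!/usr/bin/env Rscript
# Stage 7: learning and averaging curves.
#
# Mean diagonal prediction accuracy as a function of (a) the number of
# training subjects and (b) the number of averaged ensemble members, with
# the same test subjects throughout.

library(taskpred)

cohort <- load_cohort("results/cohort")
features <- readRDS("results/features.rds")
tasks <- lapply(cohort$subjects, function(s) s$task_maps[[1]])
split <- readRDS("results/split.rds")
parc <- cohort$truth$parcellation

curves <- do.call(rbind, lapply(c("glm", "nn", "rfbag"), function(kind)
  learning_curve(features, tasks, parc, kind,
                 train_ids = split$train, test_ids = split$test,
                 n_train_grid = c(5L, 10L, 20L), M_grid = 1L, seed = 2033)))
cat("learning curves (mean diagonal CC vs training subjects):\n")
print(curves, row.names = FALSE)

avg <- learning_curve(features, tasks, parc, "nn",
                      train_ids = split$train, test_ids = split$test,
                      n_train_grid = 20L, M_grid = c(1L, 5L, 10L), seed = 2034)
cat("\nNN averaging curve (mean diagonal CC vs M):\n")
print(avg, row.names = FALSE)

write.csv(rbind(curves, avg), "results/curves.csv", row.names = FALSE)
cat("wrote results/curves.csv\n")
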