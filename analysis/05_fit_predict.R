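#!/usr/bin/env Rscript
# Stage 5: per-parcel model training and test-set prediction.
#
# Aggregates the training subjects' rows per parcel and fits the three
# families: pseudoinverse GLM, Rprop-trained feed-forward networks
# (tanh hidden layer, 60/20/20 split, early stopping), and random-forest
# bagging. NN and RFbag are trained as ensembles of M seeded members whose
# predicted maps are averaged (M = 5 here).

library(taskpred)

cohort <- load_cohort("results/cohort")
features <- readRDS("results/features.rds")
tasks <- lapply(cohort$subjects, function(s) s$task_maps[[1]])
split <- readRDS("results/split.rds")
tuned <- readRDS("results/tuned_hyperparams.rds")
parc <- cohort$truth$parcellation

M_by_kind <- c(glm = 1L, nn = 5L, rfbag = 5L)
predictions <- list()
for (kind in names(M_by_kind)) {
  hp <- tuned[[kind]]
  if (is.null(hp)) hp <- list()
  t0 <- Sys.time()
  ens <- train_ensemble(kind, features[split$train], tasks[split$train], parc,
                        hyperparams = hp, M = M_by_kind[[kind]], seed = 2031)
  preds <- lapply(split$test, function(id) predict_ensemble(ens, features[[id]]))
  names(preds) <- split$test
  predictions[[kind]] <- preds
  cat(sprintf("%-6s M=%d trained+predicted in %.1fs\n", kind,
              M_by_kind[[kind]], as.numeric(Sys.time() - t0, units = "secs")))
}

saveRDS(predictions, "results/predictions.rds")
cat("wrote results/predictions.rds (predicted z maps for",
    length(split$test), "test subjects x 3 models)\n")
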