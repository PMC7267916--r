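#!/usr/bin/env Rscript
# Stage 4: sequential hyperparameter search on the dedicated hyperopt
# subjects (no parcellation: one whole-domain model per candidate, RMSE on
# a held-out 20% test subset). Each parameter is swept in turn and fixed
# at its RMSE-minimizing value. Grids here are decimated versions of the
# full searches (size 1-50 / layers 1-3 / learning rate 0.001-0.1;
# trees 1-200 / predictors 1-(F-1) / leaf 1-30) to keep the stage fast.

library(taskpred)

cohort <- load_cohort("results/cohort")
features <- readRDS("results/features.rds")
tasks <- lapply(cohort$subjects, function(s) s$task_maps[[1]])

split <- make_split(names(cohort$subjects), c(20, 5, 5), seed = 2028)
saveRDS(split, "results/split.rds")
print(split)

nn_tuned <- tune_nn(features[split$hyperopt], tasks[split$hyperopt],
                    grids = list(hidden_size = c(1L, 2L, 5L, 10L, 20L, 50L),
                                 n_layers = 1:3,
                                 learning_rate = c(0.001, 0.005, 0.02, 0.1)),
                    seed = 2029, max_rows = 3000, max_epochs = 150)
cat("NN chosen:", sprintf("hidden %d, layers %d, lr %.3f\n",
                          nn_tuned$hyperparams$hidden_size,
                          nn_tuned$hyperparams$n_layers,
                          nn_tuned$hyperparams$learning_rate))

rf_tuned <- tune_rfbag(features[split$hyperopt], tasks[split$hyperopt],
                       grids = list(n_trees = c(1L, 10L, 50L, 100L, 200L),
                                    n_predictors_per_split = c(2L, 5L, 8L, 11L),
                                    min_leaf = c(1L, 5L, 15L, 30L)),
                       seed = 2030, max_rows = 3000)
cat("RFbag chosen:", sprintf("trees %d, predictors %d, min leaf %d\n",
                             rf_tuned$hyperparams$n_trees,
                             rf_tuned$hyperparams$n_predictors_per_split,
                             rf_tuned$hyperparams$min_leaf))

write.csv(rbind(cbind(model = "nn", nn_tuned$trace),
                cbind(model = "rfbag", rf_tuned$trace)),
          "results/tuning_trace.csv", row.names = FALSE)
saveRDS(list(nn = nn_tuned$hyperparams, rfbag = rf_tuned$hyperparams),
        "results/tuned_hyperparams.rds")
cat("wrote results/tuning_trace.csv and results/tuned_hyperparams.rds\n")
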