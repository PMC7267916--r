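#!/usr/bin/env Rscript
# Stage 2: resting-state connectivity features.
#
# Group PCA on the concatenated normalized runs, per-hemisphere spatial
# ICA, left-right symmetry filtering, dual regression to subject maps, and
# correlation feature maps (ICA components' L/R maps + subcortical
# structures). Writes per-subject feature matrices and the symmetry-score
# table.

library(taskpred)

cohort <- load_cohort("results/cohort")
fx <- extract_features(cohort, target_dim = 16, k_ica = 3,
                       sym_threshold = 0.4, seed = 2027)

cat("retained symmetric component pairs:\n")
print(fx$symmetry_scores)
Fdim <- ncol(fx$feature_list[[1]])
cat(sprintf("feature maps: %d features per vertex (2 x %d components + %d subcortical)\n",
            Fdim, nrow(fx$symmetry_scores), cohort$space$n_structures))

saveRDS(fx$feature_list, "results/features.rds")
write.csv(fx$symmetry_scores, "results/symmetry_scores.csv", row.names = FALSE)
cat("wrote results/features.rds and results/symmetry_scores.csv\n")
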