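#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
#
# A synthetic multi-subject resting-state + task dataset with known ground
# truth: mirrored smooth cortical networks, subject-specific perturbations,
# AR(1) network time courses, subcortical structures, and task maps built
# from the subjects' features through a saturating (nonlinear) link. The
# cohort, its truth and a JSON manifest land in results/cohort/.

library(taskpred)

dir.create("results", showWarnings = FALSE)

cohort <- make_cohort(
  n_subjects = 30,
  n_vertices_per_hemisphere = 150,
  n_subcortical_structures = 8,
  k_per_hemisphere = 3,
  smoothness = 4,
  n_parcels_per_hemisphere = 10,
  subject_variability = 0.4,
  ts_noise_sd = 0.5,
  n_runs = 2,
  n_timepoints = 100,
  link_type = "nonlinear",
  task_noise_sd = 0.15,
  seed = 2026,
  dir = "results/cohort"
)

print(cohort)
cat(sprintf("grayordinates: %d (%d cortical + %d subcortical)\n",
            cohort$space$n_vertices, cohort$space$n_cortical,
            cohort$space$n_vertices - cohort$space$n_cortical))
cat(sprintf("parcels: %d cortical + %d subcortical\n",
            cohort$truth$parcellation$n_cortical_parcels,
            cohort$space$n_structures))
cat("wrote results/cohort/ (one RDS per subject + truth + manifest.json)\n")
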