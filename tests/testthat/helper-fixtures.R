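# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

tiny_space <- function() memo_fixture("space", make_space(60, 4, seed = 42))

# Small noisy cohort with individual variability (general-purpose).
tiny_cohort <- function() memo_fixture("cohort", make_cohort(
  n_subjects = 8, n_vertices_per_hemisphere = 80, n_subcortical_structures = 4,
  k_per_hemisphere = 3, smoothness = 4, n_parcels_per_hemisphere = 4,
  subject_variability = 0.4, ts_noise_sd = 0.5, n_runs = 2, n_timepoints = 100,
  link_type = "linear", task_noise_sd = 0.1, seed = 42))

# Noiseless linear cohort with unstandardized task maps: the regime in
# which the no-intercept GLM is an exact model of the generator.
exact_cohort <- function() memo_fixture("exact", make_cohort(
  n_subjects = 12, n_vertices_per_hemisphere = 80, n_subcortical_structures = 4,
  k_per_hemisphere = 3, smoothness = 4, n_parcels_per_hemisphere = 4,
  subject_variability = 0.3, ts_noise_sd = 0.5, n_runs = 2, n_timepoints = 80,
  link_type = "linear", task_noise_sd = 0, standardize_tasks = FALSE, seed = 7))

# Nonlinear-link cohort for model-ordering checks.
nonlinear_cohort <- function() memo_fixture("nonlinear", make_cohort(
  n_subjects = 24, n_vertices_per_hemisphere = 80, n_subcortical_structures = 4,
  k_per_hemisphere = 3, smoothness = 4, n_parcels_per_hemisphere = 4,
  subject_variability = 0.4, ts_noise_sd = 0.5, n_runs = 2, n_timepoints = 80,
  link_type = "nonlinear", task_noise_sd = 0.15, seed = 11))

cohort_features <- function(cohort)
  lapply(cohort$truth$subject_truths, subject_features)

cohort_tasks <- function(cohort)
  lapply(cohort$subjects, function(s) s$task_maps[[1L]])

model_accuracy <- function(model_or_ens, feature_list, target_list, test_ids) {
  pred_fun <- if (inherits(model_or_ens, "parcel_ensemble")) predict_ensemble
  else predict_parcel_model
  preds <- lapply(test_ids, function(id) pred_fun(model_or_ens, feature_list[[id]]))
  names(preds) <- test_ids
  prediction_accuracy(prediction_matrix(preds, target_list[test_ids]))
}
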