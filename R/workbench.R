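# Experiment orchestration: subject splits, end-to-end runs, manifests.

#' Split subjects into training / test / hyperopt sets
#'
#' Seeded disjoint random assignment, persisted in the returned object so
#' every model family shares the same split (in particular the same test
#' subjects).
#'
#' @param ids subject ids.
#' @param counts length-3 vector `c(train, test, hyperopt)`.
#' @param seed RNG seed.
#' @return A `split_spec`: `train`, `test`, `hyperopt` id vectors, the
#'   inner 60/20/20 model-level fractions, and the seed.
#' @export
make_split <- function(ids, counts, seed = 1L) {
  if (length(counts) != 3L || any(counts < 0))
    stop("`counts` must be c(train, test, hyperopt)", call. = FALSE)
  if (sum(counts) > length(ids))
    stop("requested split exceeds the available subjects", call. = FALSE)
  perm <- local_seed(seed, sample(ids))
  structure(list(
    train = perm[seq_len(counts[1L])],
    test = perm[counts[1L] + seq_len(counts[2L])],
    hyperopt = perm[counts[1L] + counts[2L] + seq_len(counts[3L])],
    inner_fractions = c(train = 0.6, validation = 0.2, test = 0.2),
    seed = as.integer(seed)
  ), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: %d train / %d test / %d hyperopt (seed %d)\n",
              length(x$train), length(x$test), length(x$hyperopt), x$seed))
  invisible(x)
}

#' Assemble an experiment configuration
#'
#' @param cohort_params arguments for [make_cohort()] (ignored when
#'   `cohort` is supplied).
#' @param cohort an existing `cohort`, optional.
#' @param features `"true"` (generator-side feature maps) or `"extracted"`
#'   (full group-ICA / dual-regression pipeline).
#' @param kinds model families to run.
#' @param hyperparams named list (per kind) of member hyperparameters.
#' @param tune named list (per kind) of tuning grids, or `NULL` to skip
#'   the tuning stage.
#' @param counts subjects per split `c(train, test, hyperopt)`.
#' @param n_train training subjects actually used (`NULL` = all).
#' @param M ensemble size per kind (scalar or named).
#' @param compute_dice fit per-map mixture models and report mean Dice.
#' @param extract_args arguments for [extract_features()].
#' @param seed master seed; every stage seed derives from it.
#' @param out_dir optional artifact directory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort_params = list(), cohort = NULL,
                              features = c("true", "extracted"),
                              kinds = c("glm", "nn", "rfbag"),
                              hyperparams = list(), tune = NULL,
                              counts = c(40L, 10L, 10L), n_train = NULL,
                              M = 1L, compute_dice = FALSE,
                              extract_args = list(), seed = 1L,
                              out_dir = NULL) {
  structure(list(cohort_params = cohort_params, cohort = cohort,
                 features = match.arg(features), kinds = kinds,
                 hyperparams = hyperparams, tune = tune, counts = counts,
                 n_train = n_train, M = M, compute_dice = compute_dice,
                 extract_args = extract_args, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

# True (generator-side) per-subject feature matrices of a cohort.
true_feature_list <- function(cohort) {
  out <- lapply(cohort$truth$subject_truths, subject_features)
  names(out) <- names(cohort$subjects)
  out
}

# Per-subject task maps (first contrast) of a cohort.
cohort_task_list <- function(cohort, contrast = NULL) {
  out <- lapply(cohort$subjects, function(s) {
    tm <- if (is.null(contrast)) s$task_maps[[1L]] else s$task_maps[[contrast]]
    tm
  })
  names(out) <- names(cohort$subjects)
  out
}

#' Run an experiment end to end
#'
#' Cohort generation (or reuse), feature preparation, split, optional
#' hyperparameter tuning, ensemble training per model family, prediction
#' for the shared test subjects, and evaluation (raw and normalized
#' prediction matrices, mean diagonal accuracy, optional mixture-model
#' Dice, repeated-measures ANOVA across families). Stage seeds all derive
#' from the config's master seed, so a rerun with the same config
#' reproduces the report exactly.
#'
#' @param config an [experiment_config()].
#' @return An `eval_report` list: per-kind matrices, accuracies, Dice
#'   (optional), `anova` (when >= 2 kinds), predictions, the split, tuning
#'   results, and the manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed

  cohort <- config$cohort
  if (is.null(cohort))
    cohort <- do.call(make_cohort, utils::modifyList(
      list(seed = derive_seed(seed, 1L)), config$cohort_params))

  feature_list <- if (config$features == "true") true_feature_list(cohort)
  else do.call(extract_features, c(list(cohort = cohort,
                                        seed = derive_seed(seed, 2L)),
                                   config$extract_args))$feature_list
  target_list <- cohort_task_list(cohort)
  parc <- cohort$truth$parcellation

  split <- make_split(names(cohort$subjects), config$counts,
                      seed = derive_seed(seed, 3L))
  train_ids <- split$train
  if (!is.null(config$n_train)) train_ids <- train_ids[seq_len(config$n_train)]

  tuned <- list()
  if (!is.null(config$tune)) {
    for (kind in intersect(names(config$tune), config$kinds)) {
      tuner <- if (kind == "nn") tune_nn else tune_rfbag
      tuned[[kind]] <- tuner(feature_list[split$hyperopt],
                             target_list[split$hyperopt],
                             grids = config$tune[[kind]],
                             seed = derive_seed(seed, 4L))
    }
  }

  results <- list()
  for (kind in config$kinds) {
    hp <- config$hyperparams[[kind]] %||% list()
    if (!is.null(tuned[[kind]])) hp <- utils::modifyList(hp, tuned[[kind]]$hyperparams)
    M <- if (length(config$M) > 1L) config$M[[kind]] else config$M
    ens <- train_ensemble(kind, feature_list[train_ids], target_list[train_ids],
                          parc, hyperparams = hp, M = M,
                          seed = derive_seed(seed, 5L + match(kind, config$kinds)))
    preds <- lapply(split$test, function(id) predict_ensemble(ens, feature_list[[id]]))
    names(preds) <- split$test
    m <- prediction_matrix(preds, target_list[split$test])
    res <- list(kind = kind, matrix = m,
                matrix_normalized = normalize_matrix(m),
                accuracy = prediction_accuracy(m),
                predictions = preds, M = M, hyperparams = hp)
    if (isTRUE(config$compute_dice)) {
      dcs <- vapply(split$test, function(id) {
        actual_fit <- fit_mixture(task_z(target_list[[id]]))
        pred_fit <- fit_mixture(preds[[id]])
        dice(threshold_map(task_z(target_list[[id]]), actual_fit),
             threshold_map(preds[[id]], pred_fit))
      }, numeric(1L))
      res$dice <- dcs
      res$mean_dice <- mean(dcs)
    }
    results[[kind]] <- res
  }

  report <- list(results = results,
                 accuracy = vapply(results, `[[`, 0, "accuracy"),
                 split = split, tuning = tuned,
                 manifest = list(config = config[setdiff(names(config), "cohort")],
                                 cohort_manifest = cohort$manifest))
  if (length(config$kinds) >= 2L) {
    scores <- vapply(results, function(r) diag(r$matrix),
                     numeric(length(split$test)))
    colnames(scores) <- names(results)
    report$anova <- compare_models(scores)
    report$scores <- scores
  }
  class(report) <- "eval_report"

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: mean diagonal CC per model\n")
  for (k in names(x$accuracy))
    cat(sprintf("  %-6s %.4f\n", k, x$accuracy[[k]]))
  if (!is.null(x$anova))
    cat(sprintf("  rmANOVA F(%d,%d) = %.3f, p = %.3g\n",
                x$anova$df[1L], x$anova$df[2L], x$anova$F, x$anova$p))
  invisible(x)
}

# CSV artifacts shaped like the report tables.
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("could not create report directory: ", dir, call. = FALSE)
  acc <- data.frame(model = names(report$accuracy),
                    mean_cc = as.numeric(report$accuracy))
  if (!is.null(report$results[[1L]]$mean_dice))
    acc$mean_dice <- vapply(report$results, `[[`, 0, "mean_dice")
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  for (k in names(report$results))
    utils::write.csv(report$results[[k]]$matrix,
                     file.path(dir, paste0("matrix_", k, ".csv")))
  if (!is.null(report$anova))
    utils::write.csv(report$anova$pairwise, file.path(dir, "pairwise.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report$manifest$cohort_manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
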