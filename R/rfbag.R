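# Random-forest bagging: per-parcel bootstrap-aggregated regression trees
# with a fresh random feature subset at every split (variance-reduction
# splits, leaf means, prediction = mean over trees), backed by ranger.

#' Fit per-parcel random-forest bagging predictors
#'
#' For each parcel, trains a forest of regression trees on the parcel's
#' rows stacked across training subjects: each tree sees a bootstrap
#' resample of the rows (`bootstrap = TRUE`) and considers a random subset
#' of `n_predictors_per_split` features at every split; leaves hold the
#' mean target and predictions average over trees.
#'
#' @inheritParams fit_glm
#' @param n_trees trees per forest (default 100).
#' @param n_predictors_per_split features sampled at each split; default
#'   `ceiling(F/3)`, mirroring the tuned third of the feature set.
#' @param min_leaf minimum leaf size (default 5).
#' @param seed RNG seed.
#' @param bootstrap resample rows with replacement (disable, together with
#'   `n_trees = 1`, for a single fully grown tree on the raw rows).
#' @return A `parcel_model` of kind `"rfbag"`.
#' @export
fit_rfbag <- function(features_list, target_list, parcellation,
                      n_trees = 100L, n_predictors_per_split = NULL,
                      min_leaf = 5L, seed = 1L, bootstrap = TRUE) {
  check_model_inputs(features_list, target_list, parcellation)
  Fdim <- ncol(features_list[[1L]])
  if (is.null(n_predictors_per_split)) n_predictors_per_split <- ceiling(Fdim / 3)
  if (n_predictors_per_split < 1L || n_predictors_per_split > Fdim)
    stop("`n_predictors_per_split` must lie in 1..F", call. = FALSE)

  feature_names <- paste0("f", seq_len(Fdim))
  P <- parcellation$n_parcels
  forests <- vector("list", P)
  for (p in seq_len(P)) {
    idx <- which(parcellation$labels == p)
    if (!length(idx)) stop("parcel ", p, " is empty", call. = FALSE)
    d <- stack_parcel(features_list, target_list, idx)
    if (min_leaf > nrow(d$X))
      stop("`min_leaf` exceeds the number of training rows", call. = FALSE)
    df <- as.data.frame(d$X)
    names(df) <- feature_names
    df$.y <- d$y
    forests[[p]] <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, mtry = n_predictors_per_split,
      min.node.size = min_leaf, replace = bootstrap,
      sample.fraction = 1, splitrule = "variance",
      seed = derive_seed(seed, p), num.threads = 1L)
  }
  structure(list(kind = "rfbag", forests = forests, parcellation = parcellation,
                 n_features = Fdim, feature_names = feature_names,
                 hyperparams = list(n_trees = n_trees,
                                    n_predictors_per_split = n_predictors_per_split,
                                    min_leaf = min_leaf),
                 meta = list(n_train = length(features_list), seed = seed)),
            class = "parcel_model")
}
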