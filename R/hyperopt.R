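# Sequential one-parameter-at-a-time hyperparameter search minimizing
# held-out RMSE on the dedicated hyperparameter-optimization subjects,
# with no parcellation (one whole-domain model per candidate).

# Coordinate-wise sweep: for each parameter in order, evaluate the grid
# with all other parameters fixed at their current values, then fix the
# parameter at its objective-minimizing value. `objective(params)` returns
# a single number. Returns the chosen values and the full trace.
coord_sweep <- function(objective, grids, init = NULL) {
  if (!length(grids) || any(!lengths(grids)))
    stop("all grids must be non-empty", call. = FALSE)
  current <- if (is.null(init)) lapply(grids, `[`, 1L) else init
  trace <- data.frame(parameter = character(), value = numeric(),
                      objective = numeric())
  for (par in names(grids)) {
    vals <- grids[[par]]
    obj <- vapply(vals, function(v) {
      cand <- current; cand[[par]] <- v
      objective(cand)
    }, numeric(1L))
    if (all(is.na(obj))) stop("objective was NaN over the whole `", par,
                              "` grid", call. = FALSE)
    trace <- rbind(trace, data.frame(parameter = par, value = vals,
                                     objective = obj))
    current[[par]] <- vals[which.min(obj)]
  }
  list(chosen = current, trace = trace)
}

# Pool rows across hyperopt subjects (optionally subsampled with a fixed
# seed to bound cost) into one whole-domain design.
pool_rows <- function(features_list, target_list, max_rows = NULL, seed = 1L) {
  X <- do.call(rbind, lapply(features_list, as.matrix))
  y <- unlist(lapply(target_list, task_z), use.names = FALSE)
  if (!is.null(max_rows) && nrow(X) > max_rows) {
    keep <- local_seed(seed, sample.int(nrow(X), max_rows))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  list(X = X, y = y)
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

#' Tune the neural network hyperparameters
#'
#' Coordinate-wise sweep over hidden-layer size, then number of hidden
#' layers, then learning rate (each parameter fixed at its RMSE-minimizing
#' value before the next sweep). One whole-domain network is fit per
#' candidate on the pooled hyperopt rows with 20% test / 20% validation
#' held out; the objective is the test-subset RMSE. Default grids follow
#' the full search (size 1-50, layers 1-3, learning rate 0.001-0.1 by
#' 0.002); pass smaller grids to bound cost.
#'
#' @param features_list,target_list hyperopt subjects' features and task
#'   maps.
#' @param grids named list `hidden_size`, `n_layers`, `learning_rate`.
#' @param seed RNG seed (shared across candidates so splits coincide).
#' @param max_rows optional row subsample bound (seeded).
#' @param max_epochs NN epoch cap during tuning.
#' @return List with `hyperparams` (chosen values) and `trace`
#'   (parameter/value/RMSE data frame, one row per evaluated candidate).
#' @export
tune_nn <- function(features_list, target_list,
                    grids = list(hidden_size = 1:50, n_layers = 1:3,
                                 learning_rate = seq(0.001, 0.1, by = 0.002)),
                    seed = 1L, max_rows = 4000L, max_epochs = 200L) {
  d <- pool_rows(features_list, target_list, max_rows, derive_seed(seed, 1L))
  objective <- function(hp) {
    fit <- mlp_fit(d$X, d$y,
                   hidden = rep(hp$hidden_size, hp$n_layers),
                   learning_rate = hp$learning_rate,
                   max_epochs = max_epochs, seed = derive_seed(seed, 2L))
    sqrt(fit$test_mse)
  }
  res <- coord_sweep(objective, grids,
                     init = list(hidden_size = grids$hidden_size[1L],
                                 n_layers = grids$n_layers[1L],
                                 learning_rate = grids$learning_rate[1L]))
  list(hyperparams = res$chosen, trace = res$trace)
}

#' Tune the random-forest bagging hyperparameters
#'
#' Coordinate-wise sweep over number of trees, then predictors sampled per
#' split, then minimum leaf size; one whole-domain forest per candidate is
#' fit on 80% of the pooled hyperopt rows and scored by RMSE on the held
#' out 20% test subset. Default grids follow the full search (trees 1-200,
#' predictors 1-(F-1), leaf 1-30).
#'
#' @inheritParams tune_nn
#' @param grids named list `n_trees`, `n_predictors_per_split`, `min_leaf`.
#' @return As [tune_nn()].
#' @export
tune_rfbag <- function(features_list, target_list,
                       grids = NULL, seed = 1L, max_rows = 4000L) {
  d <- pool_rows(features_list, target_list, max_rows, derive_seed(seed, 1L))
  Fdim <- ncol(d$X)
  if (is.null(grids))
    grids <- list(n_trees = 1:200,
                  n_predictors_per_split = seq_len(max(1L, Fdim - 1L)),
                  min_leaf = 1:30)
  split <- local_seed(derive_seed(seed, 2L), {
    n_te <- floor(nrow(d$X) * 0.2)
    sample.int(nrow(d$X), n_te)
  })
  df <- as.data.frame(d$X); names(df) <- paste0("f", seq_len(Fdim))
  df$.y <- d$y
  tr <- df[-split, , drop = FALSE]; te <- df[split, , drop = FALSE]

  objective <- function(hp) {
    fit <- ranger::ranger(dependent.variable.name = ".y", data = tr,
                          num.trees = hp$n_trees,
                          mtry = min(hp$n_predictors_per_split, Fdim),
                          min.node.size = hp$min_leaf,
                          splitrule = "variance",
                          seed = derive_seed(seed, 3L), num.threads = 1L)
    rmse(stats::predict(fit, data = te)$predictions, te$.y)
  }
  res <- coord_sweep(objective, grids,
                     init = list(n_trees = grids$n_trees[1L],
                                 n_predictors_per_split = grids$n_predictors_per_split[1L],
                                 min_leaf = grids$min_leaf[1L]))
  list(hyperparams = res$chosen, trace = res$trace)
}
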