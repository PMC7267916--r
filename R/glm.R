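# Per-parcel GLM: beta = pinv(X) %*% y on training rows aggregated across
# subjects; prediction = X %*% beta assembled parcel by parcel.

# Extract the z vector from a task_map or pass a numeric vector through.
task_z <- function(y) if (is.list(y)) y$z else y

# Stack one parcel's rows across subjects: X (sum_i |parcel| x F), y.
stack_parcel <- function(features_list, target_list, idx) {
  X <- do.call(rbind, lapply(features_list, function(Xi) Xi[idx, , drop = FALSE]))
  y <- unlist(lapply(target_list, function(yi) task_z(yi)[idx]), use.names = FALSE)
  list(X = X, y = y)
}

check_model_inputs <- function(features_list, target_list, parcellation) {
  if (length(features_list) != length(target_list))
    stop("feature and target lists must have equal length", call. = FALSE)
  V <- length(parcellation$labels)
  for (Xi in features_list)
    if (nrow(Xi) != V) stop("feature matrix rows must match the parcellation",
                            call. = FALSE)
}

#' Fit the per-parcel GLM predictor
#'
#' For each parcel, stacks the parcel's vertices across all training
#' subjects into one design and computes the minimum-norm least-squares
#' coefficients `beta = pinv(X) %*% y`, giving an `F x P` coefficient
#' matrix (one column per parcel).
#'
#' @param features_list named list of per-subject `n_vertices x F` feature
#'   matrices (training subjects).
#' @param target_list matching list of task maps (or numeric z vectors).
#' @param parcellation a `parcellation`.
#' @return A `parcel_model` of kind `"glm"` with the `beta` matrix.
#' @export
fit_glm <- function(features_list, target_list, parcellation) {
  check_model_inputs(features_list, target_list, parcellation)
  P <- parcellation$n_parcels
  Fdim <- ncol(features_list[[1L]])
  beta <- matrix(0, Fdim, P)
  for (p in seq_len(P)) {
    idx <- which(parcellation$labels == p)
    if (!length(idx)) stop("parcel ", p, " is empty", call. = FALSE)
    d <- stack_parcel(features_list, target_list, idx)
    beta[, p] <- drop(pinv(d$X) %*% d$y)
  }
  structure(list(kind = "glm", beta = beta, parcellation = parcellation,
                 n_features = Fdim,
                 meta = list(n_train = length(features_list))),
            class = "parcel_model")
}

#' Predict a task map with a fitted parcel model
#'
#' Assembles the full-vertex predicted map, each vertex written exactly once
#' by its parcel's predictor.
#'
#' @param model a `parcel_model` (any kind).
#' @param X `n_vertices x F` feature matrix of the test subject.
#' @return Numeric vector of predicted z-scores over vertices.
#' @export
predict_parcel_model <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features,
         call. = FALSE)
  parc <- model$parcellation
  if (nrow(X) != length(parc$labels))
    stop("vertex count mismatch with the model's parcellation", call. = FALSE)
  y <- numeric(nrow(X))
  for (p in seq_len(parc$n_parcels)) {
    idx <- which(parc$labels == p)
    if (!length(idx)) next
    y[idx] <- predict_one_parcel(model, p, X[idx, , drop = FALSE])
  }
  y
}

predict_one_parcel <- function(model, p, Xp) {
  switch(model$kind,
         glm = drop(Xp %*% model$beta[, p]),
         nn = mlp_predict(model$nets[[p]], Xp),
         rfbag = {
           df <- as.data.frame(Xp)
           names(df) <- model$feature_names
           as.numeric(stats::predict(model$forests[[p]], data = df)$predictions)
         },
         stop("unknown model kind: ", model$kind, call. = FALSE))
}

#' @export
print.parcel_model <- function(x, ...) {
  cat(sprintf("parcel_model: kind=%s, %d parcels, %d features\n",
              x$kind, x$parcellation$n_parcels, x$n_features))
  invisible(x)
}
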