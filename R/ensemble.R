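# Ensemble-of-models averaging: M independently seeded trainings of the
# same model family; the M predicted maps are averaged into one map.

fit_parcel_model <- function(kind, features_list, target_list, parcellation,
                             hyperparams = list(), seed = 1L) {
  switch(kind,
         glm = fit_glm(features_list, target_list, parcellation),
         nn = fit_nn(features_list, target_list, parcellation,
                     hyperparams = hyperparams, seed = seed),
         rfbag = do.call(fit_rfbag,
                         c(list(features_list, target_list, parcellation,
                                seed = seed), hyperparams)),
         stop("unknown model kind: ", kind, call. = FALSE))
}

#' Train an ensemble of per-parcel models
#'
#' Trains `M` models of the same family that differ only in their random
#' splits / initializations / bootstraps (member seeds derive from `seed`).
#' A failed member is retrained with the next derived seed (bounded
#' retries). The GLM is deterministic, so all its members coincide.
#'
#' @param kind `"glm"`, `"nn"` or `"rfbag"`.
#' @inheritParams fit_glm
#' @param hyperparams passed to the member fitter.
#' @param M number of members (>= 1).
#' @param seed master seed for the members.
#' @param max_retries retrain attempts per failed member.
#' @return A `parcel_ensemble` holding the `M` members.
#' @export
train_ensemble <- function(kind, features_list, target_list, parcellation,
                           hyperparams = list(), M = 1L, seed = 1L,
                           max_retries = 3L) {
  stopifnot_scalar_count(M, "M")
  members <- vector("list", M)
  for (m in seq_len(M)) {
    fit <- NULL
    for (attempt in 0:max_retries) {
      fit <- try(fit_parcel_model(kind, features_list, target_list, parcellation,
                                  hyperparams = hyperparams,
                                  seed = derive_seed(seed, m * 1000L + attempt)),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) break
    }
    if (inherits(fit, "try-error"))
      stop("ensemble member ", m, " failed after retries: ",
           attr(fit, "condition")$message, call. = FALSE)
    members[[m]] <- fit
  }
  structure(list(kind = kind, members = members, M = M,
                 parcellation = parcellation, seed = seed),
            class = "parcel_ensemble")
}

#' Predict with an ensemble (mean of member maps)
#'
#' @param ensemble a `parcel_ensemble`.
#' @param X `n_vertices x F` feature matrix of the test subject.
#' @return Predicted z-score map (arithmetic mean over members).
#' @export
predict_ensemble <- function(ensemble, X) {
  preds <- lapply(ensemble$members, function(m) predict_parcel_model(m, X))
  rowMeans(do.call(cbind, preds))
}

#' @export
print.parcel_ensemble <- function(x, ...) {
  cat(sprintf("parcel_ensemble: kind=%s, M=%d members\n", x$kind, x$M))
  invisible(x)
}
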