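# Evaluation: cross-subject correlation matrices, normalization, accuracy,
# Dice overlap, repeated-measures ANOVA, diagonal-dominance permutation
# test, and learning / averaging curves.

#' Cross-subject prediction correlation matrix
#'
#' Entry (i, j) is the Pearson correlation over vertices between subject
#' i's predicted map and subject j's actual map; the diagonal therefore
#' holds each subject's own prediction accuracy.
#'
#' @param predicted,actual equal-length named lists (or matrices with one
#'   column per subject) of vertex maps on the same vertex set.
#' @return `S x S` matrix with subject ids on the dimnames.
#' @export
prediction_matrix <- function(predicted, actual) {
  P <- as_map_matrix(predicted)
  A <- as_map_matrix(actual)
  if (!identical(dim(P), dim(A)))
    stop("predicted and actual maps must cover the same subjects and vertices",
         call. = FALSE)
  for (j in seq_len(ncol(P))) {
    if (stats::sd(P[, j]) < 1e-12)
      stop("zero-variance predicted map for subject ", colnames(P)[j] %||% j,
           call. = FALSE)
    if (stats::sd(A[, j]) < 1e-12)
      stop("zero-variance actual map for subject ", colnames(A)[j] %||% j,
           call. = FALSE)
  }
  M <- stats::cor(P, A)
  dimnames(M) <- list(predicted = colnames(P), actual = colnames(A))
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_map_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  out <- vapply(maps, function(m) as.numeric(task_z(m)),
                numeric(length(task_z(maps[[1L]]))))
  if (is.null(colnames(out)) && !is.null(names(maps))) colnames(out) <- names(maps)
  out
}

#' Row-and-column standardization of a correlation matrix
#'
#' Alternately standardizes rows (mean 0, SD 1) then columns, repeating the
#' sweep until the matrix stops changing, which accounts for the differing
#' variances of actual and predicted maps across subjects. The fixpoint has
#' exactly standardized columns and (to tolerance) standardized rows, and
#' renormalizing a normalized matrix leaves it unchanged. The scheme is
#' recorded in the `"normalization"` attribute.
#'
#' @param m square numeric matrix.
#' @param tol,max_sweeps convergence controls for the alternating sweeps.
#' @return Normalized matrix of the same shape.
#' @export
normalize_matrix <- function(m, tol = 1e-10, max_sweeps = 500L) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(!is.finite(m)))
    stop("`m` must be a finite square matrix", call. = FALSE)
  rs <- apply(m, 1L, stats::sd); cs0 <- apply(m, 2L, stats::sd)
  if (any(rs < 1e-12) || any(cs0 < 1e-12))
    stop("zero-variance row or column; cannot normalize", call. = FALSE)
  dm <- dimnames(m)
  for (i in seq_len(max_sweeps)) {
    prev <- m
    m <- t(scale(t(m)))        # rows
    m <- scale(m)              # then columns
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (max(abs(m - prev)) < tol) break
  }
  dimnames(m) <- dm
  attr(m, "normalization") <- "alternating row/column z-score to convergence"
  m
}

#' Prediction accuracy: mean diagonal correlation
#'
#' Mean of the diagonal of the raw (non-normalized) prediction matrix —
#' the average correlation between each subject's actual and predicted map.
#'
#' @param m a raw prediction matrix.
#' @return A single number.
#' @export
prediction_accuracy <- function(m) mean(diag(as.matrix(m)))

#' Diagonal-dominance permutation test
#'
#' Statistic: mean diagonal minus mean off-diagonal entry. The null
#' permutes the predicted-to-actual subject pairing (rows) and recomputes
#' the statistic.
#'
#' @param m raw prediction matrix.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return List with `statistic` and permutation `p`.
#' @export
diagonal_dominance <- function(m, n_perm = 999L, seed = 1L) {
  m <- as.matrix(m)
  stat <- function(x) mean(diag(x)) - mean(x[row(x) != col(x)])
  obs <- stat(m)
  perm <- local_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(m[sample.int(nrow(m)), , drop = FALSE]), numeric(1L)))
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Dice overlap coefficient
#'
#' `2 |A1 n A2| / (|A1| + |A2|)` for two binary masks of equal length.
#' Two empty masks give 0, flagged via the `"both_empty"` attribute.
#'
#' @param a1,a2 logical (or 0/1) vectors of equal length.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a1, a2) {
  a1 <- as.logical(a1); a2 <- as.logical(a2)
  if (length(a1) != length(a2)) stop("mask lengths differ", call. = FALSE)
  denom <- sum(a1) + sum(a2)
  if (denom == 0L) return(structure(0, both_empty = TRUE))
  2 * sum(a1 & a2) / denom
}

#' Repeated-measures ANOVA comparison of models
#'
#' One-way repeated-measures ANOVA (model as the within-subject factor)
#' computed from the standard sums of squares, followed by one-sided paired
#' t-tests for the ordered contrasts (each later model > each earlier one
#' in `colnames(scores)` order), Bonferroni-corrected by the number of
#' pairwise tests.
#'
#' @param scores `S subjects x K models` matrix of per-subject scores
#'   (e.g. diagonal correlations), columns ordered weakest to strongest
#'   expected model.
#' @return List: `F`, `df`, `p`, and a `pairwise` data frame with raw and
#'   Bonferroni-corrected one-sided p-values.
#' @export
compare_models <- function(scores) {
  scores <- as.matrix(scores)
  S <- nrow(scores); K <- ncol(scores)
  if (K < 2L) stop("need at least 2 models", call. = FALSE)
  if (S < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)

  grand <- mean(scores)
  ss_model <- S * sum((colMeans(scores) - grand)^2)
  ss_subj <- K * sum((rowMeans(scores) - grand)^2)
  ss_tot <- sum((scores - grand)^2)
  ss_err <- ss_tot - ss_model - ss_subj
  df_model <- K - 1L
  df_err <- (S - 1L) * (K - 1L)
  ms_model <- ss_model / df_model
  ms_err <- ss_err / df_err
  if (ms_model < 1e-300) {
    Fstat <- 0; p <- 1
  } else if (ms_err < 1e-300) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- ms_model / ms_err
    p <- stats::pf(Fstat, df_model, df_err, lower.tail = FALSE)
  }

  names_k <- colnames(scores) %||% paste0("model", seq_len(K))
  pairs <- utils::combn(K, 2L)
  n_tests <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_tests), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]   # tests model b > model a
    d <- scores[, b] - scores[, a]
    if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
      p1 <- if (mean(d) > 0) 0 else 1
    } else {
      p1 <- stats::t.test(d, alternative = "greater")$p.value
    }
    data.frame(contrast = paste(names_k[b], ">", names_k[a]),
               mean_difference = mean(d), p = p1,
               p_bonferroni = min(1, p1 * n_tests))
  }))
  list(F = Fstat, df = c(df_model, df_err), p = p,
       n_pairwise_tests = n_tests, pairwise = pw)
}

#' Learning and averaging curves
#'
#' Mean diagonal correlation as a function of the number of training
#' subjects (`n_train_grid`) and of ensemble averages (`M_grid`), with the
#' same test subjects throughout. Training subjects for size `n` are the
#' first `n` of `train_ids` (nested subsets).
#'
#' @param feature_list named per-subject feature matrices.
#' @param target_list matching named task maps.
#' @param parcellation a `parcellation`.
#' @param kind model family.
#' @param train_ids,test_ids subject id vectors.
#' @param n_train_grid grid of training-set sizes.
#' @param M_grid grid of ensemble sizes.
#' @param hyperparams member hyperparameters.
#' @param seed RNG seed.
#' @return Data frame `kind`, `n_train`, `M`, `mean_cc`.
#' @export
learning_curve <- function(feature_list, target_list, parcellation, kind,
                           train_ids, test_ids,
                           n_train_grid = c(5L, 10L, 20L, 40L),
                           M_grid = 1L, hyperparams = list(), seed = 1L) {
  if (max(n_train_grid) > length(train_ids))
    stop("`n_train_grid` exceeds the available training subjects", call. = FALSE)
  grid <- expand.grid(n_train = n_train_grid, M = M_grid)
  actual <- target_list[test_ids]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n_train[i]; M <- grid$M[i]
    ids <- train_ids[seq_len(n)]
    ens <- train_ensemble(kind, feature_list[ids], target_list[ids],
                          parcellation, hyperparams = hyperparams, M = M,
                          seed = derive_seed(seed, i))
    preds <- lapply(test_ids, function(id) predict_ensemble(ens, feature_list[[id]]))
    names(preds) <- test_ids
    data.frame(kind = kind, n_train = n, M = M,
               mean_cc = prediction_accuracy(prediction_matrix(preds, actual)))
  })
  do.call(rbind, out)
}
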