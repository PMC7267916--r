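#' Normalize a resting run to zero mean, unit SD per vertex
#'
#' @param run `n_vertices x n_timepoints` matrix.
#' @return Matrix of the same shape; each vertex's series has mean 0 and
#'   SD 1. All-constant series are set to zeros and their indices recorded
#'   in the `"constant_vertices"` attribute.
#' @export
normalize_timeseries <- function(run) {
  run <- as.matrix(run)
  if (ncol(run) < 2L) stop("a run needs at least 2 timepoints", call. = FALSE)
  mu <- rowMeans(run)
  sdv <- apply(run, 1L, stats::sd)
  out <- run - mu
  ok <- sdv > 1e-12
  out[ok, ] <- out[ok, , drop = FALSE] / sdv[ok]
  out[!ok, ] <- 0
  attr(out, "constant_vertices") <- which(!ok)
  out
}

# Concatenate a subject's normalized runs along time.
concat_runs <- function(runs) {
  do.call(cbind, lapply(runs, normalize_timeseries))
}

#' Group dimensionality reduction (PCA over concatenated runs)
#'
#' Reduces the temporally concatenated, per-vertex-normalized cohort data to
#' `target_dim` principal components. Computed incrementally from the
#' accumulated vertex-by-vertex covariance (one run in memory at a time),
#' which equals exact PCA of the concatenated matrix up to numerical
#' tolerance.
#'
#' @param subjects list of `subject_data` (each with `$runs`).
#' @param target_dim number of components to keep.
#' @return `target_dim x n_vertices` matrix of scaled spatial eigenvectors
#'   (pseudo time courses); attribute `"explained_variance"` carries the
#'   full eigenvalue fractions.
#' @export
group_reduce <- function(subjects, target_dim) {
  stopifnot_scalar_count(target_dim, "target_dim")
  total_t <- sum(vapply(subjects, function(s)
    sum(vapply(s$runs, ncol, 0L)), 0))
  if (target_dim > total_t)
    stop("`target_dim` exceeds the total number of timepoints", call. = FALSE)

  V <- nrow(subjects[[1L]]$runs[[1L]])
  C <- matrix(0, V, V)
  for (s in subjects) for (r in s$runs) {
    x <- normalize_timeseries(r)
    C <- C + tcrossprod(x)
  }
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- seq_len(target_dim)
  reduced <- sqrt(ev[keep]) * t(e$vectors[, keep, drop = FALSE])
  attr(reduced, "explained_variance") <- ev / sum(ev)
  reduced
}

#' Spatial group ICA on one hemisphere
#'
#' Fixed-point negentropy-maximizing ICA (tanh contrast, deflation) applied
#' to the reduced group matrix restricted to one hemisphere, yielding `k`
#' independent spatial maps. Maps are sign-fixed to non-negative skewness
#' and ordered by decreasing explained variance (back-projection energy), so
#' the decomposition is deterministic under a fixed seed.
#'
#' @param reduced `d x n_vertices` reduced matrix from [group_reduce()].
#' @param space a `brain_space`.
#' @param hemisphere `"L"` or `"R"`.
#' @param k number of components (<= d).
#' @param seed RNG seed for the random orthogonal start.
#' @param maxit,tol fixed-point iteration controls.
#' @param attempts restarts with fresh seeds before giving up.
#' @return `n_hemisphere_vertices x k` matrix of spatial maps (unit
#'   variance per map).
#' @export
group_ica <- function(reduced, space, hemisphere = c("L", "R"), k,
                      seed = 1L, maxit = 1000L, tol = 1e-6, attempts = 3L) {
  hemisphere <- match.arg(hemisphere)
  stopifnot_scalar_count(k, "k")
  if (k > nrow(reduced)) stop("`k` exceeds the reduced dimension", call. = FALSE)
  X <- reduced[, space_indices(space, hemisphere), drop = FALSE]

  for (a in seq_len(attempts)) {
    fit <- try(fast_ica(X, k, seed = derive_seed(seed, a - 1L),
                        maxit = maxit, tol = tol), silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit)
  }
  stop("group_ica did not converge after ", attempts, " restarts", call. = FALSE)
}

# FastICA by deflation on a d x n matrix whose rows are mixtures of k
# independent spatial sources. Returns n x k source maps.
fast_ica <- function(X, k, seed, maxit = 1000L, tol = 1e-6) {
  d <- nrow(X); n <- ncol(X)
  X <- X - rowMeans(X)
  s <- svd(X, nu = min(d, n), nv = 0)
  keep <- which(s$d > 1e-10 * s$d[1L])
  if (length(keep) < k) stop("data rank below k", call. = FALSE)
  keep <- keep[seq_len(max(k, min(length(keep), k)))]
  K <- (1 / s$d[keep]) * t(s$u[, keep, drop = FALSE])  # whitening: Z = sqrt(n) K X
  Z <- sqrt(n) * (K %*% X)                             # k' x n, rows unit variance

  W <- matrix(0, k, nrow(Z))
  init <- local_seed(seed, matrix(stats::rnorm(k * nrow(Z)), k, nrow(Z)))
  for (p in seq_len(k)) {
    w <- init[p, ]
    w <- w / sqrt(sum(w^2))
    prev_delta <- Inf
    damp <- FALSE   # sign-aligned averaging kills the period-2 limit
                    # cycles the plain fixed-point update can enter
    for (it in seq_len(maxit)) {
      wz <- drop(w %*% Z)
      g <- tanh(wz)
      w_new <- drop(Z %*% g) / n - mean(1 - g^2) * w
      if (p > 1L) {
        proj <- t(W[seq_len(p - 1L), , drop = FALSE]) %*%
          (W[seq_len(p - 1L), , drop = FALSE] %*% w_new)
        w_new <- w_new - drop(proj)
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) stop("degenerate ICA direction", call. = FALSE)
      w_new <- w_new / nrm
      delta <- abs(abs(sum(w_new * w)) - 1)
      converged <- delta < tol
      if (!converged && damp) {
        w_new <- w_new * sign(sum(w_new * w)) + w
        w_new <- w_new / sqrt(sum(w_new^2))
      }
      if (!damp && it > 10L && delta >= prev_delta) damp <- TRUE
      prev_delta <- delta
      w <- w_new
      if (converged) break
    }
    if (!converged) stop("fastICA fixed point did not converge", call. = FALSE)
    W[p, ] <- w
  }

  S <- t(W %*% Z)  # n x k, unit-variance sources
  # sign: non-negative skewness; order: back-projection energy
  for (j in seq_len(k)) {
    sk <- mean(S[, j]^3)
    if (sk < 0) S[, j] <- -S[, j]
  }
  energy <- colSums((X %*% S)^2)
  S[, order(energy, decreasing = TRUE), drop = FALSE]
}

#' Filter components by left-right symmetry
#'
#' Greedy one-to-one matching of left to right components by the absolute
#' spatial correlation of each left map with each right map brought into
#' left-hemisphere register via the mirror map; pairs scoring at or above
#' `threshold` are retained, ordered by score.
#'
#' @param left_maps `n x kL` left-hemisphere maps.
#' @param right_maps `n x kR` right-hemisphere maps, row `i` corresponding
#'   to the mirror of left vertex `i` (the layout [make_space()] produces).
#' @param threshold minimum |correlation| to retain a pair (default 0.5).
#' @return A `group_components` list: retained `pairs` data frame
#'   (`left`, `right`, `score`), plus the input maps.
#' @export
filter_symmetric <- function(left_maps, right_maps, threshold = 0.5) {
  left_maps <- as.matrix(left_maps); right_maps <- as.matrix(right_maps)
  if (nrow(left_maps) != nrow(right_maps))
    stop("left and right maps must share the mirrored vertex count", call. = FALSE)
  cc <- abs(stats::cor(left_maps, right_maps))
  kL <- ncol(left_maps); kR <- ncol(right_maps)

  pairs <- data.frame(left = integer(), right = integer(), score = numeric())
  avail_l <- rep(TRUE, kL); avail_r <- rep(TRUE, kR)
  repeat {
    m <- cc
    m[!avail_l, ] <- -Inf; m[, !avail_r] <- -Inf
    best <- arrayInd(which.max(m), dim(m))
    if (!is.finite(m[best]) || m[best] < threshold) break
    pairs <- rbind(pairs, data.frame(left = best[1L], right = best[2L],
                                     score = m[best]))
    avail_l[best[1L]] <- FALSE; avail_r[best[2L]] <- FALSE
    if (!any(avail_l) || !any(avail_r)) break
  }
  if (nrow(pairs) == 0L) {
    warning("no symmetric component pairs at threshold ", threshold)
    stop("symmetry filtering retained no components; no features possible",
         call. = FALSE)
  }
  structure(list(left_maps = left_maps, right_maps = right_maps,
                 pairs = pairs, threshold = threshold),
            class = "group_components")
}

# Assemble retained components into full-space regressor maps
# (n_vertices x 2*retained): left components on left vertices, matched
# right components on right vertices, zero elsewhere.
component_maps <- function(components, space) {
  n <- space$n_per_hemisphere
  r <- nrow(components$pairs)
  maps <- matrix(0, space$n_vertices, 2L * r)
  for (j in seq_len(r)) {
    maps[seq_len(n), j] <- components$left_maps[, components$pairs$left[j]]
    maps[n + seq_len(n), r + j] <- components$right_maps[, components$pairs$right[j]]
  }
  colnames(maps) <- c(paste0("L", seq_len(r)), paste0("R", seq_len(r)))
  maps
}

#' Dual regression: subject-level maps from group maps
#'
#' Stage 1 regresses each timepoint of the subject's concatenated,
#' normalized runs onto the group spatial maps, giving one time course per
#' component; stage 2 regresses each vertex's time series onto those time
#' courses, giving the subject's spatial maps. Rank-deficient designs fall
#' back to the minimum-norm least-squares solution with a warning.
#'
#' @param runs list of `n_vertices x time` run matrices.
#' @param group_maps `n_vertices x C` spatial regressors.
#' @return `n_vertices x C` subject spatial maps; the stage-1 time courses
#'   are attached as attribute `"time_courses"` (`C x time`).
#' @export
dual_regression <- function(runs, group_maps) {
  group_maps <- as.matrix(group_maps)
  if (ncol(group_maps) < 1L) stop("need at least one group map", call. = FALSE)
  Y <- concat_runs(runs)
  Pg <- pinv(group_maps)
  if (attr(Pg, "rank") < ncol(group_maps))
    warning("rank-deficient spatial design; minimum-norm solution used")
  tc <- Pg %*% Y                       # C x T
  Pt <- pinv(t(tc))
  if (attr(Pt, "rank") < nrow(tc))
    warning("rank-deficient temporal design; minimum-norm solution used")
  maps <- t(Pt %*% t(Y))               # V x C
  dimnames(maps) <- list(NULL, colnames(group_maps))
  attr(maps, "time_courses") <- tc
  maps
}

#' Mean time course per subcortical structure
#'
#' @param runs list of run matrices.
#' @param space a `brain_space`.
#' @return `n_structures x time` matrix (runs concatenated after
#'   normalization).
#' @export
subcortical_signals <- function(runs, space) {
  Y <- concat_runs(runs)
  out <- matrix(0, space$n_structures, ncol(Y))
  for (s in seq_len(space$n_structures)) {
    members <- which(space$structure == s)
    if (!length(members)) stop("subcortical structure ", s, " is empty", call. = FALSE)
    out[s, ] <- colMeans(Y[members, , drop = FALSE])
  }
  out
}

#' Connectivity feature maps for one subject
#'
#' (a) Regresses the subject's concatenated normalized time series onto the
#' stacked spatial design (subject dual-regression maps plus subcortical
#' indicator maps), yielding one time course per feature; (b) correlates
#' each feature time course with every grayordinate's time series; (c)
#' z-scores each feature column. Zero-variance vertices get feature value 0.
#'
#' @param runs list of run matrices.
#' @param subject_maps `n_vertices x C` subject spatial maps.
#' @param space a `brain_space`.
#' @param normalize z-score the columns (default TRUE).
#' @return A `feature_maps` list: `id` (optional), `X`
#'   (`n_vertices x F`, `F = C + n_structures`), `normalized`.
#' @export
feature_maps <- function(runs, subject_maps, space, normalize = TRUE) {
  subject_maps <- as.matrix(subject_maps)
  D <- cbind(subject_maps, subcortical_indicators(space))
  if (ncol(D) == 0L) stop("no features to extract", call. = FALSE)
  Y <- concat_runs(runs)
  tc <- pinv(D) %*% Y                  # F x T feature time courses

  Yc <- Y - rowMeans(Y)
  Tc <- tc - rowMeans(tc)
  ysd <- sqrt(rowSums(Yc^2))
  tsd <- sqrt(rowSums(Tc^2))
  X <- (Yc %*% t(Tc))
  ok_v <- ysd > 1e-12; ok_f <- tsd > 1e-12
  X[ok_v, ] <- X[ok_v, , drop = FALSE] / ysd[ok_v]
  X[, ok_f] <- sweep(X[, ok_f, drop = FALSE], 2L, tsd[ok_f], "/")
  X[!ok_v, ] <- 0
  X[, !ok_f] <- 0

  if (normalize) X <- zscore_cols(X)
  structure(list(X = X, normalized = normalize,
                 n_components = ncol(subject_maps),
                 n_subcortical = space$n_structures),
            class = "feature_maps")
}

#' Run the full feature-extraction pipeline on a cohort
#'
#' Group PCA on all subjects' concatenated runs, per-hemisphere spatial ICA,
#' left-right symmetry filtering, dual regression per subject, and
#' correlation feature maps with subcortical parcels.
#'
#' @param cohort a `cohort`.
#' @param target_dim group PCA dimension.
#' @param k_ica ICA components per hemisphere.
#' @param sym_threshold symmetry-filter threshold.
#' @param seed RNG seed (ICA restarts).
#' @return A list with `components` (the retained symmetric set),
#'   `feature_list` (named per-subject `n_vertices x F` matrices), and the
#'   symmetry-score table.
#' @export
extract_features <- function(cohort, target_dim = 20L, k_ica = NULL,
                             sym_threshold = 0.5, seed = 1L) {
  space <- cohort$space
  if (is.null(k_ica)) k_ica <- cohort$truth$k_per_hemisphere
  reduced <- group_reduce(cohort$subjects, target_dim)
  left <- group_ica(reduced, space, "L", k_ica, seed = derive_seed(seed, 11L))
  right <- group_ica(reduced, space, "R", k_ica, seed = derive_seed(seed, 12L))
  comps <- filter_symmetric(left, right, threshold = sym_threshold)
  G <- component_maps(comps, space)

  feature_list <- lapply(cohort$subjects, function(s) {
    maps <- dual_regression(s$runs, G)
    feature_maps(s$runs, maps, space)$X
  })
  names(feature_list) <- names(cohort$subjects)
  list(components = comps, feature_list = feature_list,
       symmetry_scores = comps$pairs)
}
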