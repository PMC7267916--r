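#' Generate mirrored group network maps
#'
#' Plants `k` spatially smooth, approximately non-overlapping network maps
#' per hemisphere. Left-hemisphere maps are smoothed bumps around
#' well-separated seed vertices (farthest-point sampling on the mesh graph);
#' each right-hemisphere map is the exact mirror image of its left
#' counterpart, emulating the left-right symmetric organisation of
#' large-scale resting-state networks.
#'
#' @param space a `brain_space`.
#' @param k_per_hemisphere number of networks per hemisphere.
#' @param smoothness number of diffusion-smoothing steps applied to each
#'   seed indicator (larger = smoother, wider networks). `smoothness = 0`
#'   leaves unsmoothed indicator noise-like maps.
#' @param seed RNG seed.
#' @return A `cohort_truth` list holding the group maps
#'   (`n_vertices x 2k`, columns `L1..Lk, R1..Rk`, zero off-hemisphere and
#'   on subcortex) and generator metadata.
#' @export
make_group_networks <- function(space, k_per_hemisphere, smoothness = 6, seed = 1L) {
  stopifnot(inherits(space, "brain_space"))
  stopifnot_scalar_count(k_per_hemisphere, "k_per_hemisphere")
  if (smoothness < 0) stop("`smoothness` must be non-negative", call. = FALSE)
  k <- as.integer(k_per_hemisphere)
  n <- space$n_per_hemisphere
  if (k > n) stop("`k_per_hemisphere` exceeds hemisphere vertex count", call. = FALSE)

  g_left <- igraph::graph_from_adj_list(space$adjacency[seq_len(n)], mode = "all")

  seeds <- local_seed(seed, {
    s <- sample.int(n, 1L)
    d <- igraph::distances(g_left, v = s)[1L, ]
    for (i in seq_len(k - 1L)) {
      s <- c(s, which.max(d))
      d <- pmin(d, igraph::distances(g_left, v = s[length(s)])[1L, ])
    }
    s
  })

  bump <- matrix(0, n, k)
  bump[cbind(seeds, seq_len(k))] <- 1
  left <- smooth_cortical_hemisphere(space, bump, smoothness)
  left <- scale(left, center = FALSE, scale = apply(left, 2L, stats::sd))

  maps <- matrix(0, space$n_vertices, 2L * k)
  maps[seq_len(n), seq_len(k)] <- left
  maps[n + seq_len(n), k + seq_len(k)] <- left  # mirror: right vertex n+i <-> left i
  colnames(maps) <- c(paste0("L", seq_len(k)), paste0("R", seq_len(k)))

  structure(list(
    space = space,
    group_maps = maps,
    k_per_hemisphere = k,
    smoothness = smoothness,
    network_seed = as.integer(seed),
    seeds_left = seeds
  ), class = "cohort_truth")
}

# Smooth a left-hemisphere-sized matrix on the left-hemisphere subgraph only.
smooth_cortical_hemisphere <- function(space, x, steps) {
  n <- space$n_per_hemisphere
  A <- space$A[seq_len(n), seq_len(n), drop = FALSE]
  deg <- Matrix::rowSums(A); deg[deg == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  x <- as.matrix(x)
  for (i in seq_len(max(0L, round(steps)))) x <- as.matrix((x + W %*% x) / 2)
  x
}

#' Generate one synthetic subject
#'
#' The subject's network maps are the group maps plus a smooth
#' subject-specific perturbation (an additive smoothed Gaussian random field
#' on each map's supporting hemisphere) scaled by `subject_variability`
#' relative to the group map's spatial SD. Each resting run is the outer
#' product of the subject's spatial design (network maps plus subcortical
#' indicator maps) with independent unit-variance AR(1) network time courses
#' (lag-1 autocorrelation 0.3), plus white Gaussian noise.
#'
#' @param space a `brain_space`.
#' @param truth a `cohort_truth` from [make_group_networks()].
#' @param subject_variability perturbation scale (0 = subject equals group).
#' @param ts_noise_sd SD of additive time-series noise.
#' @param n_runs,n_timepoints runs per subject and samples per run.
#' @param seed RNG seed.
#' @param id subject identifier.
#' @return A `subject_data` list (`id`, `runs`, later `task_maps`) plus the
#'   per-subject truth. Because the analysis pipeline works on per-vertex
#'   variance-normalized series, the truth's `subject_maps` and spatial
#'   `design` are expressed in those normalized units (the raw-amplitude
#'   versions are kept as `subject_maps_raw` / `design_raw`).
#' @export
make_subject <- function(space, truth, subject_variability = 0.3, ts_noise_sd = 0.5,
                         n_runs = 4L, n_timepoints = 100L, seed = 1L, id = "sub-01") {
  stopifnot(inherits(space, "brain_space"), inherits(truth, "cohort_truth"))
  if (subject_variability < 0) stop("`subject_variability` must be non-negative", call. = FALSE)
  if (ts_noise_sd < 0) stop("`ts_noise_sd` must be non-negative", call. = FALSE)
  stopifnot_scalar_count(n_runs, "n_runs")
  if (n_timepoints < 2) stop("`n_timepoints` must be >= 2", call. = FALSE)

  k <- truth$k_per_hemisphere
  n <- space$n_per_hemisphere
  V <- space$n_vertices

  local_seed(seed, {
    subj_maps <- truth$group_maps
    if (subject_variability > 0) {
      # one smooth field per map, supported on the map's own hemisphere
      noise <- matrix(stats::rnorm(n * 2L * k), n, 2L * k)
      field <- smooth_cortical_hemisphere(space, noise, truth$smoothness)
      field <- scale(field, center = FALSE, scale = apply(field, 2L, stats::sd))
      for (j in seq_len(2L * k)) {
        idx <- if (j <= k) seq_len(n) else n + seq_len(n)
        gsd <- stats::sd(truth$group_maps[idx, j])
        subj_maps[idx, j] <- subj_maps[idx, j] +
          subject_variability * gsd * field[if (j <= k) seq_len(n) else seq_len(n), j]
      }
    }
    raw_design <- cbind(subj_maps, subcortical_indicators(space))
    Fdim <- ncol(raw_design)

    runs <- lapply(seq_len(n_runs), function(r) {
      tc <- ar1_courses(n_timepoints, Fdim, rho = 0.3)
      ts <- raw_design %*% t(tc)
      if (ts_noise_sd > 0) ts <- ts + matrix(stats::rnorm(V * n_timepoints, sd = ts_noise_sd),
                                             V, n_timepoints)
      ts
    })
  })

  # The pipeline analyses per-vertex variance-normalized series, so the
  # ground truth is stored in those units: each vertex's analytic marginal
  # SD is sqrt(sum of squared loadings + noise variance) because the
  # network courses have unit marginal variance.
  sd_v <- sqrt(rowSums(raw_design^2) + ts_noise_sd^2)
  scale_v <- ifelse(sd_v > 1e-12, 1 / sd_v, 0)
  norm_design <- raw_design * scale_v

  list(
    subject = list(id = id, runs = runs, task_maps = list()),
    truth = list(id = id,
                 subject_maps = subj_maps * scale_v,
                 subject_maps_raw = subj_maps,
                 design = norm_design,
                 design_raw = raw_design,
                 vertex_sd = sd_v,
                 subject_variability = subject_variability,
                 ts_noise_sd = ts_noise_sd, seed = as.integer(seed))
  )
}

# Independent unit-marginal-variance AR(1) series, one column per network.
ar1_courses <- function(n_t, k, rho = 0.3) {
  e <- matrix(stats::rnorm(n_t * k), n_t, k)
  if (rho == 0) return(e)
  out <- e * sqrt(1 - rho^2)
  out[1L, ] <- e[1L, ]
  for (t in 2L:n_t) out[t, ] <- rho * out[t - 1L, ] + out[t, ]
  out
}

#' Group network maps in normalized-data units
#'
#' Rescales the group maps by the analytic per-vertex SD of a subject whose
#' maps equal the group maps (loadings plus noise variance), i.e. the
#' ground truth that variance-normalized group analyses estimate.
#'
#' @param truth a `cohort_truth`.
#' @param ts_noise_sd the cohort's time-series noise SD.
#' @return `n_vertices x 2k` matrix.
#' @export
normalized_group_maps <- function(truth, ts_noise_sd = 0) {
  raw <- cbind(truth$group_maps, subcortical_indicators(truth$space))
  sd_v <- sqrt(rowSums(raw^2) + ts_noise_sd^2)
  truth$group_maps * ifelse(sd_v > 1e-12, 1 / sd_v, 0)
}

#' True (generator-side) feature maps of a subject
#'
#' Column-standardized version of the subject's spatial design (network maps
#' plus subcortical indicators); this is the feature matrix the task link
#' acts on, and what the extracted connectivity features estimate.
#'
#' @param subject_truth per-subject truth from [make_subject()].
#' @return `n_vertices x F` matrix with columns of mean 0, SD 1.
#' @export
subject_features <- function(subject_truth) {
  zscore_cols(subject_truth$design)
}

#' Generate a task z-score map from subject features
#'
#' Per parcel, activation is a (linear or saturating nonlinear) combination
#' of the subject's true features: `y[p] = g(X[p, ]) %*% w[, p] + noise`,
#' with `g` the identity (linear link) or the fixed saturation
#' `g(x) = tanh(1.5 x)` (nonlinear link). The map is finally z-scored over
#' vertices (`standardize = TRUE`, the default); disable standardization to
#' keep the target exactly inside the feature span, which a no-intercept
#' GLM requires for exact recovery.
#'
#' @param subject_truth per-subject truth from [make_subject()].
#' @param parcellation a `parcellation` covering all vertices.
#' @param link_weights `F x P` matrix of feature-to-activation weights.
#' @param link_type `"linear"` or `"nonlinear"`.
#' @param task_noise_sd SD of additive vertexwise noise.
#' @param standardize z-score the map over vertices after generation.
#' @param seed RNG seed for the noise.
#' @param contrast contrast name.
#' @return A `task_map` list: `id`, `contrast`, numeric `z` over vertices.
#' @export
make_task_maps <- function(subject_truth, parcellation, link_weights,
                           link_type = c("linear", "nonlinear"),
                           task_noise_sd = 0.1, standardize = TRUE,
                           seed = 1L, contrast = "task1") {
  link_type <- match.arg(link_type)
  if (task_noise_sd < 0) stop("`task_noise_sd` must be non-negative", call. = FALSE)
  X <- subject_features(subject_truth)
  P <- parcellation$n_parcels
  if (is.null(dim(link_weights)) || ncol(link_weights) < P ||
      nrow(link_weights) != ncol(X))
    stop("`link_weights` must be an F x P matrix with weights for every parcel",
         call. = FALSE)

  y <- numeric(nrow(X))
  for (p in seq_len(P)) {
    idx <- which(parcellation$labels == p)
    if (!length(idx)) next
    H <- X[idx, , drop = FALSE]
    if (link_type == "nonlinear") H <- tanh(1.5 * H)
    y[idx] <- drop(H %*% link_weights[, p])
  }
  if (task_noise_sd > 0)
    y <- y + local_seed(seed, stats::rnorm(length(y), sd = task_noise_sd))
  if (standardize) y <- drop(scale(y))

  list(id = subject_truth$id, contrast = contrast, z = y,
       link_type = link_type, standardized = standardize)
}

#' Generate a full synthetic cohort
#'
#' Builds the space, mirrored group networks, a random Voronoi parcellation,
#' per-parcel task-link weights, and `n_subjects` subjects with resting runs
#' and task maps. Every parameter and derived seed is recorded in the
#' manifest so a cohort can be regenerated exactly.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_vertices_per_hemisphere,n_subcortical_structures space size.
#' @param k_per_hemisphere,smoothness group-network parameters.
#' @param n_parcels_per_hemisphere Voronoi parcels per hemisphere.
#' @param subject_variability,ts_noise_sd,n_runs,n_timepoints subject
#'   generator parameters.
#' @param link_type,task_noise_sd,standardize_tasks task-link parameters.
#' @param active_parcel_fraction,active_gain,baseline_gain focal-activation
#'   profile: a seeded `active_parcel_fraction` of parcels gets link
#'   weights scaled by `active_gain`, the rest by `baseline_gain`,
#'   emulating the localized activation of real task z maps.
#' @param seed master seed; all stage seeds derive from it.
#' @param dir optional directory: when given, subject/truth containers
#'   (RDS) and a JSON manifest are written there.
#' @return A `cohort` list: `space`, `truth` (group maps, parcellation, link
#'   weights, per-subject truths), `subjects`, `manifest`.
#' @export
make_cohort <- function(n_subjects = 60L,
                        n_vertices_per_hemisphere = 150L,
                        n_subcortical_structures = 8L,
                        k_per_hemisphere = 6L,
                        smoothness = 6,
                        n_parcels_per_hemisphere = 10L,
                        subject_variability = 0.3,
                        ts_noise_sd = 0.5,
                        n_runs = 2L,
                        n_timepoints = 80L,
                        link_type = "linear",
                        task_noise_sd = 0.1,
                        standardize_tasks = TRUE,
                        active_parcel_fraction = 0.3,
                        active_gain = 3,
                        baseline_gain = 0.3,
                        seed = 1L,
                        dir = NULL) {
  stopifnot_scalar_count(n_subjects, "n_subjects", min = 3)

  manifest <- list(
    n_subjects = n_subjects,
    n_vertices_per_hemisphere = n_vertices_per_hemisphere,
    n_subcortical_structures = n_subcortical_structures,
    k_per_hemisphere = k_per_hemisphere,
    smoothness = smoothness,
    n_parcels_per_hemisphere = n_parcels_per_hemisphere,
    subject_variability = subject_variability,
    ts_noise_sd = ts_noise_sd,
    n_runs = n_runs,
    n_timepoints = n_timepoints,
    link_type = link_type,
    task_noise_sd = task_noise_sd,
    standardize_tasks = standardize_tasks,
    active_parcel_fraction = active_parcel_fraction,
    active_gain = active_gain,
    baseline_gain = baseline_gain,
    seed = as.integer(seed)
  )

  space <- make_space(n_vertices_per_hemisphere, n_subcortical_structures,
                      seed = derive_seed(seed, 1L))
  truth <- make_group_networks(space, k_per_hemisphere, smoothness,
                               seed = derive_seed(seed, 2L))
  parc <- voronoi_parcellate(space, n_parcels_per_hemisphere,
                             seed = derive_seed(seed, 3L))

  # Focal activation: a seeded subset of parcels carries strong
  # feature-to-task weights, the rest stay weak, so task maps show the
  # localized, heavy-tailed activation structure of real z maps.
  Fdim <- 2L * truth$k_per_hemisphere + space$n_structures
  weights <- local_seed(derive_seed(seed, 4L), {
    w <- matrix(stats::rnorm(Fdim * parc$n_parcels) / sqrt(Fdim),
                Fdim, parc$n_parcels)
    gain <- rep(baseline_gain, parc$n_parcels)
    n_active <- max(1L, round(active_parcel_fraction * parc$n_parcels))
    gain[sample.int(parc$n_parcels, n_active)] <- active_gain
    sweep(w, 2L, gain, "*")
  })

  subjects <- vector("list", n_subjects)
  subject_truths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("sub-%03d", i)
    made <- make_subject(space, truth, subject_variability, ts_noise_sd,
                         n_runs, n_timepoints,
                         seed = derive_seed(seed, 100L + i), id = id)
    tm <- make_task_maps(made$truth, parc, weights, link_type, task_noise_sd,
                         standardize = standardize_tasks,
                         seed = derive_seed(seed, 10000L + i))
    made$subject$task_maps[[tm$contrast]] <- tm
    subjects[[i]] <- made$subject
    subject_truths[[i]] <- made$truth
  }
  names(subjects) <- names(subject_truths) <- vapply(subjects, `[[`, "", "id")

  truth$parcellation <- parc
  truth$link_weights <- weights
  truth$link_type <- link_type
  truth$subject_truths <- subject_truths

  cohort <- structure(list(space = space, truth = truth, subjects = subjects,
                           manifest = manifest), class = "cohort")
  if (!is.null(dir)) save_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, %d grayordinates, %d networks/hemisphere, %s task link\n",
              length(x$subjects), x$space$n_vertices,
              x$truth$k_per_hemisphere, x$truth$link_type))
  invisible(x)
}

#' Save / load a cohort
#'
#' One RDS container per subject plus a truth container and a JSON manifest
#' of all generator parameters and the master seed.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `save_cohort` returns `dir` invisibly; `load_cohort` returns the
#'   reassembled `cohort`.
#' @export
save_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("could not create cohort directory: ", dir, call. = FALSE)
  for (id in names(cohort$subjects))
    saveRDS(cohort$subjects[[id]], file.path(dir, paste0(id, ".rds")))
  saveRDS(cohort$space, file.path(dir, "space.rds"))
  saveRDS(cohort$truth, file.path(dir, "truth.rds"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  space <- readRDS(file.path(dir, "space.rds"))
  truth <- readRDS(file.path(dir, "truth.rds"))
  ids <- sprintf("sub-%03d", seq_len(manifest$n_subjects))
  subjects <- lapply(ids, function(id) readRDS(file.path(dir, paste0(id, ".rds"))))
  names(subjects) <- ids
  structure(list(space = space, truth = truth, subjects = subjects,
                 manifest = manifest), class = "cohort")
}

#' Regenerate a cohort from its manifest
#'
#' @param manifest a manifest list as stored by [make_cohort()].
#' @return A `cohort` identical (bitwise on all arrays) to the original.
#' @export
replay_cohort <- function(manifest) {
  do.call(make_cohort, manifest)
}
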