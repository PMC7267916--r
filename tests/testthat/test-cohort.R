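test_that("group maps are mirrored, smooth, and approximately non-overlapping", {
  sp <- tiny_space()
  tr <- make_group_networks(sp, 4, smoothness = 4, seed = 2)
  n <- sp$n_per_hemisphere
  expect_equal(ncol(tr$group_maps), 8L)
  # each right map equals the mirrored left map
  for (j in 1:4)
    expect_equal(tr$group_maps[n + 1:n, 4 + j], tr$group_maps[1:n, j])
  # smoothness: adjacent-vertex correlation beats a shuffled map's
  adj_pairs <- do.call(rbind, lapply(1:n, function(i)
    cbind(i, sp$adjacency[[i]][sp$adjacency[[i]] <= n])))
  for (j in 1:4) {
    map <- tr$group_maps[1:n, j]
    obs <- cor(map[adj_pairs[, 1]], map[adj_pairs[, 2]])
    shuf <- taskpred:::local_seed(5, sample(map))
    expect_gt(obs, cor(shuf[adj_pairs[, 1]], shuf[adj_pairs[, 2]]) + 0.3)
  }
  # mean pairwise overlap below 0.3
  cm <- cor(tr$group_maps[1:n, 1:4])
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.3)
})

test_that("zero smoothness gives noise-like (spatially uncorrelated) maps", {
  sp <- tiny_space()
  tr <- make_group_networks(sp, 3, smoothness = 0, seed = 3)
  n <- sp$n_per_hemisphere
  adj_pairs <- do.call(rbind, lapply(1:n, function(i)
    cbind(i, sp$adjacency[[i]][sp$adjacency[[i]] <= n])))
  ac <- sapply(1:3, function(j) {
    map <- tr$group_maps[1:n, j]
    cor(map[adj_pairs[, 1]], map[adj_pairs[, 2]])
  })
  expect_lt(mean(abs(ac)), 0.35)  # indicator maps: near-zero adjacency corr
})

test_that("noiseless runs lie exactly in the span of the group design", {
  sp <- tiny_space()
  tr <- make_group_networks(sp, 3, smoothness = 4, seed = 2)
  ms <- make_subject(sp, tr, subject_variability = 0, ts_noise_sd = 0,
                     n_runs = 2, n_timepoints = 40, seed = 4)
  D <- ms$truth$design_raw
  for (run in ms$subject$runs) {
    resid <- run - D %*% (taskpred:::pinv(D) %*% run)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("subject maps stay closest to their own group map under perturbation", {
  sp <- tiny_space()
  tr <- make_group_networks(sp, 3, smoothness = 4, seed = 2)
  ms <- make_subject(sp, tr, subject_variability = 0.5, ts_noise_sd = 0,
                     n_runs = 1, n_timepoints = 40, seed = 6)
  n <- sp$n_per_hemisphere
  cc <- abs(cor(ms$truth$subject_maps_raw[1:n, 1:3], tr$group_maps[1:n, 1:3]))
  for (j in 1:3) {
    expect_lt(cc[j, j], 1)
    expect_true(all(cc[j, j] > cc[j, -j]))
  }
})

test_that("subject generation is seed-deterministic", {
  sp <- tiny_space()
  tr <- make_group_networks(sp, 3, smoothness = 4, seed = 2)
  a <- make_subject(sp, tr, 0.3, 0.5, 2, 30, seed = 5)
  b <- make_subject(sp, tr, 0.3, 0.5, 2, 30, seed = 5)
  d <- make_subject(sp, tr, 0.3, 0.5, 2, 30, seed = 6)
  expect_identical(a$subject$runs, b$subject$runs)
  expect_false(isTRUE(all.equal(a$truth$subject_maps, d$truth$subject_maps)))
})

test_that("linear task maps are exactly recovered by a same-subject GLM", {
  co <- exact_cohort()
  parc <- co$truth$parcellation
  X <- subject_features(co$truth$subject_truths[[1]])
  y <- co$subjects[[1]]$task_maps[[1]]$z
  fl <- list(s1 = X); tl <- list(s1 = y)
  m <- fit_glm(fl, tl, parc)
  pred <- predict_parcel_model(m, X)
  expect_gt(cor(pred, y), 1 - 1e-6)
})

test_that("default task maps are z-scored and noise washes out the signal", {
  co <- tiny_cohort()
  z <- co$subjects[[1]]$task_maps[[1]]$z
  expect_lt(abs(mean(z)), 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)

  st <- co$truth$subject_truths[[1]]
  parc <- co$truth$parcellation
  w <- co$truth$link_weights
  clean <- make_task_maps(st, parc, w, "linear", task_noise_sd = 0, seed = 1)
  noisy <- make_task_maps(st, parc, w, "linear", task_noise_sd = 50, seed = 1)
  expect_lt(abs(cor(noisy$z, clean$z)), 0.2)
})

test_that("task-map argument errors are raised", {
  co <- tiny_cohort()
  st <- co$truth$subject_truths[[1]]
  parc <- co$truth$parcellation
  w <- co$truth$link_weights
  expect_error(make_task_maps(st, parc, w[, 1:3], "linear"), "every parcel")
  expect_error(make_task_maps(st, parc, w, "linear", task_noise_sd = -1),
               "non-negative")
})

test_that("cohorts have the advertised contents and replay bitwise", {
  co <- make_cohort(n_subjects = 3, n_vertices_per_hemisphere = 60,
                    n_subcortical_structures = 2, k_per_hemisphere = 2,
                    n_parcels_per_hemisphere = 3, n_runs = 2,
                    n_timepoints = 30, seed = 13)
  expect_length(co$subjects, 3L)
  expect_length(co$truth$subject_truths, 3L)
  replayed <- replay_cohort(co$manifest)
  expect_identical(serialize(co$subjects, NULL), serialize(replayed$subjects, NULL))
  expect_identical(serialize(co$truth, NULL), serialize(replayed$truth, NULL))
  expect_error(make_cohort(n_subjects = 2, seed = 1), ">= 3")
})

test_that("cohorts round-trip through disk with a manifest", {
  dir <- withr::local_tempdir()
  co <- make_cohort(n_subjects = 3, n_vertices_per_hemisphere = 60,
                    n_subcortical_structures = 2, k_per_hemisphere = 2,
                    n_parcels_per_hemisphere = 3, n_runs = 1,
                    n_timepoints = 30, seed = 13, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^sub-.*rds$"), 3L)
  back <- load_cohort(dir)
  expect_identical(serialize(back$subjects, NULL), serialize(co$subjects, NULL))
})
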