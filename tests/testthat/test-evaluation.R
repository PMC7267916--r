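test_that("prediction matrix has unit diagonal for perfect predictions", {
  set.seed(1)
  maps <- lapply(1:4, function(i) rnorm(50))
  names(maps) <- paste0("s", 1:4)
  m <- prediction_matrix(maps, maps)
  expect_equal(unname(diag(m)), rep(1, 4), tolerance = 1e-12)
})

test_that("permuted predictions move the unit correlations off the diagonal", {
  set.seed(2)
  maps <- lapply(1:5, function(i) rnorm(60))
  names(maps) <- paste0("s", 1:5)
  perm <- c(2, 3, 4, 5, 1)
  m <- prediction_matrix(maps[perm], maps)
  expect_equal(sum(abs(m - 1) < 1e-12), 5L)
  expect_true(all(abs(diag(m) - 1) > 1e-6))
})

test_that("zero-variance maps are rejected with the subject id", {
  maps <- list(s1 = rnorm(30), s2 = rep(1, 30))
  expect_error(prediction_matrix(maps, maps), "s2")
})

test_that("matrix normalization is column-standard, order-stable, near-idempotent", {
  set.seed(3)
  m <- matrix(rnorm(49), 7, 7) + diag(7)
  nm <- normalize_matrix(m)
  expect_lt(max(abs(colMeans(nm))), 1e-8)
  expect_equal(apply(nm, 2, sd), rep(1, 7), tolerance = 1e-8)
  # identity-structured input keeps a strictly maximal diagonal per row
  idm <- normalize_matrix(diag(7) + matrix(rnorm(49, sd = 1e-3), 7, 7))
  expect_true(all(apply(idm, 1, which.max) == 1:7))
  twice <- normalize_matrix(nm)
  expect_equal(unclass(twice), unclass(nm), tolerance = 1e-3, ignore_attr = TRUE)
  expect_error(normalize_matrix(matrix(0, 3, 3)), "zero-variance")
})

test_that("prediction accuracy is the diagonal mean, blind to off-diagonals", {
  m <- diag(c(0.5, 0.7))
  expect_equal(prediction_accuracy(m), 0.6)
  m2 <- m; m2[1, 2] <- 0.99
  expect_equal(prediction_accuracy(m2), 0.6)
  expect_equal(prediction_accuracy(diag(4)), 1)
})

test_that("dice equals brute-force set computation on random masks", {
  brute <- function(a, b) {
    A <- which(a); B <- which(b)
    if (length(A) + length(B) == 0) return(0)
    2 * length(intersect(A, B)) / (length(A) + length(B))
  }
  set.seed(4)
  for (i in 1:200) {
    a <- runif(40) < runif(1)
    b <- runif(40) < runif(1)
    expect_identical(dice(a, b), dice(b, a))
    expect_equal(dice(a, b), brute(a, b))
  }
  expect_equal(dice(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  expect_equal(dice(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
})

test_that("dice handles the documented worked example and empty masks", {
  a <- c(rep(TRUE, 4), rep(FALSE, 6))
  b <- c(FALSE, rep(TRUE, 6), rep(FALSE, 3))
  # |A|=4, |B|=6, overlap 3 -> 2*3/10
  expect_equal(dice(a, b), 0.6)
  both_empty <- dice(logical(5), logical(5))
  expect_equal(as.numeric(both_empty), 0)
  expect_true(attr(both_empty, "both_empty"))
  expect_error(dice(logical(3), logical(4)), "lengths differ")
})

test_that("repeated-measures ANOVA matches the textbook computation", {
  scores <- structure(c(0.4, 0.78, 0.53, 0.5, 0.66, 0.66, 0.37, 0.48, 0.65,
                        0.68, 0.61, 0.6, 0.62, 0.63, 0.82), dim = c(5L, 3L))
  res <- compare_models(scores)
  # frozen value from the standard partitioned sums of squares
  expect_equal(res$F, 0.706340703223921, tolerance = 1e-10)
  # independent oracle: aov with a subject error stratum
  df <- data.frame(score = as.vector(scores),
                   subj = factor(rep(1:5, 3)),
                   model = factor(rep(1:3, each = 5)))
  a <- summary(aov(score ~ model + Error(subj), data = df))
  F_aov <- a[["Error: Within"]][[1]]["model", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
  expect_equal(res$n_pairwise_tests, 3L)
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p))
  expect_true(all(res$pairwise$p_bonferroni <= pmin(1, res$pairwise$p * 3) + 1e-15))
})

test_that("ANOVA limits: identical scores and constant shifts", {
  scores <- matrix(rep(c(0.2, 0.4, 0.6, 0.3), 3), 4, 3)
  res <- compare_models(scores)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  shifted <- cbind(scores[, 1], scores[, 1] + 0.1, scores[, 1] + 0.2)
  res2 <- compare_models(shifted)
  expect_equal(res2$p, 0)
  expect_equal(res2$pairwise$p_bonferroni[1], 0)
  expect_error(compare_models(scores[1:2, ]), "3 subjects")
  expect_error(compare_models(scores[, 1, drop = FALSE]), "2 models")
})

test_that("rmANOVA p agrees with a permutation test on a small table", {
  set.seed(6)
  scores <- matrix(rnorm(18, mean = 0.5, sd = 0.1), 6, 3)
  scores[, 3] <- scores[, 3] + 0.08
  res <- compare_models(scores)
  # permutation of model labels within subjects
  n_perm <- 600
  perm_F <- replicate(n_perm, {
    sh <- t(apply(scores, 1, sample))
    compare_models(sh)$F
  })
  p_perm <- (1 + sum(perm_F >= res$F)) / (n_perm + 1)
  expect_lt(abs(p_perm - res$p), 0.05)
})

test_that("diagonal dominance permutation test separates planted structure", {
  set.seed(7)
  base <- matrix(rnorm(100, sd = 0.05), 10, 10)
  dd <- diagonal_dominance(base + diag(0.5, 10), n_perm = 499, seed = 1)
  expect_lt(dd$p, 0.01)
  flat <- diagonal_dominance(base, n_perm = 499, seed = 1)
  expect_gt(flat$p, 0.05)
})

test_that("learning curves have grid length and GLM averaging is flat", {
  co <- exact_cohort()
  fl <- cohort_features(co); tl <- cohort_tasks(co)
  parc <- co$truth$parcellation
  ids <- names(fl)
  curve <- learning_curve(fl, tl, parc, "glm", train_ids = ids[1:8],
                          test_ids = ids[9:12], n_train_grid = c(3L, 8L),
                          M_grid = c(1L, 3L), seed = 1)
  expect_equal(nrow(curve), 4L)
  # deterministic GLM: identical accuracy across M at fixed n_train
  for (n in c(3L, 8L)) {
    v <- curve$mean_cc[curve$n_train == n]
    expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  }
  expect_error(learning_curve(fl, tl, parc, "glm", train_ids = ids[1:4],
                              test_ids = ids[9:12], n_train_grid = 10L),
               "exceeds")
})
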