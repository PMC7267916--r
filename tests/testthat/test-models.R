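test_that("GLM recovers the generating weights on full-rank linear data", {
  set.seed(1)
  V <- 60; Fd <- 5
  space_labels <- rep(1:3, each = 20)
  parc <- structure(list(labels = space_labels, n_parcels = 3L,
                         n_cortical_parcels = 3L, n_per_hemisphere = 3L),
                    class = "parcellation")
  w <- matrix(rnorm(Fd * 3), Fd, 3)
  X1 <- matrix(rnorm(V * Fd), V, Fd); X2 <- matrix(rnorm(V * Fd), V, Fd)
  mk_y <- function(X) {
    y <- numeric(V)
    for (p in 1:3) y[space_labels == p] <-
        X[space_labels == p, ] %*% w[, p]
    y
  }
  m <- fit_glm(list(a = X1, b = X2), list(a = mk_y(X1), b = mk_y(X2)), parc)
  expect_equal(m$beta, w, tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated training subject leaves beta unchanged
  m2 <- fit_glm(list(a = X1, b = X1), list(a = mk_y(X1), b = mk_y(X1)), parc)
  m1 <- fit_glm(list(a = X1), list(a = mk_y(X1)), parc)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-8)
})

test_that("rank-deficient GLM uses the minimum-norm solution", {
  set.seed(2)
  V <- 20; Fd <- 6
  parc <- structure(list(labels = rep(1L, V), n_parcels = 1L), class = "parcellation")
  X <- matrix(rnorm(V * 3), V, 3)
  X <- cbind(X, X)                      # rank 3 of 6
  y <- rnorm(V)
  m <- fit_glm(list(a = X), list(a = y), parc)
  beta <- m$beta[, 1]
  # same residual as lm's least squares
  expect_equal(sum((y - X %*% beta)^2),
               sum(resid(lm(y ~ 0 + X))^2), tolerance = 1e-8)
  # minimum norm among solutions: adding any null-space vector grows it
  ns <- c(1, 0, 0, -1, 0, 0)            # X %*% ns = 0
  expect_lt(sum(beta^2), sum((beta + 0.1 * ns)^2))
})

test_that("GLM prediction is linear and assembles parcels", {
  co <- exact_cohort()
  fl <- cohort_features(co); tl <- cohort_tasks(co)
  parc <- co$truth$parcellation
  ids <- names(fl)
  m <- fit_glm(fl[ids[1:8]], tl[ids[1:8]], parc)
  X <- fl[[ids[9]]]
  expect_equal(predict_parcel_model(m, 2 * X),
               2 * predict_parcel_model(m, X), tolerance = 1e-10)
  expect_equal(predict_parcel_model(m, X * 0), numeric(nrow(X)))
  expect_error(predict_parcel_model(m, X[, 1:3]), "dimension mismatch")
})

test_that("NN learns a linear parcel and early stopping holds", {
  set.seed(3)
  n <- 400; Fd <- 6
  X <- matrix(rnorm(n * Fd), n, Fd)
  y <- drop(X %*% rnorm(Fd))
  fit <- taskpred:::mlp_fit(X, y, hidden = 1, learning_rate = 0.01,
                            max_epochs = 500, seed = 7)
  held <- fit$test_mse / var(y)
  expect_lt(held, 0.1)                   # CC > 0.95 <=> R2 > 0.9
  expect_lte(fit$val_trace[fit$best_epoch], fit$val_trace[length(fit$val_trace)])
  expect_lte(fit$stopped_epoch, 500)
  # determinism under seed
  fit2 <- taskpred:::mlp_fit(X, y, hidden = 1, learning_rate = 0.01,
                             max_epochs = 500, seed = 7)
  expect_identical(fit$net, fit2$net)
})

test_that("NN beats the GLM on a nonlinear parcel", {
  set.seed(4)
  n <- 600; Fd <- 5
  X <- matrix(rnorm(n * Fd), n, Fd)
  w <- rnorm(Fd)
  y <- drop(tanh(1.5 * X) %*% w) + rnorm(n, sd = 0.05)
  tr <- 1:400; te <- 401:600
  nn <- taskpred:::mlp_fit(X[tr, ], y[tr], hidden = 8, learning_rate = 0.01,
                           max_epochs = 400, seed = 5)
  nn_mse <- mean((taskpred:::mlp_predict(nn$net, X[te, ]) - y[te])^2)
  beta <- drop(taskpred:::pinv(X[tr, ]) %*% y[tr])
  glm_mse <- mean((drop(X[te, ] %*% beta) - y[te])^2)
  expect_lt(nn_mse, glm_mse)
})

test_that("a single unpruned tree without bootstrap overfits exactly", {
  co <- exact_cohort()
  fl <- cohort_features(co); tl <- cohort_tasks(co)
  parc <- co$truth$parcellation
  id <- names(fl)[1]
  m <- fit_rfbag(fl[id], tl[id], parc, n_trees = 1,
                 n_predictors_per_split = ncol(fl[[id]]),
                 min_leaf = 1, seed = 1, bootstrap = FALSE)
  pred <- predict_parcel_model(m, fl[[id]])
  expect_equal(pred, tl[[id]]$z, tolerance = 1e-8)
})

test_that("forests predict a constant when the target is constant", {
  set.seed(5)
  parc <- structure(list(labels = rep(1L, 30), n_parcels = 1L), class = "parcellation")
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(2.5, 30)
  m <- fit_rfbag(list(a = X), list(a = y), parc, n_trees = 20,
                 n_predictors_per_split = 2, min_leaf = 3, seed = 1)
  expect_equal(predict_parcel_model(m, X), y, tolerance = 1e-10)
})

test_that("held-out forest error does not grow with more trees", {
  set.seed(6)
  n <- 300; Fd <- 6
  X <- matrix(rnorm(n * Fd), n, Fd)
  y <- drop(tanh(X) %*% rnorm(Fd)) + rnorm(n, sd = 0.3)
  parc <- structure(list(labels = rep(1L, 200), n_parcels = 1L), class = "parcellation")
  mse_at <- function(nt, seed) {
    m <- fit_rfbag(list(a = X[1:200, ]), list(a = y[1:200]), parc,
                   n_trees = nt, n_predictors_per_split = 2, min_leaf = 5,
                   seed = seed)
    pr <- taskpred:::predict_one_parcel(m, 1, X[201:300, ])
    mean((pr - y[201:300])^2)
  }
  few <- mean(sapply(1:5, function(s) mse_at(1, s)))
  many <- mean(sapply(1:5, function(s) mse_at(100, s)))
  expect_lt(many, few)
})

test_that("rfbag argument validation", {
  co <- exact_cohort()
  fl <- cohort_features(co); tl <- cohort_tasks(co)
  parc <- co$truth$parcellation
  expect_error(fit_rfbag(fl[1], tl[1], parc, n_predictors_per_split = 99),
               "1..F")
  expect_error(fit_rfbag(fl[1], tl[1], parc, min_leaf = 1e6), "min_leaf")
})

test_that("ensembles average members; M=1 and GLM reduce to single models", {
  co <- nonlinear_cohort()
  fl <- cohort_features(co); tl <- cohort_tasks(co)
  parc <- co$truth$parcellation
  ids <- names(fl)
  # M=1 ensemble == its single member
  e1 <- train_ensemble("rfbag", fl[ids[1:6]], tl[ids[1:6]], parc,
                       hyperparams = list(n_trees = 10), M = 1, seed = 2)
  expect_equal(predict_ensemble(e1, fl[[ids[7]]]),
               predict_parcel_model(e1$members[[1]], fl[[ids[7]]]))
  # GLM members are identical, average == member
  eg <- train_ensemble("glm", fl[ids[1:6]], tl[ids[1:6]], parc, M = 3, seed = 2)
  expect_identical(eg$members[[1]]$beta, eg$members[[3]]$beta)
  expect_equal(predict_ensemble(eg, fl[[ids[7]]]),
               predict_parcel_model(eg$members[[1]], fl[[ids[7]]]))
})

test_that("opposite member predictions cancel in the average", {
  flip <- structure(list(kind = "glm",
                         beta = matrix(1, 2, 1),
                         parcellation = structure(list(labels = rep(1L, 4),
                                                       n_parcels = 1L),
                                                  class = "parcellation"),
                         n_features = 2, meta = list()), class = "parcel_model")
  flop <- flip; flop$beta <- -flip$beta
  ens <- structure(list(kind = "glm", members = list(flip, flop), M = 2L),
                   class = "parcel_ensemble")
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(predict_ensemble(ens, X), rep(0, 4), tolerance = 1e-12)
})
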