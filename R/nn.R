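# Feed-forward neural network: tanh hidden layer(s), linear output, trained
# full-batch by resilient backpropagation (Rprop: per-weight step sizes
# adapted from the sign of the gradient only), with a random 60/20/20
# train/validation/test row split and early stopping at the validation-MSE
# minimum (patience 6, hard cap 1000 epochs).

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  local_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l) {
      r <- 1 / sqrt(sizes[l])        # seeded uniform fan-in scaling
      matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r), sizes[l], sizes[l + 1L])
    })
    b <- lapply(sizes[-1L], function(m) numeric(m))
  })
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) tanh(z) else z
  }
  acts
}

mlp_predict <- function(net, X) drop(mlp_forward(net, as.matrix(X))[[length(net$W) + 1L]])

mlp_gradients <- function(net, X, y) {
  n <- nrow(X)
  acts <- mlp_forward(net, X)
  L <- length(net$W)
  delta <- (acts[[L + 1L]] - y) * (2 / n)   # d MSE / d output
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (1 - acts[[l]]^2)
  }
  list(W = gW, b = gb)
}

# Classic Rprop update (eta+ = 1.2, eta- = 0.5, step in [1e-6, 50]).
rprop_state <- function(net, delta0) {
  list(stepW = lapply(net$W, function(w) array(delta0, dim(w))),
       stepb = lapply(net$b, function(b) rep(delta0, length(b))),
       prevW = lapply(net$W, function(w) array(0, dim(w))),
       prevb = lapply(net$b, function(b) numeric(length(b))))
}

rprop_apply <- function(theta, grad, step, prev) {
  s <- sign(grad) * sign(prev)
  step <- ifelse(s > 0, pmin(step * 1.2, 50), ifelse(s < 0, pmax(step * 0.5, 1e-6), step))
  grad_eff <- ifelse(s < 0, 0, grad)      # iRprop-: no step after sign change
  theta <- theta - sign(grad_eff) * step
  list(theta = theta, step = step, prev = grad_eff)
}

mlp_fit <- function(X, y, hidden = 10L, learning_rate = 0.001,
                    max_epochs = 1000L, patience = 6L, seed = 1L,
                    val_frac = 0.2, test_frac = 0.2) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 5L) stop("too few rows to split for NN training", call. = FALSE)

  split <- local_seed(derive_seed(seed, 1L), {
    perm <- sample.int(n)
    n_te <- floor(n * test_frac); n_va <- floor(n * val_frac)
    list(test = perm[seq_len(n_te)],
         val = perm[n_te + seq_len(n_va)],
         train = perm[-seq_len(n_te + n_va)])
  })
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE];   yva <- y[split$val]
  Xte <- X[split$test, , drop = FALSE];  yte <- y[split$test]

  net <- mlp_init(ncol(X), hidden, derive_seed(seed, 2L))
  rp <- rprop_state(net, delta0 = learning_rate)
  mse <- function(p, t) mean((p - t)^2)

  best <- list(net = net, val = Inf, epoch = 0L)
  val_trace <- numeric(0)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    g <- mlp_gradients(net, Xtr, ytr)
    if (!all(vapply(g$W, function(m) all(is.finite(m)), TRUE)))
      stop("non-finite gradient during NN training", call. = FALSE)
    for (l in seq_along(net$W)) {
      up <- rprop_apply(net$W[[l]], g$W[[l]], rp$stepW[[l]], rp$prevW[[l]])
      net$W[[l]] <- up$theta; rp$stepW[[l]] <- up$step; rp$prevW[[l]] <- up$prev
      ub <- rprop_apply(net$b[[l]], g$b[[l]], rp$stepb[[l]], rp$prevb[[l]])
      net$b[[l]] <- ub$theta; rp$stepb[[l]] <- ub$step; rp$prevb[[l]] <- ub$prev
    }
    v <- if (length(yva)) mse(mlp_predict(net, Xva), yva) else mse(mlp_predict(net, Xtr), ytr)
    val_trace <- c(val_trace, v)
    if (v < best$val - 1e-12) {
      best <- list(net = net, val = v, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  net <- best$net
  list(net = net,
       val_mse = best$val,
       val_trace = val_trace,
       stopped_epoch = length(val_trace),
       best_epoch = best$epoch,
       test_mse = if (length(yte)) mse(mlp_predict(net, Xte), yte) else NA_real_,
       train_mse = mse(mlp_predict(net, Xtr), ytr),
       hidden = hidden, learning_rate = learning_rate, seed = seed)
}

#' Fit per-parcel feed-forward neural networks
#'
#' One network per parcel (input F -> tanh hidden layer(s) -> linear
#' output), trained by resilient backpropagation on 60% of the parcel's
#' stacked rows with early stopping at the minimum validation MSE
#' (patience 6) and a hard cap of 1000 epochs. The held-out 20% test subset
#' MSE is recorded per parcel.
#'
#' @inheritParams fit_glm
#' @param hyperparams list with `hidden_size`, `n_layers`, `learning_rate`
#'   (the Rprop initial step size); defaults 10 / 1 / 0.001.
#' @param seed RNG seed (splits and initialization derive from it).
#' @param max_epochs,patience training controls.
#' @return A `parcel_model` of kind `"nn"`.
#' @export
fit_nn <- function(features_list, target_list, parcellation,
                   hyperparams = list(), seed = 1L,
                   max_epochs = 1000L, patience = 6L) {
  check_model_inputs(features_list, target_list, parcellation)
  hp <- utils::modifyList(list(hidden_size = 10L, n_layers = 1L,
                               learning_rate = 0.001), hyperparams)
  hidden <- rep(hp$hidden_size, hp$n_layers)
  P <- parcellation$n_parcels
  nets <- vector("list", P)
  test_mse <- numeric(P)
  for (p in seq_len(P)) {
    idx <- which(parcellation$labels == p)
    if (!length(idx)) stop("parcel ", p, " is empty", call. = FALSE)
    d <- stack_parcel(features_list, target_list, idx)
    fit <- mlp_fit(d$X, d$y, hidden = hidden, learning_rate = hp$learning_rate,
                   max_epochs = max_epochs, patience = patience,
                   seed = derive_seed(seed, p))
    nets[[p]] <- fit$net
    test_mse[p] <- fit$test_mse
  }
  structure(list(kind = "nn", nets = nets, parcellation = parcellation,
                 n_features = ncol(features_list[[1L]]),
                 hyperparams = hp,
                 meta = list(n_train = length(features_list), seed = seed,
                             test_mse = test_mse)),
            class = "parcel_model")
}
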