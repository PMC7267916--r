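# Gaussian + two-gamma mixture model for z-score histograms: a central
# Gaussian null plus a positive (upper) and a mirrored negative (lower)
# shifted-gamma activation component, fit by EM. The activation threshold
# is the median of the upper gamma.

dgamma_pos <- function(x, shape, scale, loc) {
  out <- numeric(length(x))
  ok <- x > loc
  out[ok] <- stats::dgamma(x[ok] - loc, shape = shape, scale = scale)
  out
}

dgamma_neg <- function(x, shape, scale, loc) {
  out <- numeric(length(x))
  ok <- x < loc
  out[ok] <- stats::dgamma(loc - x[ok], shape = shape, scale = scale)
  out
}

# Weighted gamma MLE for t > 0 with weights w (Minka's Newton iteration on
# the shape). Returns NULL when the weighted support is degenerate.
gamma_wmle <- function(t, w) {
  keep <- w > 1e-12 & t > 1e-12
  if (sum(keep) < 2L || sum(w[keep]) < 1e-8) return(NULL)
  t <- t[keep]; w <- w[keep]
  sw <- sum(w)
  mbar <- sum(w * t) / sw
  lbar <- sum(w * log(t)) / sw
  s <- log(mbar) - lbar
  if (s <= 0) return(list(shape = 100, scale = mbar / 100))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    k_new <- k - (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    if (!is.finite(k_new) || k_new <= 0) break
    if (abs(k_new - k) < 1e-10) { k <- k_new; break }
    k <- k_new
  }
  list(shape = k, scale = mbar / k)
}

mix_density <- function(x, fit) {
  d <- fit$weights[1L] * stats::dnorm(x, fit$mu, fit$sigma)
  if (fit$weights[2L] > 0)
    d <- d + fit$weights[2L] * dgamma_pos(x, fit$shape_pos, fit$scale_pos, fit$loc_pos)
  if (fit$weights[3L] > 0)
    d <- d + fit$weights[3L] * dgamma_neg(x, fit$shape_neg, fit$scale_neg, fit$loc_neg)
  d
}

#' Fit a Gaussian + two-gamma mixture to z values
#'
#' EM fit of `w_G * Normal(mu, sigma) + w_pos * Gamma(shape, scale)` shifted
#' to `x > loc_pos` `+ w_neg *` mirrored `Gamma` on `x < loc_neg`, computed
#' on the value histogram (binned EM). Gamma locations are initialized at
#' the Gaussian centre (data median) and updated during EM by joint
#' weighted maximum likelihood over (location, shape, scale). Two
#' identifiability constraints keep the activation components away from
#' the Gaussian limit, where the mixture would be degenerate: each gamma
#' must start at or beyond the null mean, and its mode must lie at least
#' two null SDs away from the null mean. Iterates until the log-likelihood
#' gain drops below `tol` or `max_iter` is reached; the log-likelihood
#' trace is non-decreasing by construction. If a gamma weight collapses
#' (< 1e-3), the model is refit without that component and flagged
#' degenerate.
#'
#' @param z numeric vector of z values (>= 1000 recommended; fewer warns).
#' @param max_iter,tol EM controls.
#' @return A `mixture_fit`: `weights` (Gaussian, positive, negative),
#'   `mu`, `sigma`, `shape_pos`, `scale_pos`, `loc_pos`, the negative
#'   counterparts, `threshold` (median of the upper gamma), `loglik`
#'   trace, and flags.
#' @export
fit_mixture <- function(z, max_iter = 500L, tol = 1e-6) {
  z <- z[is.finite(z)]
  if (length(z) < 10L) stop("too few finite values for a mixture fit", call. = FALSE)
  if (length(z) < 1000L)
    warning("fewer than 1000 values; mixture fit may be unstable")

  # deterministic multistart: EM is sensitive to where the null width and
  # the activation onset start, so sweep a small grid of inits and keep
  # the highest-likelihood solution
  starts <- expand.grid(sigma_factor = c(0.75, 1), loc_offset = c(0, 1, 2))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- em_gg(z, use_pos = TRUE, use_neg = TRUE, max_iter = max_iter,
               tol = tol, sigma_factor = starts$sigma_factor[i],
               loc_offset = starts$loc_offset[i])
    if (is.null(fit) || f$loglik > fit$loglik) fit <- f
  }

  # BIC selection against the reduced models guards against spurious
  # activation components on null-like data (a weight -> 0 regime)
  n <- length(z)
  bic <- function(f, k) -2 * f$loglik + k * log(n)
  cands <- list(full = list(fit = fit, k = 10))
  cands$gpos <- list(fit = em_gg(z, TRUE, FALSE, max_iter, tol,
                                 sigma_factor = 0.75, loc_offset = 1), k = 6)
  cands$gneg <- list(fit = em_gg(z, FALSE, TRUE, max_iter, tol,
                                 sigma_factor = 0.75, loc_offset = 1), k = 6)
  cands$gonly <- list(fit = em_gg(z, FALSE, FALSE, max_iter, tol,
                                  sigma_factor = 1, loc_offset = 0), k = 2)
  cands$full$fit <- polish_full_fit(z, cands$full$fit)
  bics <- vapply(cands, function(cc) bic(cc$fit, cc$k), numeric(1L))
  chosen <- names(which.min(bics))
  fit <- cands[[chosen]]$fit
  fit$model <- chosen
  fit$bic <- bics
  fit$degenerate <- chosen != "full"

  fit$threshold <- if (fit$weights[2L] > 0)
    fit$loc_pos + stats::qgamma(0.5, shape = fit$shape_pos, scale = fit$scale_pos)
  else NA_real_
  class(fit) <- "mixture_fit"
  fit
}

# Joint maximum-likelihood refinement of the full three-component model:
# EM crawls slowly along the near-flat (location, shape, scale) ridge of
# the shifted gammas and can stop anywhere on it, so the EM solution is
# polished by direct likelihood maximization over all ten parameters
# (Nelder-Mead on the binned likelihood), keeping the EM constraints.
polish_full_fit <- function(z_raw, fit, n_bins = 1024L) {
  b <- bin_values(z_raw, n_bins)
  zb <- b$z; wb <- b$w
  sp <- max(stats::sd(zb), 1e-3)
  par0 <- c(fit$mu, log(fit$sigma),
            fit$loc_pos, log(fit$shape_pos), log(fit$scale_pos),
            fit$loc_neg, log(fit$shape_neg), log(fit$scale_neg),
            log(fit$weights[2L] / max(fit$weights[1L], 1e-6)),
            log(fit$weights[3L] / max(fit$weights[1L], 1e-6)))
  unpack <- function(p) {
    w_raw <- c(1, exp(p[9L]), exp(p[10L]))
    list(mu = p[1L], sigma = exp(p[2L]),
         loc_pos = p[3L], shape_pos = exp(p[4L]), scale_pos = exp(p[5L]),
         loc_neg = p[6L], shape_neg = exp(p[7L]), scale_neg = exp(p[8L]),
         weights = w_raw / sum(w_raw))
  }
  nll <- function(p) {
    f <- unpack(p)
    if (!all(is.finite(unlist(f)))) return(1e12)
    bad <- f$loc_pos < f$mu || f$loc_neg > f$mu ||
      f$shape_pos > 30 || f$shape_neg > 30 ||
      (f$shape_pos - 1) * f$scale_pos * (f$shape_pos > 1) +
        (f$loc_pos - f$mu) < 2 * f$sigma ||
      (f$shape_neg - 1) * f$scale_neg * (f$shape_neg > 1) +
        (f$mu - f$loc_neg) < 2 * f$sigma
    if (bad) return(1e12)
    -sum(wb * log(pmax(mix_density(zb, f), 1e-300)))
  }
  if (nll(par0) >= 1e12) return(fit)
  opt <- try(stats::optim(par0, nll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$value >= nll(par0)) return(fit)
  out <- unpack(opt$par)
  fit[names(out)] <- out
  fit$loglik <- -opt$value
  fit$loglik_trace <- c(fit$loglik_trace, fit$loglik)
  fit
}

# Shared binning of raw values for likelihood work on large samples.
bin_values <- function(z, n_bins = 1024L) {
  if (length(z) <= n_bins * 4L) return(list(z = z, w = rep(1, length(z))))
  br <- seq(min(z), max(z), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(z, br, rightmost.closed = TRUE), n_bins)
  ctr <- (br[-1L] + br[-length(br)]) / 2
  keep <- cnt > 0L
  list(z = ctr[keep], w = cnt[keep])
}

# EM on a binned histogram of z (bin centres weighted by counts): the
# model is a fit to the z histogram, and binning makes each iteration cost
# independent of n.
em_gg <- function(z, use_pos = TRUE, use_neg = TRUE, max_iter = 500L, tol = 1e-6,
                  n_bins = 1024L, sigma_factor = 1, loc_offset = 1) {
  n_raw <- length(z)
  b <- bin_values(z, n_bins)
  z <- b$z; w_obs <- b$w
  n <- sum(w_obs)
  # robust null-centre init from weighted quantiles
  wq <- function(p) {
    cw <- cumsum(w_obs) / n
    z[which.max(cw >= p)]
  }
  mu <- wq(0.5)
  sigma <- max(sigma_factor * (wq(0.75) - wq(0.25)) / 1.349, 1e-3)
  loc0 <- mu + loc_offset * sigma
  fit <- list(mu = mu, sigma = sigma,
              loc_pos = min(loc0, max(z) - 1e-6),
              loc_neg = max(mu - loc_offset * sigma, min(z) + 1e-6),
              shape_pos = 2, scale_pos = sigma, shape_neg = 2, scale_neg = sigma,
              weights = c(1 - 0.1 * use_pos - 0.1 * use_neg,
                          0.1 * use_pos, 0.1 * use_neg))
  # moment-based warm start from the tails beyond the starting locations
  if (use_pos && sum(z > fit$loc_pos + 0.5 * sigma) > 2) {
    t <- z[z > fit$loc_pos + 0.5 * sigma] - fit$loc_pos
    fit$shape_pos <- max(1.1, mean(t)^2 / max(stats::var(t), 1e-6))
    fit$scale_pos <- mean(t) / fit$shape_pos
  }
  if (use_neg && sum(z < fit$loc_neg - 0.5 * sigma) > 2) {
    t <- fit$loc_neg - z[z < fit$loc_neg - 0.5 * sigma]
    fit$shape_neg <- max(1.1, mean(t)^2 / max(stats::var(t), 1e-6))
    fit$scale_neg <- mean(t) / fit$shape_neg
  }

  weighted_ll <- function(f) sum(w_obs * log(pmax(mix_density(z, f), 1e-300)))
  loglik <- weighted_ll(fit)
  trace <- loglik
  for (it in seq_len(max_iter)) {
    old <- fit
    # E step
    dG <- fit$weights[1L] * stats::dnorm(z, fit$mu, fit$sigma)
    dP <- if (use_pos) fit$weights[2L] * dgamma_pos(z, fit$shape_pos, fit$scale_pos, fit$loc_pos) else numeric(length(z))
    dN <- if (use_neg) fit$weights[3L] * dgamma_neg(z, fit$shape_neg, fit$scale_neg, fit$loc_neg) else numeric(length(z))
    tot <- pmax(dG + dP + dN, 1e-300)
    rG <- dG / tot; rP <- dP / tot; rN <- dN / tot

    # M step (generalized EM: each block update cannot decrease Q, and the
    # whole step is rejected if the observed likelihood drops)
    cand <- fit
    cand$weights <- c(sum(w_obs * rG), sum(w_obs * rP), sum(w_obs * rN)) / n
    swG <- sum(w_obs * rG)
    if (swG > 1e-8) {
      cand$mu <- sum(w_obs * rG * z) / swG
      cand$sigma <- max(sqrt(sum(w_obs * rG * (z - cand$mu)^2) / swG), 1e-4)
    }
    if (use_pos) {
      g <- gamma_mstep(z, w_obs * rP, positive = TRUE,
                       cur = list(shape = cand$shape_pos, scale = cand$scale_pos,
                                  loc = cand$loc_pos),
                       mu = cand$mu, sigma = cand$sigma)
      cand$shape_pos <- g$shape; cand$scale_pos <- g$scale; cand$loc_pos <- g$loc
    }
    if (use_neg) {
      g <- gamma_mstep(z, w_obs * rN, positive = FALSE,
                       cur = list(shape = cand$shape_neg, scale = cand$scale_neg,
                                  loc = cand$loc_neg),
                       mu = cand$mu, sigma = cand$sigma)
      cand$shape_neg <- g$shape; cand$scale_neg <- g$scale; cand$loc_neg <- g$loc
    }

    ll_new <- weighted_ll(cand)
    if (ll_new >= loglik - 1e-9) {
      fit <- cand
      gain <- ll_new - loglik
      loglik <- max(ll_new, loglik)
      trace <- c(trace, loglik)
      if (gain < tol && it > 5L) break
    } else {
      fit <- old
      trace <- c(trace, loglik)
      break
    }
  }
  fit$loglik <- loglik
  fit$loglik_trace <- trace
  fit$n <- n_raw
  fit
}

# Weighted maximum-likelihood update of one shifted gamma component
# (location, shape, scale jointly, Nelder-Mead over (loc, log shape,
# log scale)); falls back to the closed-form shape/scale update at the
# current location when the search does not improve. The activation
# component is constrained to start at or beyond the null (Gaussian) mean
# and the shape is capped, keeping the gamma away from its Gaussian limit
# where the mixture would become unidentifiable.
gamma_mstep <- function(z, w, positive, cur, mu = 0, sigma = 1, shape_cap = 30) {
  keep <- w > 1e-10
  if (sum(keep) < 3L || sum(w[keep]) < 1e-6) return(cur)
  zk <- z[keep]; wk <- w[keep]
  edge <- if (positive) min(zk) else max(zk)
  nll <- function(par) {
    loc <- par[1L]; shape <- exp(par[2L]); scale <- exp(par[3L])
    bad_loc <- if (positive) loc < mu else loc > mu
    # the activation density must peak well beyond the null mean (two null
    # SDs), else it degenerates into a fit of the Gaussian flank
    mode_off <- if (shape > 1) (shape - 1) * scale else 0
    bad_mode <- mode_off + abs(loc - mu) < 2 * sigma
    t <- if (positive) zk - loc else loc - zk
    if (bad_loc || bad_mode || any(t <= 0) || shape > shape_cap || scale > 1e4) return(1e12)
    -sum(wk * stats::dgamma(t, shape = shape, scale = scale, log = TRUE))
  }
  cand <- cur
  g <- gamma_wmle(if (positive) zk - cur$loc else cur$loc - zk, wk)
  if (!is.null(g)) { cand$shape <- g$shape; cand$scale <- g$scale }
  start <- c(cand$loc, log(cand$shape), log(cand$scale))
  if (nll(start) >= 1e12)
    start <- c(edge - if (positive) 1e-3 else -1e-3, log(cand$shape), log(cand$scale))
  opt <- try(stats::optim(start, nll, method = "Nelder-Mead",
                          control = list(maxit = 200)), silent = TRUE)
  if (!inherits(opt, "try-error") && opt$value < nll(start)) {
    cand$loc <- opt$par[1L]
    cand$shape <- exp(opt$par[2L])
    cand$scale <- exp(opt$par[3L])
  }
  if (nll(c(cand$loc, log(cand$shape), log(cand$scale))) <
      nll(c(cur$loc, log(cur$shape), log(cur$scale)))) cand else cur
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: weights (G/pos/neg) = %.3f/%.3f/%.3f, mu = %.3f, sigma = %.3f\n",
    x$weights[1L], x$weights[2L], x$weights[3L], x$mu, x$sigma))
  if (is.finite(x$threshold))
    cat(sprintf("  upper gamma: shape %.2f scale %.2f loc %.2f -> threshold %.3f\n",
                x$shape_pos, x$scale_pos, x$loc_pos, x$threshold))
  invisible(x)
}

#' Threshold a z map at the upper gamma's median
#'
#' The activation threshold is `loc_pos + qgamma(0.5, shape_pos, scale_pos)`
#' (the median of the positive mixture component); the mask marks vertices
#' with `z >= threshold`. Only positive activation is masked.
#'
#' @param map numeric z map.
#' @param fit a `mixture_fit` (or any list with the positive-gamma fields).
#' @return Logical mask; if the fit has no positive component, an all-FALSE
#'   mask flagged `"no_positive_component"`.
#' @export
threshold_map <- function(map, fit) {
  has_pos <- !is.null(fit$weights) && length(fit$weights) >= 2L && fit$weights[2L] > 0
  if (!has_pos || is.null(fit$shape_pos)) {
    out <- rep(FALSE, length(map))
    attr(out, "no_positive_component") <- TRUE
    return(out)
  }
  thr <- fit$loc_pos + stats::qgamma(0.5, shape = fit$shape_pos, scale = fit$scale_pos)
  map >= thr
}

#' Simulate from a Gaussian + two-gamma mixture
#'
#' Test-bed generator matching the model [fit_mixture()] estimates. The
#' defaults describe a well-identified activation histogram: a strongly
#' skewed positive gamma whose sharp support edge pins its location (a
#' high-shape gamma is close to a Gaussian, and its location, shape and
#' scale are then barely identifiable from data).
#'
#' @param n draws.
#' @param weights 3-simplex (Gaussian, positive, negative).
#' @param mu,sigma Gaussian parameters.
#' @param shape_pos,scale_pos,loc_pos upper (positive) gamma.
#' @param shape_neg,scale_neg,loc_neg lower (negative, mirrored) gamma.
#' @param seed RNG seed.
#' @return Numeric vector of draws.
#' @export
rmix_gg <- function(n, weights = c(0.75, 0.2, 0.05), mu = 0, sigma = 1,
                    shape_pos = 2, scale_pos = 1, loc_pos = 2,
                    shape_neg = 2, scale_neg = 0.8, loc_neg = -1.5,
                    seed = 1L) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  weights <- weights / sum(weights)
  local_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = weights)
    out <- numeric(n)
    out[comp == 1L] <- stats::rnorm(sum(comp == 1L), mu, sigma)
    out[comp == 2L] <- loc_pos + stats::rgamma(sum(comp == 2L), shape = shape_pos, scale = scale_pos)
    out[comp == 3L] <- loc_neg - stats::rgamma(sum(comp == 3L), shape = shape_neg, scale = scale_neg)
  })
  out
}
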