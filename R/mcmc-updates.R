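# Gibbs full conditionals.  Every block below is conjugate: given the rest
# of the state the block is multivariate normal (gamma, W, c, the temporal
# series on its sum-to-zero subspace), inverse-gamma (sigma2), gamma
# (tau0, tau1) or discrete over the range grid (phi).  Each fc_* function
# returns the exact full-conditional parameters; the update_* wrappers draw
# from them.  log_joint evaluates the joint density the conditionals are
# derived from, which the test suite uses for density-ratio identities.

#' Precompute quantities reused across Gibbs iterations
#'
#' Fixed-effect design, pairwise site distances, and a Cholesky/inverse/
#' log-determinant of the tapered correlation at every candidate range, so
#' the discrete range update and the latent-process update reuse
#' factorisations instead of refactorising per iteration.
#'
#' @param data A \code{\link{downscale_data}}.
#' @param prior A \code{\link{downscale_priors}}.
#' @return List of cached quantities (internal structure).
#' @keywords internal
build_chain_cache <- function(data, prior) {
  x <- cbind(intercept = 1, aod = data$aod, data$Z)
  d <- pairwise_distances(data$coords)
  corr <- lapply(prior$phi_grid, function(phi) {
    r <- tapered_exponential(d, spatial_cov_params(phi, prior$taper_km,
                                                   prior$taper))
    diag(r) <- diag(r) + prior$jitter
    ch <- chol(r)
    list(phi = phi, chol = ch, inv = chol2inv(ch),
         logdet = 2 * sum(log(diag(ch))))
  })
  tt <- data$n_days
  q <- rw1_precision(tt)          # unit-precision RW1 structure
  k <- sum_zero_basis(tt)
  list(X = x, dist = d, corr = corr, Q = q, K = k,
       KQK = crossprod(k, q %*% k),
       n = length(data$y), p = ncol(x))
}

corr_for_phi <- function(cache, prior, phi) {
  i <- which.min(abs(prior$phi_grid - phi))
  if (abs(prior$phi_grid[i] - phi) > 1e-9) {
    stop("phi ", phi, " is not on the prior grid")
  }
  cache$corr[[i]]
}

# draw from N(P^{-1} b, P^{-1}) given precision P and linear term b
draw_gauss_precision <- function(prec, lin) {
  ch <- chol(prec)
  mean <- backsolve(ch, forwardsolve(t(ch), lin))
  drop(mean + backsolve(ch, stats::rnorm(length(lin))))
}

gauss_mean_precision <- function(prec, lin) {
  ch <- chol(prec)
  list(mean = drop(backsolve(ch, forwardsolve(t(ch), lin))), prec = prec,
       chol = ch)
}

# log N(x; fc$mean, fc$prec^{-1})
dmvnorm_prec <- function(x, fc) {
  ch <- if (is.null(fc$chol)) chol(fc$prec) else fc$chol
  r <- x - fc$mean
  sum(log(diag(ch))) - 0.5 * drop(crossprod(r, fc$prec %*% r)) -
    0.5 * length(x) * log(2 * pi)
}

# spatially+temporally varying random part of the mean
random_part <- function(state, data) {
  (state$c_coef[1] * state$W1[data$site] + state$beta0[data$day]) +
    (state$c_coef[2] * state$W1[data$site] +
     state$c_coef[3] * state$W2[data$site] +
     state$beta1[data$day]) * data$aod
}

fc_gamma <- function(state, data, prior, cache) {
  r <- data$y - random_part(state, data)
  prec <- crossprod(cache$X) / state$sigma2 +
    diag(1 / prior$gamma_sd^2, cache$p)
  gauss_mean_precision(prec, crossprod(cache$X, r) / state$sigma2)
}

fc_W <- function(state, data, prior, cache) {
  m <- data$n_sites
  r <- data$y - drop(cache$X %*% state$gamma) - state$beta0[data$day] -
    state$beta1[data$day] * data$aod
  a <- state$c_coef[1] + state$c_coef[2] * data$aod   # loading on W1(site)
  b <- state$c_coef[3] * data$aod                     # loading on W2(site)
  sum_by_site <- function(v) {
    out <- numeric(m)
    agg <- rowsum(v, data$site)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  aa <- sum_by_site(a * a) / state$sigma2
  bb <- sum_by_site(b * b) / state$sigma2
  ab <- sum_by_site(a * b) / state$sigma2
  lin <- c(sum_by_site(a * r), sum_by_site(b * r)) / state$sigma2
  prec <- matrix(0, 2 * m, 2 * m)
  prec[1:m, 1:m] <- corr_for_phi(cache, prior, state$phi1)$inv
  prec[m + 1:m, m + 1:m] <- corr_for_phi(cache, prior, state$phi2)$inv
  idx <- cbind(1:m, m + 1:m)
  prec[idx] <- prec[idx] + ab
  prec[idx[, 2:1]] <- prec[idx[, 2:1]] + ab
  di <- cbind(1:m, 1:m)
  prec[di] <- prec[di] + aa
  prec[di + m] <- prec[di + m] + bb
  gauss_mean_precision(prec, lin)
}

fc_c <- function(state, data, prior, cache) {
  r <- data$y - drop(cache$X %*% state$gamma) - state$beta0[data$day] -
    state$beta1[data$day] * data$aod
  d <- cbind(state$W1[data$site],
             state$W1[data$site] * data$aod,
             state$W2[data$site] * data$aod)
  prec <- crossprod(d) / state$sigma2 + diag(1 / prior$gamma_sd^2, 3)
  gauss_mean_precision(prec, crossprod(d, r) / state$sigma2)
}

# full conditional of one daily series on the sum-to-zero subspace.
# which = 0: intercept series (unit weight per record);
# which = 1: slope series (weight AOD per record).
fc_temporal <- function(state, data, prior, cache, which) {
  tt <- data$n_days
  spat_int <- state$c_coef[1] * state$W1[data$site]
  spat_slo <- (state$c_coef[2] * state$W1[data$site] +
               state$c_coef[3] * state$W2[data$site]) * data$aod
  base <- data$y - drop(cache$X %*% state$gamma) - spat_int - spat_slo
  if (which == 0) {
    r <- base - state$beta1[data$day] * data$aod
    h <- rep(1, length(r))
    tau <- state$tau0
  } else {
    r <- base - state$beta0[data$day]
    h <- data$aod
    tau <- state$tau1
  }
  sum_by_day <- function(v) {
    out <- numeric(tt)
    agg <- rowsum(v, data$day)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  w <- sum_by_day(h * h) / state$sigma2
  lin <- sum_by_day(h * r) / state$sigma2
  k <- cache$K
  prec_u <- tau * cache$KQK + crossprod(k, w * k)
  fc <- gauss_mean_precision(prec_u, drop(crossprod(k, lin)))
  fc$K <- k
  fc$mean_beta <- drop(k %*% fc$mean)
  fc
}

fc_sigma2 <- function(state, data, prior, cache) {
  res <- data$y - evaluate_mean(state, data)
  list(shape = prior$sigma2_shape + cache$n / 2,
       rate = prior$sigma2_rate + sum(res^2) / 2)
}

fc_tau <- function(state, data, prior, cache, which) {
  beta <- if (which == 0) state$beta0 else state$beta1
  list(shape = prior$tau_shape + (data$n_days - 1) / 2,
       rate = prior$tau_rate + drop(crossprod(beta, cache$Q %*% beta)) / 2)
}

# discrete full conditional over the range grid for one latent process
fc_phi <- function(state, data, prior, cache, which) {
  w <- if (which == 1) state$W1 else state$W2
  lp <- vapply(cache$corr, function(cc) {
    -0.5 * cc$logdet - 0.5 * drop(crossprod(w, cc$inv %*% w))
  }, numeric(1))
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  list(candidates = prior$phi_grid, prob = p)
}

#' Gibbs block updates
#'
#' Each \code{update_*} function draws its parameter block from the exact
#' full conditional given the rest of \code{state} and returns the updated
#' state.  \code{update_coregionalization} resolves the sign
#' non-identifiability of the latent-process decomposition (the likelihood
#' is invariant under jointly flipping \code{W1, c1, c2}) by reflecting so
#' that \code{c1 >= 0}.  The proper unit-variance process prior pins the
#' level of \code{W1, W2}, and the daily series are drawn on the
#' sum-to-zero subspace, so the global intercept and slope stay identified.
#'
#' @param state A \code{\link{model_state}}.
#' @param data A \code{\link{downscale_data}}.
#' @param prior A \code{\link{downscale_priors}}.
#' @param cache Precomputed quantities from \code{build_chain_cache};
#'   rebuilt if omitted.
#' @return The updated \code{model_state}.
#' @name gibbs-updates
NULL

#' @rdname gibbs-updates
#' @export
update_gamma <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  fc <- fc_gamma(state, data, prior, cache)
  state$gamma <- drop(fc$mean + backsolve(fc$chol,
                                          stats::rnorm(length(fc$mean))))
  state
}

#' @rdname gibbs-updates
#' @export
update_latent_W <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  fc <- fc_W(state, data, prior, cache)
  m <- data$n_sites
  w <- drop(fc$mean + backsolve(fc$chol, stats::rnorm(2 * m)))
  state$W1 <- w[1:m]
  state$W2 <- w[m + 1:m]
  state
}

#' @rdname gibbs-updates
#' @export
update_coregionalization <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  fc <- fc_c(state, data, prior, cache)
  cc <- drop(fc$mean + backsolve(fc$chol, stats::rnorm(3)))
  if (cc[1] < 0) {   # reflect the sign symmetry (W1, c1, c2) -> -(W1, c1, c2)
    cc[1:2] <- -cc[1:2]
    state$W1 <- -state$W1
  }
  state$c_coef <- cc
  state
}

#' @rdname gibbs-updates
#' @export
update_temporal <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  for (which in 0:1) {
    fc <- fc_temporal(state, data, prior, cache, which)
    u <- drop(fc$mean + backsolve(fc$chol, stats::rnorm(length(fc$mean))))
    beta <- drop(fc$K %*% u)       # sum-zero by construction
    if (which == 0) state$beta0 <- beta else state$beta1 <- beta
  }
  state
}

#' @rdname gibbs-updates
#' @export
update_variances <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  fs <- fc_sigma2(state, data, prior, cache)
  state$sigma2 <- 1 / stats::rgamma(1, shape = fs$shape, rate = fs$rate)
  for (which in 0:1) {
    ft <- fc_tau(state, data, prior, cache, which)
    tau <- stats::rgamma(1, shape = ft$shape, rate = ft$rate)
    if (which == 0) state$tau0 <- tau else state$tau1 <- tau
  }
  state
}

#' @rdname gibbs-updates
#' @export
update_phi <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  for (which in 1:2) {
    fc <- fc_phi(state, data, prior, cache, which)
    phi <- fc$candidates[sample.int(length(fc$candidates), 1,
                                    prob = fc$prob)]
    if (which == 1) state$phi1 <- phi else state$phi2 <- phi
  }
  state
}

#' Joint log density of data and model state
#'
#' Likelihood times priors: Gaussian likelihood, zero-mean latent processes
#' with tapered-exponential correlation, intrinsic random-walk densities of
#' the sum-to-zero daily series (with their rank-deficient normalising
#' power of tau), normal priors on fixed effects and coregionalization
#' coefficients, inverse-gamma on the residual variance, gamma on the
#' increment precisions, and a uniform prior over the range grid.  Constant
#' terms that depend on no parameter are dropped.
#'
#' @inheritParams gibbs-updates
#' @return Scalar log density (up to an additive constant).
#' @keywords internal
log_joint <- function(state, data, prior, cache = NULL) {
  if (is.null(cache)) cache <- build_chain_cache(data, prior)
  res <- data$y - evaluate_mean(state, data)
  ll <- -0.5 * cache$n * log(2 * pi * state$sigma2) -
    sum(res^2) / (2 * state$sigma2)
  lw <- 0
  for (which in 1:2) {
    w <- if (which == 1) state$W1 else state$W2
    cc <- corr_for_phi(cache, prior,
                       if (which == 1) state$phi1 else state$phi2)
    lw <- lw - 0.5 * cc$logdet - 0.5 * drop(crossprod(w, cc$inv %*% w))
  }
  lb <- 0
  for (which in 0:1) {
    beta <- if (which == 0) state$beta0 else state$beta1
    tau <- if (which == 0) state$tau0 else state$tau1
    lb <- lb + 0.5 * (data$n_days - 1) * log(tau) -
      0.5 * tau * drop(crossprod(beta, cache$Q %*% beta))
  }
  lpri <- sum(stats::dnorm(state$gamma, 0, prior$gamma_sd, log = TRUE)) +
    sum(stats::dnorm(state$c_coef, 0, prior$gamma_sd, log = TRUE)) +
    (-(prior$sigma2_shape + 1) * log(state$sigma2) -
       prior$sigma2_rate / state$sigma2) +
    sum(vapply(c(state$tau0, state$tau1), function(tau) {
      (prior$tau_shape - 1) * log(tau) - prior$tau_rate * tau
    }, numeric(1)))
  ll + lw + lb + lpri
}
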