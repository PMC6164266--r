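#' Spatial covariance parameters
#'
#' Correlation of the latent spatial processes: an exponential kernel with
#' range \code{phi_km}, multiplied by a compactly supported taper so that
#' pairs further apart than \code{taper_km} have exactly zero correlation
#' and the resulting matrices are sparse.  The default taper support of
#' 400 km is the upper end of the mesoscale variability of
#' lower-tropospheric aerosol (roughly 40-400 km), so within-region
#' correlation is retained while cross-country correlation is cut exactly
#' to zero.  Marginal variance is fixed at 1; process scales are carried by
#' the coregionalization coefficients.
#'
#' @param phi_km Exponential correlation range in km (> 0).
#' @param taper_km Taper support radius in km (> 0).
#' @param taper Taper family: Wendland-1 (default) or spherical.
#' @return An object of class \code{spatial_cov_params}.
#' @export
spatial_cov_params <- function(phi_km, taper_km = 400,
                               taper = c("wendland1", "spherical")) {
  taper <- match.arg(taper)
  if (!is.numeric(phi_km) || length(phi_km) != 1L || !is.finite(phi_km) ||
      phi_km <= 0) {
    stop("spatial_cov_params: phi_km must be a positive scalar")
  }
  if (!is.numeric(taper_km) || length(taper_km) != 1L ||
      !is.finite(taper_km) || taper_km <= 0) {
    stop("spatial_cov_params: taper_km must be a positive scalar")
  }
  structure(list(phi_km = phi_km, taper_km = taper_km, taper = taper),
            class = "spatial_cov_params")
}

#' Tapered exponential correlation matrix
#'
#' Entry-wise \code{exp(-d/phi_km)} times the taper.  The Wendland-1 taper
#' is \code{(1 - d/T)^2 (1 + d/(2T))} for \code{d < T} and 0 beyond; the
#' spherical alternative is \code{1 - 1.5 d/T + 0.5 (d/T)^3}.  Both are
#' valid correlation functions in the plane, so the product with the
#' exponential remains positive definite.
#'
#' @param dist_matrix Matrix of pairwise distances in km (any shape; for a
#'   correlation matrix pass a symmetric matrix with zero diagonal).
#' @param params A \code{\link{spatial_cov_params}}.
#' @return Correlation matrix of the same shape as \code{dist_matrix}.
#' @export
tapered_exponential <- function(dist_matrix, params) {
  stopifnot(inherits(params, "spatial_cov_params"))
  d <- as.matrix(dist_matrix)
  if (any(d < 0)) stop("tapered_exponential: negative distances")
  u <- d / params$taper_km
  tap <- switch(params$taper,
    wendland1 = ifelse(u < 1, (1 - u)^2 * (1 + u / 2), 0),
    spherical = ifelse(u < 1, 1 - 1.5 * u + 0.5 * u^3, 0))
  exp(-d / params$phi_km) * tap
}

#' Precision parameters of the first-order random-walk daily effects
#'
#' @param tau Precision of the daily increments (> 0).
#' @param n_days Length of the daily series (>= 2).
#' @export
rw1_params <- function(tau, n_days) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("rw1_params: tau must be a positive scalar")
  }
  if (n_days < 2) stop("rw1_params: n_days must be >= 2")
  structure(list(tau = tau, n_days = as.integer(n_days)),
            class = "rw1_params")
}

#' Structure matrix / precision of an intrinsic first-order random walk
#'
#' Tridiagonal with diagonal \code{tau * (1, 2, ..., 2, 1)} and off-diagonal
#' \code{-tau}; row sums are zero, so the matrix has rank \code{n_days - 1}
#' (the level of the series is unidentified and must be pinned by a
#' constraint or by the likelihood).  The implied conditional mean of an
#' interior day given all others is the average of its two neighbours.
#'
#' @param params An \code{\link{rw1_params}}, or a plain integer number of
#'   days (then \code{tau = 1}, giving the unscaled structure matrix).
#' @return A dense \code{n_days x n_days} matrix.
#' @export
rw1_precision <- function(params) {
  if (is.numeric(params)) params <- rw1_params(1, params)
  stopifnot(inherits(params, "rw1_params"))
  n <- params$n_days
  q <- diag(c(1, rep(2, n - 2), 1))
  q[cbind(1:(n - 1), 2:n)] <- -1
  q[cbind(2:n, 1:(n - 1))] <- -1
  params$tau * q
}

# orthonormal basis of the sum-to-zero subspace {x : sum(x) = 0} in R^n
sum_zero_basis <- function(n) {
  qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
}

#' Gaussian process conditional (simple kriging) at new locations
#'
#' Conditional mean and covariance of a zero-mean, unit-variance process
#' with tapered-exponential correlation at \code{new_locs}, given its values
#' at \code{obs_locs}.  A small jitter is added to the observed-location
#' correlation before factorisation for numerical stability with
#' near-coincident sites.
#'
#' @param obs_locs,new_locs Two-column coordinate matrices (km).
#' @param params A \code{\link{spatial_cov_params}}.
#' @param obs_values Process values at \code{obs_locs}.
#' @param jitter Diagonal jitter (default 1e-8).
#' @return List with \code{mean} (length \code{nrow(new_locs)}) and
#'   \code{cov} (conditional covariance matrix).
#' @export
gp_conditional <- function(obs_locs, new_locs, params, obs_values,
                           jitter = 1e-8) {
  obs_locs <- as.matrix(obs_locs)
  new_locs <- as.matrix(new_locs)
  if (length(obs_values) != nrow(obs_locs)) {
    stop("gp_conditional: obs_values length must match obs_locs")
  }
  r_oo <- tapered_exponential(pairwise_distances(obs_locs), params)
  diag(r_oo) <- diag(r_oo) + jitter
  ch <- tryCatch(chol(r_oo), error = function(e) {
    stop("gp_conditional: observed-location correlation is singular after ",
         "jitter ", jitter, "; reciprocal condition number ",
         format(rcond(r_oo), digits = 3))
  })
  r_no <- tapered_exponential(pairwise_distances(new_locs, obs_locs), params)
  r_nn <- tapered_exponential(pairwise_distances(new_locs), params)
  # with L = t(ch): mean = (L^-1 R_on)' (L^-1 y), cov = R_nn - (L^-1 R_on)'(L^-1 R_on)
  v <- forwardsolve(t(ch), t(r_no))
  cond_mean <- drop(crossprod(v, forwardsolve(t(ch), obs_values)))
  cond_cov <- r_nn - crossprod(v)
  # clamp tiny negative variances from finite precision
  diag(cond_cov) <- pmax(diag(cond_cov), 0)
  list(mean = cond_mean, cov = (cond_cov + t(cond_cov)) / 2)
}

# one draw from N(mean, cov) given the conditional returned by gp_conditional
draw_gp_conditional <- function(cond, jitter = 1e-8) {
  n <- length(cond$mean)
  cv <- cond$cov
  diag(cv) <- diag(cv) + jitter
  ch <- chol(cv)
  drop(cond$mean + crossprod(ch, stats::rnorm(n)))
}
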