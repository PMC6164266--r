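#' Prior specification for the downscaling model
#'
#' Weakly informative defaults of the kind standard for downscaler-type
#' hierarchical models: independent mean-zero normal priors with a large SD
#' on the fixed effects and coregionalization coefficients, a vague
#' inverse-gamma prior on the residual variance, a vague gamma prior on the
#' random-walk increment precisions, and a finite log-spaced grid of
#' candidate spatial ranges spanning 10-400 km, updated by a discrete
#' (griddy) Gibbs step so every candidate's correlation factorisation can
#' be precomputed once per run.
#'
#' @param gamma_sd Prior SD of fixed effects and coregionalization
#'   coefficients (default 100).
#' @param sigma2_shape,sigma2_rate Inverse-gamma prior on the residual
#'   variance (default 0.001, 0.001).
#' @param tau_shape,tau_rate Gamma prior on the random-walk precisions
#'   (default 0.5, 5e-4).
#' @param phi_grid Candidate spatial ranges in km (default six log-spaced
#'   values from 10 to 400).
#' @param taper_km,taper Taper support radius and family passed to
#'   \code{\link{spatial_cov_params}}.
#' @param jitter Diagonal jitter for correlation factorisations.
#' @return Object of class \code{downscale_priors}.
#' @export
downscale_priors <- function(gamma_sd = 100,
                             sigma2_shape = 0.001, sigma2_rate = 0.001,
                             tau_shape = 0.5, tau_rate = 5e-4,
                             phi_grid = exp(seq(log(10), log(400),
                                                length.out = 6)),
                             taper_km = 400,
                             taper = "wendland1",
                             jitter = 1e-8) {
  stopifnot(gamma_sd > 0, sigma2_shape > 0, sigma2_rate > 0,
            tau_shape > 0, tau_rate > 0, length(phi_grid) >= 1,
            all(phi_grid > 0), taper_km > 0)
  structure(list(gamma_sd = gamma_sd,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 phi_grid = sort(phi_grid), taper_km = taper_km,
                 taper = taper, jitter = jitter),
            class = "downscale_priors")
}

#' MCMC chain configuration
#'
#' @param n_iter Total Gibbs iterations.
#' @param n_burn Burn-in iterations discarded (must be < \code{n_iter}).
#' @param thin Keep every \code{thin}-th post-burn state.
#' @param seed Optional integer seed; the chain is reproducible given it.
#' @param verbose Log progress every 100 iterations?
#' @param update Named logical vector switching individual Gibbs blocks on
#'   or off (\code{gamma}, \code{W}, \code{c}, \code{temporal},
#'   \code{variances}, \code{phi}); disabled blocks stay at their initial
#'   values, which is how reduced conjugate sub-models are run.
#' @return Object of class \code{chain_control}.
#' @export
chain_control <- function(n_iter = 5000, n_burn = 2500, thin = 5,
                          seed = NULL, verbose = FALSE,
                          update = c(gamma = TRUE, W = TRUE, c = TRUE,
                                     temporal = TRUE, variances = TRUE,
                                     phi = TRUE)) {
  stopifnot(n_iter >= 1, n_burn >= 0, n_burn < n_iter, thin >= 1)
  blocks <- c("gamma", "W", "c", "temporal", "variances", "phi")
  upd <- stats::setNames(rep(TRUE, 6), blocks)
  upd[names(update)] <- update
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = seed, verbose = verbose,
                 update = upd),
            class = "chain_control")
}
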