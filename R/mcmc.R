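#' Initial model state for a chain
#'
#' Fixed effects from ordinary least squares of the response on the design,
#' latent processes and daily series at zero, residual variance from the
#' OLS residuals, increment precisions at 1, and ranges at the grid median.
#'
#' @inheritParams gibbs-updates
#' @return A \code{\link{model_state}}.
#' @export
init_state <- function(data, prior) {
  x <- cbind(1, data$aod, data$Z)
  fit <- stats::lm.fit(x, data$y)
  g <- fit$coefficients
  g[is.na(g)] <- 0
  s2 <- max(stats::var(fit$residuals), 1e-6)
  mid <- prior$phi_grid[ceiling(length(prior$phi_grid) / 2)]
  model_state(gamma = unname(g), c_coef = c(0.1, 0, 0.1),
              W1 = numeric(data$n_sites), W2 = numeric(data$n_sites),
              beta0 = numeric(data$n_days), beta1 = numeric(data$n_days),
              sigma2 = s2, tau0 = 1, tau1 = 1, phi1 = mid, phi2 = mid)
}

#' Run the Gibbs sampler for one regional model
#'
#' Systematic-scan Gibbs sampler over the conjugate blocks in the fixed
#' order fixed effects, latent processes, coregionalization coefficients,
#' daily series, variances, spatial ranges.  All draws flow from R's RNG,
#' so a given \code{seed} reproduces the chain exactly.
#'
#' @param data A \code{\link{downscale_data}}.
#' @param prior A \code{\link{downscale_priors}}.
#' @param control A \code{\link{chain_control}}.
#' @param state Optional starting \code{\link{model_state}}.
#' @return Object of class \code{posterior_samples}: retained states,
#'   configuration and seed provenance.
#' @export
run_chain <- function(data, prior = downscale_priors(),
                      control = chain_control(), state = NULL) {
  stopifnot(inherits(data, "downscale_data"),
            inherits(prior, "downscale_priors"),
            inherits(control, "chain_control"))
  if (!is.null(control$seed)) set.seed(control$seed)
  cache <- build_chain_cache(data, prior)
  if (is.null(state)) state <- init_state(data, prior)
  upd <- control$update
  n_keep <- length(seq.int(control$n_burn + 1, control$n_iter,
                           by = control$thin))
  states <- vector("list", n_keep)
  kept <- 0L
  for (it in seq_len(control$n_iter)) {
    ok <- tryCatch({
      if (upd["gamma"]) state <- update_gamma(state, data, prior, cache)
      if (upd["W"]) state <- update_latent_W(state, data, prior, cache)
      if (upd["c"]) {
        state <- update_coregionalization(state, data, prior, cache)
      }
      if (upd["temporal"]) state <- update_temporal(state, data, prior, cache)
      if (upd["variances"]) {
        state <- update_variances(state, data, prior, cache)
      }
      if (upd["phi"]) state <- update_phi(state, data, prior, cache)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("run_chain: update failed at iteration ", it, ": ",
           conditionMessage(ok))
    }
    if (it > control$n_burn && (it - control$n_burn - 1) %% control$thin == 0) {
      kept <- kept + 1L
      states[[kept]] <- state
    }
    if (control$verbose && it %% 100 == 0) {
      message(sprintf("[run_chain] iteration %d/%d (sigma2=%.3f, phi1=%.0f)",
                      it, control$n_iter, state$sigma2, state$phi1))
    }
  }
  structure(list(states = states[seq_len(kept)],
                 prior = prior, control = control,
                 seed = control$seed,
                 n_records = length(data$y),
                 site_ids = data$site_ids,
                 coords = data$coords,
                 days = data$days,
                 covariates = data$covariates,
                 acceptance = c(gibbs = 1)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", length(x$states), "retained states (n_iter =",
      x$control$n_iter, ", burn =", x$control$n_burn, ", thin =",
      x$control$thin, ")\n")
  invisible(x)
}

#' Extract a posterior draw matrix of scalar parameters
#'
#' @param samples A \code{posterior_samples}.
#' @return Matrix with one row per retained state and named columns for the
#'   fixed effects, coregionalization coefficients, variances, precisions
#'   and ranges.
#' @export
as_draw_matrix <- function(samples) {
  g <- t(vapply(samples$states, function(s) s$gamma,
                numeric(length(samples$states[[1]]$gamma))))
  p <- ncol(g) - 2
  colnames(g) <- c("mu0", "mu_aod",
                   if (p > 0) samples$covariates else character(0))
  other <- t(vapply(samples$states, function(s) {
    c(c1 = s$c_coef[1], c2 = s$c_coef[2], c3 = s$c_coef[3],
      sigma2 = s$sigma2, tau0 = s$tau0, tau1 = s$tau1,
      phi1 = s$phi1, phi2 = s$phi2)
  }, numeric(8)))
  cbind(g, other)
}
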