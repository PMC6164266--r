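#' Fit the Bayesian downscaling model for one region and temporal block
#'
#' End-to-end fit: monitor records are paired with their containing grid
#' cell, covariates are log/z-transformed (scaling fitted on the training
#' records and stored for prediction), the optional AOD-by-temperature
#' interaction column is built, and the Gibbs sampler is run.
#'
#' @param monitors Data frame \code{site_id, x_km, y_km, day, pm25}.
#' @param grid Data frame \code{cell_id, x_km, y_km, day, aod} plus
#'   covariate columns; missing AOD as \code{NA}.
#' @param cov_spec A \code{\link{covariate_spec}}.
#' @param cell_km Grid cell size in km.
#' @param prior A \code{\link{downscale_priors}}.
#' @param control A \code{\link{chain_control}}.
#' @param days Optional integer day range of the temporal block (defaults
#'   to the observed range).
#' @return Object of class \code{downscale_fit}: the posterior samples,
#'   the assembled analysis data, the fitted transform, and bookkeeping.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sites = 12, n_days = 8, seed = 1))
#' fit <- downscale(sim$monitors, sim$grid, sim$cov_spec, cell_km = 12,
#'                  control = chain_control(n_iter = 200, n_burn = 100,
#'                                          thin = 2, seed = 1))
#' coef(fit)[1:2]
#' @export
downscale <- function(monitors, grid, cov_spec, cell_km = 12,
                      prior = downscale_priors(),
                      control = chain_control(), days = NULL) {
  stopifnot(inherits(cov_spec, "covariate_spec"))
  ali <- align_monitors_to_cells(monitors, grid, cell_km)
  tr <- apply_transforms(ali$table, cov_spec)
  tab <- tr$panel
  covs <- cov_spec$names
  if (cov_spec$interaction_aod_temp) {
    tab$aod_temp <- tab$aod * tab[[cov_spec$temp_name]]
    covs <- c(covs, "aod_temp")
  }
  data <- downscale_data(tab, covs, days = days)
  samples <- run_chain(data, prior, control)
  structure(list(samples = samples, data = data,
                 transform = tr$transform, cov_spec = cov_spec,
                 cell_km = cell_km,
                 n_dropped_aod = ali$n_dropped_aod,
                 n_dropped_outside = ali$n_dropped_outside,
                 call = match.call()),
            class = "downscale_fit")
}

#' @export
print.downscale_fit <- function(x, ...) {
  cat("Bayesian downscaling fit\n")
  cat("  records:", length(x$data$y), " sites:", x$data$n_sites,
      " days:", x$data$n_days, "\n")
  cat("  records dropped for missing AOD:", x$n_dropped_aod, "\n")
  cat("  retained posterior states:", length(x$samples$states), "\n")
  cat("  posterior mean AOD slope:",
      format(mean(vapply(x$samples$states, function(s) s$gamma[2],
                         numeric(1))), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.downscale_fit <- function(object, prob = 0.9, ...) {
  dm <- as_draw_matrix(object$samples)
  a <- (1 - prob) / 2
  tab <- data.frame(
    mean = colMeans(dm),
    sd = apply(dm, 2, stats::sd),
    lower = apply(dm, 2, stats::quantile, a),
    upper = apply(dm, 2, stats::quantile, 1 - a))
  structure(list(coefficients = tab, prob = prob,
                 n_records = length(object$data$y),
                 n_states = nrow(dm)),
            class = "summary.downscale_fit")
}

#' @export
print.summary.downscale_fit <- function(x, ...) {
  cat("Posterior summary (", x$n_states, " states, ",
      format(100 * x$prob), "% intervals):\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.downscale_fit <- function(object, ...) {
  colMeans(as_draw_matrix(object$samples))
}

#' @export
fitted.downscale_fit <- function(object, ...) {
  mu <- vapply(object$samples$states,
               function(s) evaluate_mean(s, object$data),
               numeric(length(object$data$y)))
  rowMeans(mu)
}

#' @export
residuals.downscale_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Posterior predictive replicates of the training records
#'
#' @param object A \code{downscale_fit}.
#' @param nsim Number of replicate datasets (each uses one retained state,
#'   cycling through the chain).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix, one column per replicate of the training response.
#' @export
simulate.downscale_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  states <- object$samples$states
  n <- length(object$data$y)
  idx <- rep_len(seq_along(states), nsim)
  out <- vapply(idx, function(i) {
    s <- states[[i]]
    evaluate_mean(s, object$data) + stats::rnorm(n, 0, sqrt(s$sigma2))
  }, numeric(n))
  matrix(out, nrow = n)
}

#' Trace plots of key scalar parameters
#'
#' @param x A \code{downscale_fit}.
#' @param pars Parameter names (columns of \code{\link{as_draw_matrix}}).
#' @param ... Passed to \code{plot}.
#' @export
plot.downscale_fit <- function(x, pars = c("mu0", "mu_aod", "sigma2", "c1"),
                               ...) {
  dm <- as_draw_matrix(x$samples)
  pars <- intersect(pars, colnames(dm))
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    plot(dm[, p], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}
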