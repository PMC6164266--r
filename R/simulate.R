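#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure the downscaling model assumes:
#' point monitors scattered inside a regular grid of cells (spatial
#' misalignment), satellite AOD observed only on a fraction of cell-days
#' (retrieval gaps from cloud and snow cover; observed national coverage is
#' roughly 12-30 percent, default 20), log-normal AOD on the descriptive
#' scale of the real retrievals (mean about 0.14, SD about 0.15), strictly
#' positive unimodal covariates, latent spatial processes with
#' tapered-exponential correlation, sum-to-zero random-walk daily effects,
#' and Gaussian residual noise.  Default effect sizes are on the scale of a
#' regional PM2.5 model: baseline near 10 ug/m3, AOD slope in the tens,
#' covariate effects of order one, residual SD 2 ug/m3.
#'
#' @param n_sites Number of monitors.
#' @param grid_nx,grid_ny Grid dimensions (cells).
#' @param cell_km Cell size in km (default 12).
#' @param n_days Number of days in the block.
#' @param covariates Covariate names (those in \code{c("fire", "emission",
#'   "road")} are treated as count-like).
#' @param gamma True fixed effects: global intercept, global AOD slope,
#'   then one coefficient per covariate (on the transformed scale).
#' @param c_coef True coregionalization coefficients (c1, c2, c3).
#' @param sigma2 Residual variance.
#' @param tau0,tau1 Random-walk increment precisions.
#' @param phi_km Spatial range of both latent processes.
#' @param taper_km Taper support radius.
#' @param aod_meanlog,aod_sdlog Log-normal AOD parameters.
#' @param aod_coverage Fraction of cell-days with an AOD retrieval.
#' @param n_regions 1 or 2 side-by-side rectangular regions.
#' @param buffer_km Region buffer width.
#' @param seed Integer seed; everything is reproducible from it.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_sites = 60, grid_nx = 10, grid_ny = 8,
                       cell_km = 12, n_days = 40,
                       covariates = c("fire", "forest", "rh", "temp"),
                       gamma = c(10, 15, 0.4, -0.6, 1.5, 2),
                       c_coef = c(2, 5, 3),
                       sigma2 = 4, tau0 = 0.5, tau1 = 2,
                       phi_km = 50, taper_km = 400,
                       aod_meanlog = -2.35, aod_sdlog = 0.87,
                       aod_coverage = 0.2,
                       n_regions = 2, buffer_km = 30,
                       seed = 1) {
  stopifnot(aod_coverage > 0, aod_coverage <= 1,
            n_sites >= 1, grid_nx >= 1, grid_ny >= 1, n_days >= 2,
            length(gamma) == 2 + length(covariates),
            length(c_coef) == 3, sigma2 >= 0, n_regions %in% 1:2)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic monitor/grid dataset with known truth
#'
#' Lays out the grid, scatters monitors uniformly over the domain, draws
#' the two latent processes jointly at monitor sites and cell centroids
#' from the tapered-exponential Gaussian process, draws the two daily
#' series from a sum-to-zero first-order random walk, draws true AOD for
#' every cell-day (log-normal) and hides it off-coverage, draws covariates,
#' and composes PM2.5 from the model mean plus Gaussian noise.  Covariates
#' enter the true mean after the same log/z transforms the fitting path
#' applies, with scaling fitted on the records that carry observed AOD, so
#' fitted fixed effects are directly comparable to \code{config$gamma}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{monitors}, \code{grid}, \code{regions} (a
#'   \code{\link{region_set}} of one or two rectangles), \code{cov_spec},
#'   and \code{truth} (generating state, latent fields at sites and cells,
#'   daily series, fitted transform, noiseless record means).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  nx <- cfg$grid_nx; ny <- cfg$grid_ny; ck <- cfg$cell_km
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cells$cell_id <- sprintf("c%03d", seq_len(nrow(cells)))
  cells$x_km <- (cells$ix - 0.5) * ck
  cells$y_km <- (cells$iy - 0.5) * ck

  sites <- data.frame(
    site_id = sprintf("s%03d", seq_len(cfg$n_sites)),
    x_km = stats::runif(cfg$n_sites, 0, nx * ck),
    y_km = stats::runif(cfg$n_sites, 0, ny * ck))

  # latent processes on sites + centroids jointly
  all_loc <- rbind(as.matrix(sites[c("x_km", "y_km")]),
                   as.matrix(cells[c("x_km", "y_km")]))
  cp <- spatial_cov_params(cfg$phi_km, cfg$taper_km)
  r <- tapered_exponential(pairwise_distances(all_loc), cp)
  diag(r) <- diag(r) + 1e-8
  ch <- chol(r)
  w1 <- drop(crossprod(ch, stats::rnorm(nrow(all_loc))))
  w2 <- drop(crossprod(ch, stats::rnorm(nrow(all_loc))))
  ns <- cfg$n_sites
  w1_sites <- w1[seq_len(ns)] - mean(w1[seq_len(ns)])
  w2_sites <- w2[seq_len(ns)] - mean(w2[seq_len(ns)])
  w1_cells <- w1[-seq_len(ns)] - mean(w1[seq_len(ns)])
  w2_cells <- w2[-seq_len(ns)] - mean(w2[seq_len(ns)])

  rw1_series <- function(tau, tt) {
    b <- cumsum(c(0, stats::rnorm(tt - 1, sd = 1 / sqrt(tau))))
    b - mean(b)
  }
  beta0 <- rw1_series(cfg$tau0, cfg$n_days)
  beta1 <- rw1_series(cfg$tau1, cfg$n_days)

  # per cell-day AOD (true everywhere, observed on a coverage subset)
  n_cd <- nrow(cells) * cfg$n_days
  grid <- data.frame(
    cell_id = rep(cells$cell_id, each = cfg$n_days),
    x_km = rep(cells$x_km, each = cfg$n_days),
    y_km = rep(cells$y_km, each = cfg$n_days),
    day = rep(seq_len(cfg$n_days), nrow(cells)))
  aod_true <- stats::rlnorm(n_cd, cfg$aod_meanlog, cfg$aod_sdlog)
  observed <- stats::runif(n_cd) < cfg$aod_coverage
  grid$aod <- ifelse(observed, aod_true, NA_real_)
  for (v in cfg$covariates) {
    grid[[v]] <- stats::rlnorm(n_cd, meanlog = 0.5, sdlog = 0.6)
  }

  # monitors: one record per site-day; covariates come from the site's cell
  cell_of_site <- pmin(pmax(floor(sites$x_km / ck), 0), nx - 1) + 1 +
    nx * pmin(pmax(floor(sites$y_km / ck), 0), ny - 1)
  rec <- data.frame(
    site_id = rep(sites$site_id, each = cfg$n_days),
    day = rep(seq_len(cfg$n_days), ns),
    site = rep(seq_len(ns), each = cfg$n_days),
    cell = rep(cell_of_site, each = cfg$n_days))
  gi <- (rec$cell - 1) * cfg$n_days + rec$day   # row of grid for (cell, day)
  rec$aod_true <- aod_true[gi]
  rec$aod_obs <- observed[gi]

  # transform scaling fitted on the likelihood records (observed AOD),
  # exactly as the fitting path will refit it
  spec <- covariate_spec(cfg$covariates, interaction_aod_temp = FALSE)
  raw_cov <- grid[gi, cfg$covariates, drop = FALSE]
  tr_fit <- apply_transforms(raw_cov[rec$aod_obs, , drop = FALSE], spec)
  tr_all <- apply_transforms(raw_cov, spec, fitted = tr_fit$transform)
  z <- as.matrix(tr_all$panel)

  g <- cfg$gamma
  mu <- (g[1] + cfg$c_coef[1] * w1_sites[rec$site] + beta0[rec$day]) +
    (g[2] + cfg$c_coef[2] * w1_sites[rec$site] +
       cfg$c_coef[3] * w2_sites[rec$site] + beta1[rec$day]) * rec$aod_true +
    drop(z %*% g[-(1:2)])
  pm <- mu + stats::rnorm(nrow(rec), sd = sqrt(cfg$sigma2))

  monitors <- data.frame(site_id = rec$site_id,
                         x_km = sites$x_km[rec$site],
                         y_km = sites$y_km[rec$site],
                         day = rec$day, pm25 = pm)

  regions <- simulate_regions(nx * ck, ny * ck, cfg$n_regions, cfg$buffer_km)

  truth_state <- model_state(gamma = g, c_coef = cfg$c_coef,
                             W1 = w1_sites, W2 = w2_sites,
                             beta0 = beta0, beta1 = beta1,
                             sigma2 = max(cfg$sigma2, 1e-12),
                             tau0 = cfg$tau0, tau1 = cfg$tau1,
                             phi1 = cfg$phi_km, phi2 = cfg$phi_km)
  list(monitors = monitors, grid = grid, regions = regions,
       cov_spec = spec,
       truth = list(state = truth_state, config = config,
                    sites = sites,
                    W1_cells = w1_cells, W2_cells = w2_cells,
                    beta0 = beta0, beta1 = beta1,
                    transform = tr_fit$transform,
                    mean = mu, aod_true = rec$aod_true,
                    aod_observed = rec$aod_obs))
}

# one or two side-by-side rectangular regions covering the domain
simulate_regions <- function(width_km, height_km, n_regions, buffer_km) {
  rect <- function(id, x0, x1) {
    data.frame(region_id = id, vertex_order = 1:4,
               x_km = c(x0, x1, x1, x0),
               y_km = c(0, 0, height_km, height_km))
  }
  polys <- if (n_regions == 1) {
    rect("R1", 0, width_km)
  } else {
    rbind(rect("R1", 0, width_km / 2), rect("R2", width_km / 2, width_km))
  }
  region_set(polygons = polys, buffer_km = buffer_km)
}

#' Simulation-based parameter recovery experiment
#'
#' Repeatedly simulates a dataset, fits the model by MCMC, and records the
#' posterior mean, 90 percent credible interval and coverage flag for every
#' scalar generating parameter, plus the relative bias of the posterior
#' mean of the residual variance.
#'
#' @param config A \code{\link{sim_config}}; replicate \code{r} uses seed
#'   \code{config$seed + r - 1}.
#' @param n_replicates Number of simulate-fit replicates.
#' @param prior,control Passed to \code{\link{run_chain}} (the chain seed
#'   follows the replicate seed).
#' @return List with \code{per_replicate} (long data frame: replicate,
#'   parameter, truth, posterior mean, lower, upper, covered) and
#'   \code{summary} (per-parameter coverage and relative bias).
#' @export
recovery_experiment <- function(config, n_replicates,
                                prior = downscale_priors(),
                                control = chain_control()) {
  stopifnot(n_replicates >= 1)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    sim <- simulate_dataset(cfg)
    ctl <- control
    ctl$seed <- cfg$seed + 10000L
    fit <- downscale(sim$monitors, sim$grid, cov_spec = sim$cov_spec,
                     cell_km = cfg$cell_km, prior = prior, control = ctl)
    dm <- as_draw_matrix(fit$samples)
    truth <- c(mu0 = cfg$gamma[1], mu_aod = cfg$gamma[2],
               stats::setNames(cfg$gamma[-(1:2)], cfg$covariates),
               c1 = cfg$c_coef[1], c2 = cfg$c_coef[2], c3 = cfg$c_coef[3],
               sigma2 = cfg$sigma2)
    keep <- intersect(names(truth), colnames(dm))
    est <- colMeans(dm[, keep, drop = FALSE])
    lo <- apply(dm[, keep, drop = FALSE], 2, stats::quantile, 0.05)
    hi <- apply(dm[, keep, drop = FALSE], 2, stats::quantile, 0.95)
    rows[[r]] <- data.frame(replicate = r, parameter = keep,
                            truth = truth[keep], estimate = est,
                            lower = lo, upper = hi,
                            covered = truth[keep] >= lo & truth[keep] <= hi,
                            row.names = NULL)
  }
  per <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(per, per$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               coverage = mean(d$covered),
               rel_bias = mean((d$estimate - d$truth) /
                                 ifelse(d$truth == 0, 1, abs(d$truth))))
  }))
  rownames(sm) <- NULL
  list(per_replicate = per, summary = sm)
}
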