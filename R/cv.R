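#' Random record-level folds
#'
#' Uniform partition of record indices into \code{k} folds whose sizes
#' differ by at most one; reproducible given the seed.
#'
#' @param n Number of records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold labels of length \code{n}.
#' @export
make_random_folds <- function(n, k = 10, seed = 1) {
  stopifnot(k >= 2)
  if (k > n) stop("make_random_folds: k exceeds the number of records")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Spatially blocked folds by site
#'
#' Sites are clustered into \code{k} spatially contiguous groups by k-means
#' on their planar coordinates (best of 10 seeded restarts); every record
#' of a site inherits the site's fold, so held-out folds contain entire
#' monitor locations and the scheme measures spatial extrapolation.
#'
#' @param site_coords Two-column coordinate matrix, one row per site.
#' @param k Number of folds (>= 2, at most the number of distinct sites).
#' @param seed Integer seed.
#' @return Integer fold labels, one per site (row of \code{site_coords}).
#' @export
make_spatial_folds <- function(site_coords, k = 10, seed = 1) {
  xy <- as.matrix(site_coords)
  stopifnot(k >= 2)
  if (nrow(unique(xy)) < k) {
    stop("make_spatial_folds: fewer distinct sites than folds")
  }
  set.seed(seed)
  km <- stats::kmeans(xy, centers = k, nstart = 10)
  as.integer(km$cluster)
}

#' Cross-validation metrics
#'
#' Calibration regression of observed on predicted PM2.5 (intercept and
#' slope, with the coefficient of determination from that fit), root mean
#' squared prediction error, empirical coverage of the 90 percent
#' predictive intervals, and their mean length.
#'
#' @param observed,predicted Aligned numeric vectors (n >= 3).
#' @param pi_lower,pi_upper Optional predictive interval bounds.
#' @return One-row data frame: n, r2, intercept, slope, rmse, coverage,
#'   pi_length.  With zero-variance predictions r2/intercept/slope are NA.
#' @export
cv_metrics <- function(observed, predicted, pi_lower = NULL,
                       pi_upper = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  rmse <- sqrt(mean((observed - predicted)^2))
  if (stats::sd(predicted) == 0) {
    r2 <- intercept <- slope <- NA_real_
  } else {
    fit <- stats::lm(observed ~ predicted)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
    tss <- sum((observed - mean(observed))^2)
    r2 <- if (tss == 0) NA_real_ else 1 - sum(fit$residuals^2) / tss
  }
  coverage <- pi_length <- NA_real_
  if (!is.null(pi_lower) && !is.null(pi_upper)) {
    coverage <- mean(observed >= pi_lower & observed <= pi_upper)
    pi_length <- mean(pi_upper - pi_lower)
  }
  data.frame(n = length(observed), r2 = r2, intercept = intercept,
             slope = slope, rmse = rmse, coverage = coverage,
             pi_length = pi_length)
}

#' Cross-validated evaluation of the downscaling model
#'
#' Random 10-fold CV holds out records; spatial 10-fold CV holds out whole
#' monitor locations (k-means blocks).  For each fold the model is refitted
#' on the complement (covariate scaling refitted on the training records)
#' and the held-out records are predicted from the posterior predictive
#' distribution: the latent processes are kriged to held-out sites, the
#' daily effects of the held-out record's day are reused, and a residual
#' draw is added.  A held-out site beyond the taper range of every training
#' site simply receives a fresh latent draw, i.e. prediction from the fixed
#' and temporal effects with full latent uncertainty.
#'
#' @param monitors,grid,cov_spec,cell_km As in \code{\link{downscale}}.
#' @param k Number of folds.
#' @param scheme \code{"random"} or \code{"spatial"}.
#' @param prior,control Passed to each fold's \code{\link{run_chain}}
#'   (fold f uses chain seed \code{seed + f}).
#' @param seed Seed for fold assignment and chain seeds.
#' @return Object of class \code{cv_report}: \code{pooled} metrics row,
#'   \code{per_fold} metrics, and \code{predictions} (record-level table
#'   with fold, observed, predicted, interval bounds).
#' @export
run_cv <- function(monitors, grid, cov_spec, cell_km = 12, k = 10,
                   scheme = c("random", "spatial"),
                   prior = downscale_priors(),
                   control = chain_control(n_iter = 1000, n_burn = 500,
                                           thin = 5),
                   seed = 1) {
  scheme <- match.arg(scheme)
  ali <- align_monitors_to_cells(monitors, grid, cell_km)
  tab <- ali$table
  days <- seq(min(tab$day), max(tab$day))
  sites <- unique(tab[c("site_id", "x_km", "y_km")])
  if (scheme == "random") {
    fold <- make_random_folds(nrow(tab), k, seed)
  } else {
    site_fold <- make_spatial_folds(sites[c("x_km", "y_km")], k, seed)
    fold <- site_fold[match(tab$site_id, sites$site_id)]
  }
  covs0 <- cov_spec$names
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- tab[fold != f, , drop = FALSE]
    test <- tab[fold == f, , drop = FALSE]
    if (nrow(test) == 0) next
    tr <- apply_transforms(train, cov_spec)
    train_t <- tr$panel
    test_t <- apply_transforms(test, cov_spec, fitted = tr$transform)$panel
    covs <- covs0
    if (cov_spec$interaction_aod_temp) {
      train_t$aod_temp <- train_t$aod * train_t[[cov_spec$temp_name]]
      test_t$aod_temp <- test_t$aod * test_t[[cov_spec$temp_name]]
      covs <- c(covs, "aod_temp")
    }
    dat <- downscale_data(train_t, covs, days = days)
    ctl <- control
    ctl$seed <- if (is.null(seed)) NULL else seed + f
    samples <- run_chain(dat, prior, ctl)
    test_sites <- unique(test_t[c("site_id", "x_km", "y_km")])
    draws <- posterior_predict_records(
      samples, as.matrix(test_sites[c("x_km", "y_km")]),
      match(test_t$site_id, test_sites$site_id),
      match(test_t$day, days), test_t$aod,
      as.matrix(test_t[covs]), include_resid = TRUE)
    sm <- summarise_draws(draws)
    preds[[f]] <- data.frame(fold = f, site_id = test_t$site_id,
                             day = test_t$day, observed = test_t$pm25,
                             predicted = sm$mean, lo90 = sm$lo90,
                             hi90 = sm$hi90)
  }
  pred <- do.call(rbind, preds)
  pooled <- cv_metrics(pred$observed, pred$predicted, pred$lo90, pred$hi90)
  per_fold <- do.call(rbind, lapply(split(pred, pred$fold), function(d) {
    cbind(fold = d$fold[1],
          cv_metrics(d$observed, d$predicted, d$lo90, d$hi90))
  }))
  rownames(per_fold) <- NULL
  structure(list(scheme = scheme, k = k, pooled = pooled,
                 per_fold = per_fold, predictions = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation (", x$scheme, ", ", x$k, " folds, ",
      nrow(x$predictions), " held-out records)\n", sep = "")
  cat(sprintf("  pooled R2 %.3f  slope %.3f  intercept %.3f  RMSE %.3f\n",
              x$pooled$r2, x$pooled$slope, x$pooled$intercept,
              x$pooled$rmse))
  cat(sprintf("  90%% PI coverage %.3f  mean length %.3f\n",
              x$pooled$coverage, x$pooled$pi_length))
  invisible(x)
}
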