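# Posterior predictive draws at arbitrary point locations.  For each
# retained state the latent processes are kriged from the fitted sites to
# the target locations (simple kriging under the state's range, reusing one
# factorisation per unique range on the grid), the model mean is composed,
# and a residual draw is added, giving one predictive draw per state.
posterior_predict_records <- function(samples, new_coords, loc, day, aod, z,
                                      include_resid = TRUE) {
  stopifnot(inherits(samples, "posterior_samples"))
  n_days <- length(samples$days)
  if (any(day < 1 | day > n_days)) {
    stop("prediction day outside the fitted temporal block")
  }
  prior <- samples$prior
  obs <- samples$coords
  new_coords <- as.matrix(new_coords)
  d_oo <- pairwise_distances(obs)
  d_no <- pairwise_distances(new_coords, obs)
  d_nn <- pairwise_distances(new_coords)
  krig <- new.env(parent = emptyenv())
  krig_for <- function(phi) {
    key <- format(phi, digits = 12)
    if (!is.null(krig[[key]])) return(krig[[key]])
    cp <- spatial_cov_params(phi, prior$taper_km, prior$taper)
    r_oo <- tapered_exponential(d_oo, cp)
    diag(r_oo) <- diag(r_oo) + prior$jitter
    ch <- chol(r_oo)
    r_on <- t(tapered_exponential(d_no, cp))
    m <- backsolve(ch, forwardsolve(t(ch), r_on))     # R_oo^{-1} R_on
    v <- forwardsolve(t(ch), r_on)
    cc <- tapered_exponential(d_nn, cp) - crossprod(v)
    cc <- (cc + t(cc)) / 2
    diag(cc) <- pmax(diag(cc), 0) + prior$jitter
    out <- list(M = m, chol_cov = chol(cc))
    krig[[key]] <- out
    out
  }
  n_rec <- length(day)
  states <- samples$states
  draws <- matrix(NA_real_, n_rec, length(states))
  for (j in seq_along(states)) {
    s <- states[[j]]
    k1 <- krig_for(s$phi1)
    k2 <- krig_for(s$phi2)
    w1n <- drop(crossprod(k1$M, s$W1)) +
      drop(crossprod(k1$chol_cov, stats::rnorm(nrow(new_coords))))
    w2n <- drop(crossprod(k2$M, s$W2)) +
      drop(crossprod(k2$chol_cov, stats::rnorm(nrow(new_coords))))
    mu <- (s$gamma[1] + s$c_coef[1] * w1n[loc] + s$beta0[day]) +
      (s$gamma[2] + s$c_coef[2] * w1n[loc] + s$c_coef[3] * w2n[loc] +
         s$beta1[day]) * aod +
      drop(z %*% s$gamma[-(1:2)])
    draws[, j] <- if (include_resid) {
      mu + stats::rnorm(n_rec, 0, sqrt(s$sigma2))
    } else mu
  }
  draws
}

summarise_draws <- function(draws, prob = 0.9) {
  a <- (1 - prob) / 2
  q <- t(apply(draws, 1, stats::quantile, c(a, 1 - a), names = FALSE))
  data.frame(mean = rowMeans(draws),
             sd = apply(draws, 1, stats::sd),
             lo90 = q[, 1], hi90 = q[, 2])
}

#' Posterior predictive surfaces on the grid
#'
#' For every retained posterior state, the latent processes are kriged to
#' the cell centroids, the model mean is composed from the cell's AOD and
#' transformed covariates, and a residual draw is added; across states
#' this gives the posterior predictive distribution of daily PM2.5 in each
#' cell.  Cell-days without an AOD retrieval are not predicted and are
#' counted in \code{n_skipped_aod}.
#'
#' @param fit A \code{\link{downscale_fit}}.
#' @param grid Grid panel on the raw covariate scale (same dialect as the
#'   one fitted).
#' @param days Days to predict (defaults to all fitted days); days outside
#'   the fitted block are an error.
#' @param include_resid Include the residual term (predictive intervals,
#'   the default) or not (mean-surface intervals).
#' @return Object of class \code{prediction_cube}: a summary \code{table}
#'   (cell_id, x_km, y_km, day, mean, sd, lo90, hi90, n_models) and the
#'   per-record \code{draws} matrix.
#' @export
predict_cells <- function(fit, grid, days = NULL, include_resid = TRUE) {
  stopifnot(inherits(fit, "downscale_fit"))
  fit_days <- fit$samples$days
  if (is.null(days)) days <- fit_days
  if (!all(days %in% fit_days)) {
    stop("predict_cells: requested day(s) outside the fitted temporal block")
  }
  g <- grid[grid$day %in% days, , drop = FALSE]
  skipped <- sum(is.na(g$aod))
  g <- g[!is.na(g$aod), , drop = FALSE]
  if (nrow(g) == 0) stop("predict_cells: no cell-days with observed AOD")
  tr <- apply_transforms(g, fit$cov_spec, fitted = fit$transform)$panel
  covs <- fit$cov_spec$names
  if (fit$cov_spec$interaction_aod_temp) {
    tr$aod_temp <- tr$aod * tr[[fit$cov_spec$temp_name]]
    covs <- c(covs, "aod_temp")
  }
  cells <- unique(g[c("cell_id", "x_km", "y_km")])
  loc <- match(g$cell_id, cells$cell_id)
  day_idx <- match(g$day, fit_days)
  draws <- posterior_predict_records(
    fit$samples, as.matrix(cells[c("x_km", "y_km")]),
    loc, day_idx, g$aod, as.matrix(tr[covs]), include_resid)
  tab <- cbind(data.frame(cell_id = g$cell_id, x_km = g$x_km,
                          y_km = g$y_km, day = g$day),
               summarise_draws(draws), n_models = 1L)
  structure(list(table = tab, draws = draws,
                 n_skipped_aod = skipped),
            class = "prediction_cube")
}

#' @export
print.prediction_cube <- function(x, ...) {
  cat("prediction_cube:", nrow(x$table), "cell-days,",
      ncol(x$draws), "draws each;", x$n_skipped_aod,
      "cell-days skipped for missing AOD\n")
  invisible(x)
}

#' Predict PM2.5 surfaces from a fitted downscaling model
#'
#' @param object A \code{\link{downscale_fit}}.
#' @param grid Grid panel to predict on (raw covariate scale).
#' @param days Days to predict (default: all fitted days).
#' @param include_resid Predictive (TRUE) or mean-surface (FALSE) draws.
#' @param ... Unused.
#' @return A \code{prediction_cube}; see \code{\link{predict_cells}}.
#' @export
predict.downscale_fit <- function(object, grid, days = NULL,
                                  include_resid = TRUE, ...) {
  predict_cells(object, grid, days, include_resid)
}

#' Blend overlapping regional predictions into one surface
#'
#' Each buffered regional model predicts a superset of its core cells;
#' where several models claim the same cell-day their posterior draws are
#' pooled with equal weight before the mean, SD and interval are computed,
#' which both averages the overlapping predictions and propagates each
#' model's uncertainty.
#'
#' @param cubes List of \code{prediction_cube}s sharing cell/day indexing.
#' @return A blended \code{prediction_cube}; \code{n_models} records how
#'   many regional models contributed to each cell-day.
#' @export
blend_regions <- function(cubes) {
  stopifnot(length(cubes) >= 1,
            all(vapply(cubes, inherits, logical(1), "prediction_cube")))
  keys <- lapply(cubes, function(cb) paste(cb$table$cell_id, cb$table$day))
  all_keys <- unique(unlist(keys))
  first <- do.call(rbind, lapply(seq_along(cubes), function(i) {
    cbind(cubes[[i]]$table[c("cell_id", "x_km", "y_km", "day")],
          key = keys[[i]])
  }))
  first <- first[!duplicated(first$key), ]
  first <- first[match(all_keys, first$key), ]
  draws <- lapply(all_keys, function(k) {
    unlist(lapply(seq_along(cubes), function(i) {
      j <- which(keys[[i]] == k)
      if (length(j)) cubes[[i]]$draws[j[1], ] else NULL
    }))
  })
  n_models <- vapply(all_keys, function(k) {
    sum(vapply(keys, function(kk) k %in% kk, logical(1)))
  }, integer(1))
  n_draw <- vapply(draws, length, integer(1))
  if (length(unique(n_draw / n_models)) > 1) {
    warning("blend_regions: contributors carry different draw counts; ",
            "pooling treats every draw equally")
  }
  dmat_list <- draws
  # summaries per record (ragged draw counts allowed)
  a <- 0.05
  tab <- data.frame(
    cell_id = first$cell_id, x_km = first$x_km, y_km = first$y_km,
    day = first$day,
    mean = vapply(dmat_list, mean, numeric(1)),
    sd = vapply(dmat_list, stats::sd, numeric(1)),
    lo90 = vapply(dmat_list, stats::quantile, numeric(1), a, names = FALSE),
    hi90 = vapply(dmat_list, stats::quantile, numeric(1), 1 - a,
                  names = FALSE),
    n_models = n_models)
  structure(list(table = tab, draws = dmat_list,
                 n_skipped_aod = sum(vapply(cubes, function(cb)
                   cb$n_skipped_aod, numeric(1)))),
            class = "prediction_cube")
}

#' Aggregate daily predictions to a period mean surface
#'
#' The period mean is computed within each posterior draw over the cell's
#' predicted days in the period, then summarised across draws, so the SD
#' reflects the uncertainty of the period average rather than of a single
#' day.  Cell-days missing from the cube (no AOD retrieval) are omitted and
#' counted.
#'
#' @param cube A \code{prediction_cube} (daily).
#' @param days Days defining the period (default: all days in the cube).
#' @param label Period label for the output.
#' @return Data frame: cell_id, x_km, y_km, period, mean, sd, lo90, hi90,
#'   n_days_used.
#' @export
aggregate_time <- function(cube, days = NULL, label = "period") {
  stopifnot(inherits(cube, "prediction_cube"))
  tab <- cube$table
  if (is.null(days)) days <- sort(unique(tab$day))
  keep <- tab$day %in% days
  if (!any(keep)) stop("aggregate_time: no predicted days in the period")
  idx <- which(keep)
  by_cell <- split(idx, tab$cell_id[keep])
  rows <- lapply(names(by_cell), function(cid) {
    rs <- by_cell[[cid]]
    dr <- if (is.matrix(cube$draws)) {
      cube$draws[rs, , drop = FALSE]
    } else {
      do.call(rbind, cube$draws[rs])   # blended cubes: same cell => same length
    }
    per_draw <- colMeans(dr)
    q <- stats::quantile(per_draw, c(0.05, 0.95), names = FALSE)
    data.frame(cell_id = cid, x_km = tab$x_km[rs[1]], y_km = tab$y_km[rs[1]],
               period = label, mean = mean(per_draw), sd = stats::sd(per_draw),
               lo90 = q[1], hi90 = q[2], n_days_used = length(rs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
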