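#' Pair each monitor record with its containing grid cell
#'
#' Monitors are points; AOD and the ancillary covariates live on a regular
#' grid.  Each monitor-day record is joined to the AOD/covariates of the
#' cell whose footprint contains the monitor that day.  Cell footprints are
#' half-open squares \code{[x_lo, x_hi) x [y_lo, y_hi)} around the centroid,
#' so a monitor on a shared edge is assigned deterministically to exactly
#' one cell.  Records whose cell has no AOD retrieval that day are dropped
#' from the likelihood (no gap-filling) and counted.
#'
#' @param monitors Data frame: \code{site_id}, \code{x_km}, \code{y_km},
#'   \code{day}, \code{pm25}.
#' @param grid Data frame: \code{cell_id}, \code{x_km}, \code{y_km}
#'   (centroids), \code{day}, \code{aod}, covariate columns.
#' @param cell_km Grid cell size in km.
#' @return List with \code{table} (the joined analysis records),
#'   \code{n_dropped_aod} (records dropped for missing AOD) and
#'   \code{n_dropped_outside} (monitors outside the grid).
#' @export
align_monitors_to_cells <- function(monitors, grid, cell_km) {
  need_m <- c("site_id", "x_km", "y_km", "day", "pm25")
  if (!all(need_m %in% names(monitors))) {
    stop("align_monitors_to_cells: monitors need columns ",
         paste(need_m, collapse = ", "))
  }
  need_g <- c("cell_id", "x_km", "y_km", "day", "aod")
  if (!all(need_g %in% names(grid))) {
    stop("align_monitors_to_cells: grid needs columns ",
         paste(need_g, collapse = ", "))
  }
  cells <- unique(grid[c("cell_id", "x_km", "y_km")])
  # half-open containment: centroid c covers [c - h, c + h)
  h <- cell_km / 2
  cx <- cells$x_km
  cy <- cells$y_km
  cell_of <- vapply(seq_len(nrow(monitors)), function(i) {
    hit <- which(monitors$x_km[i] >= cx - h & monitors$x_km[i] < cx + h &
                 monitors$y_km[i] >= cy - h & monitors$y_km[i] < cy + h)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  outside <- is.na(cell_of)
  if (any(outside)) {
    warning("align_monitors_to_cells: ", sum(outside),
            " record(s) from monitors outside the grid excluded")
  }
  m <- monitors[!outside, , drop = FALSE]
  m$cell_id <- cells$cell_id[cell_of[!outside]]
  joined <- merge(m, grid[setdiff(names(grid), c("x_km", "y_km"))],
                  by = c("cell_id", "day"), sort = FALSE)
  no_aod <- is.na(joined$aod)
  list(table = joined[!no_aod, , drop = FALSE],
       n_dropped_aod = sum(no_aod),
       n_dropped_outside = sum(outside))
}

#' Assemble the analysis data for one regional model
#'
#' Packs an aligned analysis table into the indexed form the sampler uses:
#' response, AOD, covariate design matrix, and integer site/day indices
#' against a site coordinate table and a day range.
#'
#' @param table Aligned records from \code{\link{align_monitors_to_cells}}
#'   (already covariate-transformed).
#' @param covariates Character vector of covariate columns entering the
#'   linear fixed-effect term (interaction columns included).
#' @param sites Data frame \code{site_id}, \code{x_km}, \code{y_km} for all
#'   sites in the region (defaults to the sites present in \code{table}).
#' @param days Integer vector of the block's day indices (defaults to the
#'   full observed range).
#' @return Object of class \code{downscale_data}.
#' @export
downscale_data <- function(table, covariates, sites = NULL, days = NULL) {
  if (is.null(sites)) {
    sites <- unique(table[c("site_id", "x_km", "y_km")])
  }
  if (is.null(days)) days <- seq(min(table$day), max(table$day))
  if (!all(table$day %in% days)) {
    stop("downscale_data: records outside the day range")
  }
  miss <- setdiff(covariates, names(table))
  if (length(miss)) {
    stop("downscale_data: missing covariate column(s): ",
         paste(miss, collapse = ", "))
  }
  site_idx <- match(table$site_id, sites$site_id)
  if (anyNA(site_idx)) stop("downscale_data: record at unknown site")
  z <- as.matrix(table[covariates])
  if (any(!is.finite(z))) stop("downscale_data: non-finite covariate values")
  if (any(!is.finite(table$pm25)) )
    stop("downscale_data: non-finite pm25")
  structure(list(
    y = as.numeric(table$pm25),
    aod = as.numeric(table$aod),
    Z = z,
    site = site_idx,
    day = match(table$day, days),
    coords = as.matrix(sites[c("x_km", "y_km")]),
    site_ids = as.character(sites$site_id),
    days = days,
    n_sites = nrow(sites),
    n_days = length(days),
    covariates = covariates
  ), class = "downscale_data")
}

#' @export
print.downscale_data <- function(x, ...) {
  cat("downscale_data:", length(x$y), "records,", x$n_sites, "sites,",
      x$n_days, "days,", ncol(x$Z), "covariates\n")
  invisible(x)
}

#' Construct a model state
#'
#' One full parameter state of the downscaling model: fixed effects
#' \code{gamma} (global intercept, global AOD slope, then covariate
#' coefficients), coregionalization coefficients \code{c_coef = (c1,c2,c3)}
#' mapping the two latent unit-variance processes to the spatial intercept
#' (\code{c1 W1}) and spatial slope (\code{c2 W1 + c3 W2}), latent values
#' \code{W1, W2} at the sites, sum-to-zero daily series \code{beta0, beta1},
#' residual variance \code{sigma2}, random-walk precisions \code{tau0,
#' tau1}, and spatial ranges \code{phi1, phi2}.
#'
#' @param gamma Numeric vector (length 2 + number of covariates).
#' @param c_coef Length-3 numeric vector.
#' @param W1,W2 Latent process values at the sites.
#' @param beta0,beta1 Daily intercept/slope series.
#' @param sigma2,tau0,tau1,phi1,phi2 Positive scalars.
#' @return Object of class \code{model_state}.
#' @export
model_state <- function(gamma, c_coef, W1, W2, beta0, beta1,
                        sigma2, tau0, tau1, phi1, phi2) {
  if (length(c_coef) != 3L) stop("model_state: c_coef must have length 3")
  if (length(W1) != length(W2)) stop("model_state: W1, W2 length mismatch")
  if (length(beta0) != length(beta1)) {
    stop("model_state: beta0, beta1 length mismatch")
  }
  for (v in c(sigma2, tau0, tau1, phi1, phi2)) {
    if (!is.finite(v) || v <= 0) {
      stop("model_state: variances, precisions and ranges must be positive")
    }
  }
  structure(list(gamma = gamma, c_coef = c_coef, W1 = W1, W2 = W2,
                 beta0 = beta0, beta1 = beta1, sigma2 = sigma2,
                 tau0 = tau0, tau1 = tau1, phi1 = phi1, phi2 = phi2),
            class = "model_state")
}

#' Evaluate the model mean for each analysis record
#'
#' The mean response of record \code{i} at site \code{s} on day \code{t} is
#' \deqn{[\mu_0 + c_1 W_1(s) + \beta_0(t)] +
#'       [\mu_1 + c_2 W_1(s) + c_3 W_2(s) + \beta_1(t)] AOD_i + Z_i' \gamma}
#' i.e. a spatially and temporally varying intercept and AOD slope plus the
#' fixed covariate term.
#'
#' @param state A \code{\link{model_state}}.
#' @param data A \code{\link{downscale_data}}.
#' @return Numeric vector of means, one per record.
#' @export
evaluate_mean <- function(state, data) {
  p <- ncol(data$Z)
  if (length(state$gamma) != p + 2L) {
    stop("evaluate_mean: gamma length must be 2 + n covariates")
  }
  if (length(state$W1) != data$n_sites ||
      length(state$beta0) != data$n_days) {
    stop("evaluate_mean: state dimensions do not match data")
  }
  intercept <- state$gamma[1] + state$c_coef[1] * state$W1[data$site] +
    state$beta0[data$day]
  slope <- state$gamma[2] + state$c_coef[2] * state$W1[data$site] +
    state$c_coef[3] * state$W2[data$site] + state$beta1[data$day]
  drop(intercept + slope * data$aod + data$Z %*% state$gamma[-(1:2)])
}
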