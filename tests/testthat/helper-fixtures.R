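# Small shared fixtures, all generated in code.

# a compact simulated dataset + assembled analysis data
tiny_sim <- function(n_sites = 10, n_days = 5, seed = 42, ...) {
  simulate_dataset(sim_config(n_sites = n_sites, n_days = n_days,
                              grid_nx = 5, grid_ny = 4, seed = seed, ...))
}

tiny_analysis <- function(sim = tiny_sim(), prior = downscale_priors()) {
  ali <- align_monitors_to_cells(sim$monitors, sim$grid,
                                 sim$truth$config$cell_km)
  tr <- apply_transforms(ali$table, sim$cov_spec)
  downscale_data(tr$panel, sim$cov_spec$names)
}

# a dispersed random model state consistent with `data`
random_state <- function(data, prior = downscale_priors(), seed = 7) {
  set.seed(seed)
  p <- ncol(data$Z)
  grid <- prior$phi_grid
  model_state(gamma = rnorm(p + 2), c_coef = rnorm(3),
              W1 = rnorm(data$n_sites), W2 = rnorm(data$n_sites),
              beta0 = local({b <- rnorm(data$n_days); b - mean(b)}),
              beta1 = local({b <- rnorm(data$n_days); b - mean(b)}),
              sigma2 = runif(1, 0.5, 2), tau0 = runif(1, 0.5, 2),
              tau1 = runif(1, 0.5, 2),
              phi1 = grid[sample.int(length(grid), 1)],
              phi2 = grid[sample.int(length(grid), 1)])
}

# random analysis data built directly (no file round trip): every site-day
# pair observed with probability p_obs
make_data <- function(n_sites = 10, n_days = 5, p_obs = 0.8, seed = 1,
                      extent_km = 120) {
  set.seed(seed)
  sites <- data.frame(site_id = sprintf("s%02d", seq_len(n_sites)),
                      x_km = runif(n_sites, 0, extent_km),
                      y_km = runif(n_sites, 0, extent_km))
  recs <- expand.grid(site = seq_len(n_sites), day = seq_len(n_days))
  recs <- recs[runif(nrow(recs)) < p_obs, ]
  tab <- data.frame(site_id = sites$site_id[recs$site],
                    x_km = sites$x_km[recs$site],
                    y_km = sites$y_km[recs$site],
                    day = recs$day,
                    pm25 = rnorm(nrow(recs), 10, 3),
                    aod = rlnorm(nrow(recs), -2, 0.8),
                    z1 = rnorm(nrow(recs)), z2 = rnorm(nrow(recs)))
  downscale_data(tab, c("z1", "z2"), sites = sites,
                 days = seq_len(n_days))
}

# maximum density-ratio discrepancy across every Gibbs block: the
# difference of full-conditional log densities at two candidate values
# must equal the difference of joint log densities with all else fixed
check_density_ratios <- function(data, state, prior, seed = 99) {
  set.seed(seed)
  cache <- downscaler:::build_chain_cache(data, prior)
  jd <- function(st) downscaler:::log_joint(st, data, prior, cache)
  disc <- c()
  gauss_block <- function(name, fc, set_fun, x1, x2) {
    lhs <- logdens_prec(x1, fc$mean, fc$prec) -
      logdens_prec(x2, fc$mean, fc$prec)
    rhs <- jd(set_fun(state, x1)) - jd(set_fun(state, x2))
    disc[[name]] <<- abs(lhs - rhs)
  }
  p <- length(state$gamma)
  gauss_block("gamma", downscaler:::fc_gamma(state, data, prior, cache),
              function(s, x) { s$gamma <- x; s }, rnorm(p), rnorm(p))
  m <- data$n_sites
  gauss_block("W", downscaler:::fc_W(state, data, prior, cache),
              function(s, x) { s$W1 <- x[1:m]; s$W2 <- x[m + 1:m]; s },
              rnorm(2 * m), rnorm(2 * m))
  gauss_block("c", downscaler:::fc_c(state, data, prior, cache),
              function(s, x) { s$c_coef <- x; s }, rnorm(3), rnorm(3))
  k <- cache$K
  for (which in 0:1) {
    fct <- downscaler:::fc_temporal(state, data, prior, cache, which)
    b1 <- drop(k %*% rnorm(ncol(k))); b2 <- drop(k %*% rnorm(ncol(k)))
    nm <- paste0("beta", which)
    lhs <- logdens_prec(drop(crossprod(k, b1)), fct$mean, fct$prec) -
      logdens_prec(drop(crossprod(k, b2)), fct$mean, fct$prec)
    set_fun <- function(s, x) { s[[nm]] <- x; s }
    rhs <- jd(set_fun(state, b1)) - jd(set_fun(state, b2))
    disc[[nm]] <- abs(lhs - rhs)
  }
  fs <- downscaler:::fc_sigma2(state, data, prior, cache)
  s1 <- runif(1, 0.5, 2); s2 <- runif(1, 2, 5)
  lhs <- (-(fs$shape + 1) * log(s1) - fs$rate / s1) -
    (-(fs$shape + 1) * log(s2) - fs$rate / s2)
  rhs <- jd({st <- state; st$sigma2 <- s1; st}) -
    jd({st <- state; st$sigma2 <- s2; st})
  disc[["sigma2"]] <- abs(lhs - rhs)
  for (which in 0:1) {
    ft <- downscaler:::fc_tau(state, data, prior, cache, which)
    t1 <- runif(1, 0.5, 2); t2 <- runif(1, 2, 5)
    lhs <- ((ft$shape - 1) * log(t1) - ft$rate * t1) -
      ((ft$shape - 1) * log(t2) - ft$rate * t2)
    nm <- paste0("tau", which)
    rhs <- jd({st <- state; st[[nm]] <- t1; st}) -
      jd({st <- state; st[[nm]] <- t2; st})
    disc[[nm]] <- abs(lhs - rhs)
  }
  for (which in 1:2) {
    fp <- downscaler:::fc_phi(state, data, prior, cache, which)
    i1 <- 1L; i2 <- length(fp$candidates)
    lhs <- log(fp$prob[i1]) - log(fp$prob[i2])
    nm <- paste0("phi", which)
    rhs <- jd({st <- state; st[[nm]] <- fp$candidates[i1]; st}) -
      jd({st <- state; st[[nm]] <- fp$candidates[i2]; st})
    disc[[nm]] <- abs(lhs - rhs)
  }
  unlist(disc)
}

# log of a multivariate normal density given mean and precision
logdens_prec <- function(x, mean, prec) {
  r <- x - mean
  0.5 * determinant(prec)$modulus - 0.5 * drop(crossprod(r, prec %*% r)) -
    0.5 * length(x) * log(2 * pi)
}
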