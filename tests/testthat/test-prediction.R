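# a small fitted model shared across prediction tests
small_fit <- function(seed = 71, n_states = 10) {
  sim <- tiny_sim(n_sites = 12, n_days = 6, seed = seed,
                  aod_coverage = 0.8)
  fit <- downscale(sim$monitors, sim$grid, sim$cov_spec, cell_km = 12,
                   control = chain_control(n_iter = 2 * n_states + 20,
                                           n_burn = 20, thin = 2,
                                           seed = seed))
  list(sim = sim, fit = fit)
}

test_that("cell prediction matches a brute-force per-state oracle", {
  sf <- small_fit()
  fit <- sf$fit
  grid <- sf$sim$grid
  days <- fit$samples$days
  # package path
  set.seed(500)
  cube <- predict_cells(fit, grid)
  # brute-force oracle: per retained state, krige with explicit dense
  # partitioned-covariance algebra and recompose the mean, consuming the
  # RNG in the same order (W1 draw, W2 draw, residual draw per state)
  g <- grid[!is.na(grid$aod), , drop = FALSE]
  tr <- apply_transforms(g, fit$cov_spec, fitted = fit$transform)$panel
  cells <- unique(g[c("cell_id", "x_km", "y_km")])
  loc <- match(g$cell_id, cells$cell_id)
  prior <- fit$samples$prior
  obs_xy <- fit$samples$coords
  new_xy <- as.matrix(cells[c("x_km", "y_km")])
  zmat <- as.matrix(tr[fit$cov_spec$names])
  set.seed(500)
  oracle <- matrix(NA_real_, nrow(g), length(fit$samples$states))
  for (j in seq_along(fit$samples$states)) {
    s <- fit$samples$states[[j]]
    kr <- function(phi, w) {
      cp <- spatial_cov_params(phi, prior$taper_km, prior$taper)
      r_oo <- tapered_exponential(pairwise_distances(obs_xy), cp) +
        diag(prior$jitter, nrow(obs_xy))
      r_no <- tapered_exponential(pairwise_distances(new_xy, obs_xy), cp)
      r_nn <- tapered_exponential(pairwise_distances(new_xy), cp)
      mu <- r_no %*% solve(r_oo, w)
      cv <- r_nn - r_no %*% solve(r_oo, t(r_no))
      cv <- (cv + t(cv)) / 2
      diag(cv) <- pmax(diag(cv), 0) + prior$jitter
      drop(mu) + drop(crossprod(chol(cv), rnorm(nrow(new_xy))))
    }
    w1n <- kr(s$phi1, s$W1)
    w2n <- kr(s$phi2, s$W2)
    t_idx <- match(g$day, days)
    mu <- (s$gamma[1] + s$c_coef[1] * w1n[loc] + s$beta0[t_idx]) +
      (s$gamma[2] + s$c_coef[2] * w1n[loc] + s$c_coef[3] * w2n[loc] +
         s$beta1[t_idx]) * g$aod +
      drop(zmat %*% s$gamma[-(1:2)])
    oracle[, j] <- mu + rnorm(nrow(g), 0, sqrt(s$sigma2))
  }
  expect_equal(cube$draws, oracle, tolerance = 1e-6)
  expect_equal(cube$table$mean, rowMeans(oracle), tolerance = 1e-6)
})

test_that("a degenerate chain with vanishing residual variance gives zero predictive SD", {
  sf <- small_fit(seed = 72, n_states = 3)
  fit <- sf$fit
  # collapse the chain to one repeated state with ~zero noise and no latent
  s <- fit$samples$states[[1]]
  s$sigma2 <- 1e-20
  s$c_coef <- c(0, 0, 0)
  fit$samples$states <- list(s, s, s, s)
  cube <- predict_cells(fit, sf$sim$grid)
  expect_lt(max(cube$table$sd), 1e-8)
  expect_lt(max(cube$table$hi90 - cube$table$lo90), 1e-8)
})

test_that("prediction refuses days outside the fitted block and skips missing AOD", {
  sf <- small_fit(seed = 73, n_states = 3)
  expect_error(predict_cells(sf$fit, sf$sim$grid, days = 999),
               "temporal block")
  g <- sf$sim$grid
  n_na <- sum(is.na(g$aod[g$day %in% sf$fit$samples$days]))
  cube <- predict_cells(sf$fit, g)
  expect_equal(cube$n_skipped_aod, n_na)
  expect_false(any(is.na(cube$table$mean)))
})

fake_cube <- function(tab, draws) {
  structure(list(table = tab, draws = draws, n_skipped_aod = 0),
            class = "prediction_cube")
}

test_that("blending pools draws with equal weight across claiming regions", {
  tab <- data.frame(cell_id = "c1", x_km = 5, y_km = 5, day = 1,
                    mean = NA, sd = NA, lo90 = NA, hi90 = NA, n_models = 1L)
  cube_a <- fake_cube(tab, matrix(c(2, 4), 1))
  cube_b <- fake_cube(tab, matrix(c(6, 8), 1))
  blended <- blend_regions(list(cube_a, cube_b))
  expect_equal(blended$table$mean, 5)           # pooled {2,4,6,8}
  expect_equal(blended$table$n_models, 2L)
  # single contributor: identity
  one <- blend_regions(list(cube_a))
  expect_equal(one$table$mean, 3)
  expect_equal(one$table$n_models, 1L)
  # identical draws: idempotent summaries
  twin <- blend_regions(list(cube_a, cube_a))
  expect_equal(twin$table$mean, one$table$mean)
  expect_equal(twin$table$sd, sd(c(2, 4, 2, 4)))
})

test_that("the pooled 90% interval lies within the union of contributor intervals", {
  set.seed(74)
  for (rep in 1:10) {
    tab <- data.frame(cell_id = "c1", x_km = 0, y_km = 0, day = 1,
                      mean = NA, sd = NA, lo90 = NA, hi90 = NA,
                      n_models = 1L)
    d1 <- matrix(rnorm(200, mean = runif(1, -2, 2)), 1)
    d2 <- matrix(rnorm(200, mean = runif(1, -2, 2)), 1)
    b <- blend_regions(list(fake_cube(tab, d1), fake_cube(tab, d2)))
    lo_union <- min(quantile(d1, 0.05), quantile(d2, 0.05))
    hi_union <- max(quantile(d1, 0.95), quantile(d2, 0.95))
    expect_gte(b$table$lo90, lo_union - 1e-10)
    expect_lte(b$table$hi90, hi_union + 1e-10)
  }
})

test_that("cells claimed by different regions keep their own predictions", {
  tab1 <- data.frame(cell_id = c("c1", "c2"), x_km = c(5, 15), y_km = 5,
                     day = 1, mean = NA, sd = NA, lo90 = NA, hi90 = NA,
                     n_models = 1L)
  tab2 <- tab1[2, ]
  b <- blend_regions(list(fake_cube(tab1, rbind(c(1, 3), c(10, 12))),
                          fake_cube(tab2, matrix(c(20, 22), 1))))
  expect_equal(b$table$mean[b$table$cell_id == "c1"], 2)
  expect_equal(b$table$mean[b$table$cell_id == "c2"], 16)
  expect_equal(b$table$n_models, c(1L, 2L))
})

test_that("temporal aggregation equals the explicit two-stage oracle", {
  set.seed(75)
  n_days <- 4; n_draws <- 30
  tab <- data.frame(cell_id = rep(c("c1", "c2"), each = n_days),
                    x_km = rep(c(5, 15), each = n_days), y_km = 5,
                    day = rep(1:n_days, 2),
                    mean = NA, sd = NA, lo90 = NA, hi90 = NA, n_models = 1L)
  draws <- matrix(rnorm(2 * n_days * n_draws, 10, 3), 2 * n_days)
  cube <- fake_cube(tab, draws)
  agg <- aggregate_time(cube, label = "annual")
  for (cid in c("c1", "c2")) {
    rows <- which(tab$cell_id == cid)
    per_draw <- colMeans(draws[rows, ])      # stage 1: average within draw
    expect_equal(agg$mean[agg$cell_id == cid], mean(per_draw),
                 tolerance = 1e-10)
    expect_equal(agg$sd[agg$cell_id == cid], sd(per_draw),
                 tolerance = 1e-10)
  }
  expect_equal(agg$n_days_used, c(4L, 4L))
  # single-day period reduces to the daily cube
  agg1 <- aggregate_time(cube, days = 2)
  for (cid in c("c1", "c2")) {
    r <- which(tab$cell_id == cid & tab$day == 2)
    expect_equal(agg1$mean[agg1$cell_id == cid], mean(draws[r, ]))
  }
  # a period with no predicted days is an error
  expect_error(aggregate_time(cube, days = 99), "no predicted days")
  # constant field over time: period-mean SD shrinks per the per-draw oracle
  const <- fake_cube(tab, matrix(rep(rnorm(n_draws, 10, 2), each = 2 * n_days),
                                 2 * n_days))
  aggc <- aggregate_time(const)
  expect_equal(aggc$sd[1], sd(const$draws[1, ]), tolerance = 1e-10)
})
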