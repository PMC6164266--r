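test_that("every full conditional satisfies the density-ratio identity", {
  d <- make_data(n_sites = 8, n_days = 5, seed = 51)
  prior <- downscale_priors()
  for (s in 1:3) {
    st <- random_state(d, prior, seed = s)
    disc <- check_density_ratios(d, st, prior, seed = 100 + s)
    expect_lt(max(disc), 1e-8)
  }
})

test_that("an overwhelming prior pins the fixed effects at zero", {
  d <- make_data(seed = 52)
  prior <- downscale_priors(gamma_sd = 1e-8)
  st <- random_state(d, prior)
  set.seed(1)
  got <- update_gamma(st, d, prior)
  expect_lt(max(abs(got$gamma)), 1e-4)
})

test_that("with diffuse prior and no random effects the gamma conditional is the OLS solution", {
  d <- make_data(seed = 53)
  prior <- downscale_priors(gamma_sd = 1e7)
  st <- random_state(d, prior)
  st$c_coef <- c(0, 0, 0)
  st$W1[] <- 0; st$W2[] <- 0; st$beta0[] <- 0; st$beta1[] <- 0
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_gamma(st, d, prior, cache)
  x <- cbind(1, d$aod, d$Z)
  ols <- solve(crossprod(x), crossprod(x, d$y))
  expect_equal(fc$mean, drop(ols), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("repeated gamma draws reproduce the analytic full conditional", {
  d <- make_data(seed = 54)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_gamma(st, d, prior, cache)
  set.seed(2)
  n_mc <- 4000
  draws <- t(replicate(n_mc, update_gamma(st, d, prior, cache)$gamma))
  cov_true <- solve(fc$prec)
  se_mean <- sqrt(diag(cov_true) / n_mc)
  expect_true(all(abs(colMeans(draws) - fc$mean) < 3 * se_mean))
  # variances: SE of a normal variance estimate is var * sqrt(2/(n-1))
  v <- apply(draws, 2, var)
  expect_true(all(abs(v - diag(cov_true)) <
                    3 * diag(cov_true) * sqrt(2 / (n_mc - 1))))
})

test_that("with zero coregionalization the latent conditional is its prior", {
  d <- make_data(n_sites = 6, seed = 55)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  st$c_coef <- c(0, 0, 0)
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_W(st, d, prior, cache)
  m <- d$n_sites
  expect_equal(fc$mean, rep(0, 2 * m))
  expect_equal(fc$prec[1:m, 1:m],
               downscaler:::corr_for_phi(cache, prior, st$phi1)$inv)
  expect_equal(fc$prec[1:m, m + 1:m], matrix(0, m, m))
})

test_that("a single informative record gives the scalar normal-normal posterior for W1", {
  tab <- data.frame(site_id = "a", x_km = 0, y_km = 0, day = 1,
                    pm25 = 12, aod = 0.4, z1 = 0.3)
  d <- downscale_data(tab, "z1", days = 1:2)
  prior <- downscale_priors(jitter = 0)
  st <- random_state(d, prior)
  st$c_coef <- c(1.5, 2, 0)     # c3 = 0 decouples W2
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_W(st, d, prior, cache)
  r <- d$y - sum(cbind(1, d$aod, d$Z) * st$gamma) - st$beta0[1] -
    st$beta1[1] * d$aod
  a <- 1.5 + 2 * 0.4
  prec <- 1 + a^2 / st$sigma2          # unit prior variance at one site
  expect_equal(fc$prec[1, 1], prec)
  expect_equal(fc$mean[1], (a * r / st$sigma2) / prec, ignore_attr = TRUE)
  # W2 keeps its prior
  expect_equal(fc$mean[2], 0)
  expect_equal(fc$prec[2, 2], 1)
})

test_that("sites beyond the taper have independent latent conditionals", {
  tab <- data.frame(site_id = c("a", "b"), x_km = c(0, 5000), y_km = 0,
                    day = 1, pm25 = c(10, 11), aod = c(0.1, 0.2),
                    z1 = c(0, 1))
  d <- downscale_data(tab, "z1", days = 1:2)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_W(st, d, prior, cache)
  # no cross-site coupling anywhere in the 4x4 precision
  expect_equal(fc$prec[1, 2], 0)
  expect_equal(fc$prec[3, 4], 0)
  expect_equal(fc$prec[1, 4], 0)
  expect_equal(fc$prec[2, 3], 0)
})

test_that("with zero latent processes the coregionalization conditional is its prior", {
  d <- make_data(seed = 56)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  st$W1[] <- 0; st$W2[] <- 0
  fc <- downscaler:::fc_c(st, d, prior,
                          downscaler:::build_chain_cache(d, prior))
  expect_equal(fc$mean, rep(0, 3))
  expect_equal(fc$prec, diag(1 / prior$gamma_sd^2, 3))
})

test_that("the likelihood is invariant under the latent sign symmetry", {
  d <- make_data(seed = 57)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  flipped <- st
  flipped$W1 <- -st$W1
  flipped$c_coef[1:2] <- -st$c_coef[1:2]
  expect_equal(evaluate_mean(flipped, d), evaluate_mean(st, d),
               tolerance = 1e-12)
  # and the update enforces c1 >= 0
  set.seed(8)
  for (i in 1:5) {
    st2 <- update_coregionalization(random_state(d, prior, seed = i), d,
                                    prior)
    expect_gte(st2$c_coef[1], 0)
  }
})

test_that("temporal series are smoothed across gaps, vanish as tau grows, and stay sum-zero", {
  # observations on days 1 and 3 only; day 2 is filled by smoothing
  tab <- data.frame(site_id = "a", x_km = 0, y_km = 0, day = c(1, 3),
                    pm25 = c(8, 12), aod = 0, z1 = 0)
  d <- downscale_data(tab, "z1", days = 1:3)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  st$c_coef[] <- 0; st$W1[] <- 0; st$W2[] <- 0
  st$gamma[] <- 0; st$beta1[] <- 0
  cache <- downscaler:::build_chain_cache(d, prior)
  fc <- downscaler:::fc_temporal(st, d, prior, cache, 0)
  b <- fc$mean_beta
  expect_equal(sum(b), 0, tolerance = 1e-10)
  # independent oracle for the constrained smoothing mean: solve the KKT
  # system of (prior precision + likelihood) under the sum-zero constraint
  w <- c(1, 0, 1) / st$sigma2
  l <- c(st$tau0 * 0, 0, 0) + c(8, 0, 12) / st$sigma2
  p_full <- st$tau0 * rw1_precision(3) + diag(w)
  kkt <- rbind(cbind(p_full, 1), c(1, 1, 1, 0))
  sol <- solve(kkt, c(l, 0))
  expect_equal(b, sol[1:3], tolerance = 1e-8)
  # the smoothed gap day interpolates the increments: given its neighbours
  # the RW1 conditional puts it at their midpoint
  expect_equal(b[2], (b[1] + b[3]) / 2 - sol[4] / (2 * st$tau0),
               tolerance = 1e-8)
  # enormous increment precision forces the series to zero
  st_inf <- st; st_inf$tau0 <- 1e12
  fc_inf <- downscaler:::fc_temporal(st_inf, d, prior, cache, 0)
  expect_lt(max(abs(fc_inf$mean_beta)), 1e-6)
  # no observations at all: prior draw, still sum-zero and mean-zero
  tab0 <- tab; tab0$day <- c(1, 2)
  d0 <- downscale_data(tab0, "z1", days = 1:5)
  st0 <- random_state(d0, prior)
  st0$c_coef[] <- 0
  cache0 <- downscaler:::build_chain_cache(d0, prior)
  fc0 <- downscaler:::fc_temporal(st0, d0, prior, cache0, 1)   # aod = 0: no info
  expect_equal(fc0$mean_beta, rep(0, 5), tolerance = 1e-10)
  set.seed(9)
  st0b <- update_temporal(st0, d0, prior, cache0)
  expect_equal(sum(st0b$beta1), 0, tolerance = 1e-10)
})

test_that("variance conditionals reduce to their priors in degenerate cases", {
  d <- make_data(seed = 58)
  prior <- downscale_priors()
  st <- random_state(d, prior)
  cache <- downscaler:::build_chain_cache(d, prior)
  # perfect fit: make the response equal the mean
  d2 <- d; d2$y <- evaluate_mean(st, d)
  fs <- downscaler:::fc_sigma2(st, d2, prior, cache)
  expect_equal(fs$rate, prior$sigma2_rate, tolerance = 1e-8)
  expect_equal(fs$shape, prior$sigma2_shape + length(d$y) / 2)
  # constant daily series: no increments, rate unchanged, rank increment only
  st$beta0[] <- 0
  ft <- downscaler:::fc_tau(st, d, prior, cache, 0)
  expect_equal(ft$rate, prior$tau_rate)
  expect_equal(ft$shape, prior$tau_shape + (d$n_days - 1) / 2)
})

test_that("the range update normalises, respects a one-point grid, and recovers the truth", {
  d <- make_data(n_sites = 100, n_days = 2, seed = 59, extent_km = 300)
  prior1 <- downscale_priors(phi_grid = 75)
  st <- random_state(d, prior1)
  st$phi1 <- 75; st$phi2 <- 75
  got <- update_phi(st, d, prior1)
  expect_equal(got$phi1, 75)
  prior3 <- downscale_priors(phi_grid = c(25, 50, 100))
  cache3 <- downscaler:::build_chain_cache(d, prior3)
  st$phi1 <- 50
  fc <- downscaler:::fc_phi(st, d, prior3, cache3, 1)
  expect_equal(sum(fc$prob), 1, tolerance = 1e-12)
  # recovery: W drawn with range 50 should put the posterior mode at 50
  cp <- spatial_cov_params(50, prior3$taper_km)
  r <- tapered_exponential(pairwise_distances(d$coords), cp)
  ch <- chol(r + diag(1e-8, nrow(r)))
  set.seed(60)
  hits <- 0
  for (rep in 1:20) {
    stw <- st
    stw$W1 <- drop(crossprod(ch, rnorm(nrow(r))))
    fcw <- downscaler:::fc_phi(stw, d, prior3, cache3, 1)
    if (which.max(fcw$prob) == 2) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("chains are reproducible given a seed and keep variances positive", {
  d <- make_data(seed = 61)
  ctl <- chain_control(n_iter = 60, n_burn = 20, thin = 2, seed = 4)
  s1 <- run_chain(d, control = ctl)
  s2 <- run_chain(d, control = ctl)
  expect_identical(as_draw_matrix(s1), as_draw_matrix(s2))
  expect_equal(length(s1$states), 20)
  dm <- as_draw_matrix(s1)
  expect_true(all(dm[, c("sigma2", "tau0", "tau1")] > 0))
})

test_that("successive-conditional simulation preserves the prior of the fixed effects", {
  # Geweke-style calibration: alternately draw the state from its full
  # conditionals given y and redraw y from the likelihood; the marginal
  # of every parameter must stay at its prior.  Informative priors keep
  # the check tight on a tiny instance.
  d <- make_data(n_sites = 4, n_days = 3, seed = 62)
  prior <- downscale_priors(gamma_sd = 2, sigma2_shape = 5, sigma2_rate = 5,
                            tau_shape = 5, tau_rate = 5, phi_grid = 50)
  cache <- downscaler:::build_chain_cache(d, prior)
  st <- random_state(d, prior)
  st$sigma2 <- 1
  set.seed(63)
  n_iter <- 5000
  g1 <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    st <- update_gamma(st, d, prior, cache)
    st <- update_latent_W(st, d, prior, cache)
    st <- update_coregionalization(st, d, prior, cache)
    st <- update_temporal(st, d, prior, cache)
    st <- update_variances(st, d, prior, cache)
    d$y <- evaluate_mean(st, d) + rnorm(length(d$y), 0, sqrt(st$sigma2))
    g1[i] <- st$gamma[1]
  }
  # prior of gamma[1] is N(0, 2^2); allow for autocorrelation in the SE
  n_eff <- n_iter / (2 * sum(acf(g1, plot = FALSE, lag.max = 50)$acf) - 1)
  expect_lt(abs(mean(g1)), 5 * 2 / sqrt(max(n_eff, 10)))
  expect_gt(sd(g1), 2 * 0.8)
  expect_lt(sd(g1), 2 * 1.2)
})
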