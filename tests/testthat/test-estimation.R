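# a small observation set built by hand around a short simulation
toy_obs <- function(noise_frac = 0.01, seed = 4, times = c(0, 24, 48)) {
  cfg <- generator_config("control", times = times, n_replicates = 2,
                          noise_frac = noise_frac, truncate = FALSE,
                          seed = seed, control = quick_solver)
  generate_observations(cfg)
}

test_that("log-likelihood matches a brute-force reimplementation", {
  obs <- toy_obs()
  p <- ctrl_params
  ll <- ferm_loglik(obs, p, control = quick_solver)
  # independent loop: simulate, then accumulate Gaussian terms one by one
  tr <- simulate_fermentation(p, attr(obs, "y0"),
                              sort(unique(obs$time_hr)),
                              control = quick_solver)
  rng <- tapply(obs$value, obs$state, function(v) diff(range(v)))
  brute <- 0
  for (i in seq_len(nrow(obs))) {
    pred <- tr[[obs$state[i]]][match(obs$time_hr[i], tr$time_hr)]
    s <- max(obs$sd[i], 0.005 * rng[[obs$state[i]]])
    brute <- brute - 0.5 * ((obs$value[i] - pred) / s)^2 - log(s)
  }
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("doubling all SDs changes the log-likelihood by the analytic amount", {
  obs <- toy_obs()
  p <- ctrl_params
  ll1 <- ferm_loglik(obs, p, control = quick_solver, sd_floor_frac = 0)
  obs2 <- obs
  obs2$sd <- obs$sd * 2
  ll2 <- ferm_loglik(obs2, p, control = quick_solver, sd_floor_frac = 0)
  # quadratic terms shrink 4x, each log sigma grows by log 2
  n <- nrow(obs)
  quad1 <- ll1 + sum(log(obs$sd))
  expect_equal(ll2, quad1 / 4 - sum(log(obs$sd)) - n * log(2),
               tolerance = 1e-10)
})

test_that("the generating parameters beat 2x-perturbed sets on noiseless data", {
  obs <- toy_obs(noise_frac = 0, seed = 1, times = obs_times)
  ll_truth <- ferm_loglik(obs, ctrl_params, control = quick_solver)
  set.seed(31)
  for (i in 1:10) {
    v <- unclass(ctrl_params)
    j <- sample(15, 1)
    v[j] <- v[j] * sample(c(0.5, 2), 1)
    expect_lt(ferm_loglik(obs, as_ferm_params(v), control = quick_solver),
              ll_truth)
  }
})

test_that("solver failure yields -Inf rather than an error", {
  obs <- toy_obs()
  p <- ferm_params(base = ctrl_params, k1 = 5e4, k12 = 4e4)
  ll <- ferm_loglik(obs, p,
                    control = solver_config(n_elements = 1, order = 2,
                                            max_newton = 4))
  expect_identical(ll, -Inf)
})

test_that("least squares is stationary at the truth on noiseless data", {
  obs <- toy_obs(noise_frac = 0, seed = 1, times = obs_times)
  ls <- least_squares_fit(obs, ctrl_params, control = quick_solver)
  expect_equal(unclass(ls)[1:15], unclass(ctrl_params)[1:15],
               tolerance = 1e-6)
  expect_lt(attr(ls, "deviance"), 1e-10)
})

test_that("least squares recovers the truth from a perturbed start", {
  obs <- toy_obs(noise_frac = 0, seed = 1, times = obs_times)
  set.seed(8)
  start <- unclass(ctrl_params)
  start[1:15] <- start[1:15] * runif(15, 0.8, 1.2)
  ls <- least_squares_fit(obs, as_ferm_params(start),
                          control = quick_solver)
  expect_lt(attr(ls, "deviance"), 1e-8)
  # the well-identified constants return to the generating values
  for (nm in c("k1", "k3", "k6", "k7", "k9", "k11", "cor_bio", "cor_X"))
    expect_equal(unclass(ls)[[nm]], unclass(ctrl_params)[[nm]],
                 tolerance = 1e-3, label = nm)
})

test_that("a short chain with narrow priors recovers noiseless truth", {
  obs <- toy_obs(noise_frac = 0, seed = 1, times = obs_times)
  fit <- suppressWarnings(
    ferm_fit(obs, n_draws = 1500, prior_factor = 1.05, seed = 42,
             init_ls = FALSE, control = quick_solver))
  est <- unclass(fit$point)[1:15]
  expect_true(all(abs(est / unclass(ctrl_params)[1:15] - 1) < 0.02))
  expect_false(fit$accepted_run) # below the 10000-draw threshold
})

test_that("two sampler seeds agree within Monte-Carlo error", {
  obs <- toy_obs(noise_frac = 0.01, seed = 9, times = obs_times)
  f1 <- suppressWarnings(ferm_fit(obs, n_draws = 1200, prior_factor = 1.5,
                                  seed = 1, init_ls = FALSE,
                                  control = quick_solver))
  f2 <- suppressWarnings(ferm_fit(obs, n_draws = 1200, prior_factor = 1.5,
                                  seed = 2, init_ls = FALSE,
                                  control = quick_solver))
  # agreement within the posterior spread
  spread <- f1$ci[2, ] - f1$ci[1, ]
  expect_true(all(abs(unclass(f1$point)[f1$free] -
                        unclass(f2$point)[f2$free]) < pmax(spread, 1e-8)))
  # and a fit is reproducible given the same seed
  f3 <- suppressWarnings(ferm_fit(obs, n_draws = 1200, prior_factor = 1.5,
                                  seed = 1, init_ls = FALSE,
                                  control = quick_solver))
  expect_identical(f1$draws, f3$draws)
})

test_that("fit object methods are coherent", {
  obs <- toy_obs(noise_frac = 0.01, seed = 9, times = obs_times)
  fit <- suppressWarnings(ferm_fit(obs, n_draws = 600, prior_factor = 1.5,
                                   seed = 5, init_ls = FALSE,
                                   control = quick_solver))
  expect_named(coef(fit), fermkin:::.param_names)
  s <- summary(fit)
  expect_true(all(s$param$lower95 <= s$param$estimate &
                    s$param$estimate <= s$param$upper95))
  pr <- predict(fit, times = obs_times)
  expect_s3_class(pr, "ferm_traj")
  r <- residuals(fit)
  expect_length(r, nrow(obs))
  expect_lt(mean(abs(r)), 5) # standardized residuals at noise scale
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "ferm_obs")
  expect_identical(dim(as.data.frame(sim[[1]]))[1], nrow(obs))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("chi-squared statistic, dof and decisions follow the tables", {
  obs <- toy_obs(noise_frac = 0, seed = 1, times = obs_times)
  obs$sd <- 0.01
  truth_traj <- attr(obs, "truth_traj")
  g <- chi_squared_gof(obs, truth_traj)
  expect_equal(g$statistic, rep(0, 6), tolerance = 1e-10)
  expect_true(all(g$pass))
  expect_equal(g$dof, rep(6, 6))
  expect_equal(g$critical, rep(qchisq(0.95, 6), 6))

  # a single 5-sigma outlier on dof = 4 must reject: 25 > 9.488
  o1 <- obs[obs$state == "y4" & obs$replicate == 1, ]
  o1$value <- truth_traj$y4[match(o1$time_hr, truth_traj$time_hr)]
  o1$value[3] <- o1$value[3] + 5 * 0.01
  obs1 <- obs
  obs1[obs1$state == "y4" & obs1$replicate == 1, ] <- o1
  obs1 <- obs1[obs1$replicate == 1, ]
  g1 <- chi_squared_gof(obs1, truth_traj, n_params_per_state = 2)
  expect_equal(g1$dof, rep(4, 6))
  expect_gte(g1$statistic[g1$state == "y4"], 25 - 1e-8)
  expect_equal(qchisq(0.95, 4), 9.4877, tolerance = 1e-4)
  expect_false(g1$pass[g1$state == "y4"])

  # nonpositive dof is refused with advice
  expect_error(chi_squared_gof(obs, truth_traj, n_params_per_state = 6),
               "pool")
  # zero SDs are refused
  obs0 <- obs; obs0$sd <- 0
  expect_error(chi_squared_gof(obs0, truth_traj), "positive")
})

test_that("fit serialisation writes point, intervals and chi-squared table", {
  obs <- toy_obs(noise_frac = 0.01, seed = 9, times = obs_times)
  fit <- suppressWarnings(ferm_fit(obs, n_draws = 400, prior_factor = 1.5,
                                   seed = 5, init_ls = FALSE,
                                   control = quick_solver))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".csv")
  write_fit(fit, f1, f2)
  back <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_equal(back$point$k6, unclass(fit$point)[["k6"]], tolerance = 1e-12)
  expect_equal(back$seed, fit$seed)
  expect_equal(nrow(back$chi2), 6)
  dr <- read.csv(f2)
  expect_identical(dim(dr), dim(fit$draws))
  unlink(c(f1, f2))
})
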