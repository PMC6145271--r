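test_that("zero vector field keeps all states constant", {
  y0 <- c(0.01, 0.5, 0.1, 0.2, 0.05, 1)
  tr <- simulate_fermentation(zero_params, y0, times = obs_times,
                              control = quick_solver)
  for (i in 1:6)
    expect_equal(tr[[paste0("y", i)]], rep(y0[i], length(obs_times)),
                 tolerance = 1e-12)
})

test_that("pure lysis reproduces the closed-form exponential decay", {
  p <- ferm_params(base = zero_params, k12 = 0.05)
  y0 <- c(0.15, 0.5, 0.1, 0, 0, 1)
  tr <- simulate_fermentation(p, y0, times = obs_times,
                              control = quick_solver)
  expect_equal(tr$y1, 0.15 * exp(-0.05 * obs_times), tolerance = 1e-9)
})

test_that("collocation agrees with the adaptive Runge-Kutta oracle", {
  # both study parameter sets plus random perturbations around them
  set.seed(123)
  cases <- c(list(list(p = ctrl_params, y0 = ctrl_y0),
                  list(p = pa_params, y0 = pa_y0)),
             lapply(1:5, function(i)
               list(p = jitter_params(ctrl_params, 0.1), y0 = ctrl_y0)))
  for (cs in cases) {
    tc <- simulate_fermentation(cs$p, cs$y0, obs_times)
    trk <- simulate_fermentation(cs$p, cs$y0, obs_times, control = rk_ref)
    scale <- pmax(abs(as.matrix(trk[, -1])),
                  1e-3 * max(abs(as.matrix(trk[, -1]))))
    rel <- abs(as.matrix(tc[, -1]) - as.matrix(trk[, -1])) / scale
    expect_lt(max(rel), 1e-6)
  }
})

test_that("dense output off the element boundaries matches the oracle", {
  tt <- c(0, 3.7, 11.1, 29.9, 44.4, 59.3)
  tc <- simulate_fermentation(ctrl_params, ctrl_y0, tt)
  trk <- simulate_fermentation(ctrl_params, ctrl_y0, tt, control = rk_ref)
  expect_equal(as.matrix(tc[, -1]), as.matrix(trk[, -1]), tolerance = 1e-7)
})

test_that("grid refinement changes the solution below tolerance scale", {
  tr1 <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times)
  tr2 <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times,
                               control = solver_config(n_elements = 30))
  # doubling the default element count moves the solution by less than
  # ten times the solver tolerance (discretisation already converged)
  expect_lt(max(abs(as.matrix(tr1[, -1]) - as.matrix(tr2[, -1]))),
            10 * solver_config()$abs_tol)
})

test_that("identical inputs give bit-identical trajectories", {
  tr1 <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times)
  tr2 <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times)
  expect_identical(as.matrix(tr1[, -1]), as.matrix(tr2[, -1]))
})

test_that("trajectories respect nonnegativity and saturation bounds", {
  tt <- seq(0, 60, by = 0.5)
  for (cs in list(list(p = ctrl_params, y0 = ctrl_y0),
                  list(p = pa_params, y0 = pa_y0))) {
    tr <- simulate_fermentation(cs$p, cs$y0, tt)
    # y6 is excluded: the glucose equation is a slave variable and the
    # reported rate constants overdraw the pool (see vignette)
    for (s in paste0("y", 1:5))
      expect_true(all(tr[[s]] >= -1e-9), label = paste(s, "nonnegative"))
    expect_true(all(tr$y1 <= cs$p[["y1_max"]] * (1 + 1e-6)))
    expect_true(all(tr$y4 <= cs$p[["y4_max"]] * (1 + 1e-6)))
    expect_true(all(tr$y5 <= cs$p[["y5_max"]] * (1 + 1e-6)))
  }
  # control-batch glucose stays positive with the default initial pool
  tr <- simulate_fermentation(ctrl_params, ctrl_y0, tt)
  expect_true(all(tr$y6 >= -1e-9))
})

test_that("saturation caps are approached but not crossed without growth", {
  p <- ferm_params(base = ctrl_params, k6 = 0, k8 = 0)
  tr <- simulate_fermentation(p, ctrl_y0, seq(0, 200, by = 5))
  expect_true(all(tr$y4 <= p[["y4_max"]] * (1 + 1e-6)))
  expect_true(all(tr$y5 <= p[["y5_max"]] * (1 + 1e-6)))
  expect_gt(max(tr$y4), 0.99 * p[["y4_max"]])
})

test_that("collocation residuals are at solver tolerance and detect tampering", {
  tr <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times)
  r <- collocation_residual(tr)
  expect_lt(max(r$residual), 1e-8)
  # a perturbed trajectory violates the defect equations
  tr_bad <- tr
  attr(tr_bad, "stages")$stage_y <- attr(tr_bad, "stages")$stage_y * 1.01
  expect_gt(max(suppressWarnings(collocation_residual(tr_bad))$residual),
            1e-3)
  # manufactured constant solution has exactly zero defect
  tr0 <- simulate_fermentation(zero_params, c(0.01, 0.5, 0.1, 0, 0, 1),
                               obs_times)
  expect_lt(max(collocation_residual(tr0)$residual), 1e-13)
})

test_that("solver failure is reported with diagnostics", {
  # an extremely stiff, far-from-calibrated parameter set with a single
  # coarse element cannot satisfy the collocation equations
  p <- ferm_params(base = ctrl_params, k1 = 5e4, k12 = 4e4)
  expect_error(
    simulate_fermentation(p, ctrl_y0, obs_times,
                          control = solver_config(n_elements = 1, order = 2,
                                                  max_newton = 4)),
    "converge")
})

test_that("trajectory CSV export uses the unit-bearing header", {
  tr <- simulate_fermentation(ctrl_params, ctrl_y0, obs_times,
                              control = quick_solver)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  hdr <- readLines(f, n = 1)
  expect_identical(hdr, paste0("time_hr,y1_gdcw_per100g,y2_gN_per100g,",
                               "y3_gN_per100g,y4_g_per100g,y5_g_per100g,",
                               "y6_g_per100g"))
  back <- read.csv(f)
  expect_equal(back$y4_g_per100g, tr$y4, tolerance = 1e-10)
  unlink(f)
})

test_that("solver configuration is validated", {
  expect_error(solver_config(n_elements = 0), "n_elements")
  expect_error(solver_config(order = 1), "order")
  expect_error(solver_config(order = 8), "order")
  expect_error(solver_config(abs_tol = 0), "positive")
  expect_error(simulate_fermentation(ctrl_params, c(-1, 0, 0, 0, 0, 0),
                                     obs_times), "nonnegative")
})
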