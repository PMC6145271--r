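test_that("lag factor matches its closed form and limits", {
  expect_identical(lag_factor(0, 0.5), 0)
  expect_equal(lag_factor(24, 0.141), 1 - exp(-0.141 * 24))
  # frozen from an independent high-precision evaluation of 1 - e^(-3.384)
  expect_equal(lag_factor(24, 0.141), 0.96608846306751, tolerance = 1e-10)
  expect_equal(lag_factor(1e6, 0.141), 1)
  tt <- seq(0, 60, by = 0.5)
  expect_true(all(diff(lag_factor(tt, 0.142)) >= 0))
  expect_true(all(lag_factor(tt, 0.142) >= 0 & lag_factor(tt, 0.142) < 1))
  expect_error(lag_factor(-1, 0.5), "nonnegative")
  expect_error(lag_factor(1, 0), "positive")
})

test_that("biomass rate obeys its structural limits", {
  p <- ctrl_params
  # no cells, no growth or lysis
  st <- state_vector(y1 = 0, y2 = 0.5, t = 24)
  expect_identical(biomass_rate(st, p), 0)
  # at carrying capacity only lysis remains
  st <- state_vector(y1 = p[["y1_max"]], y2 = 0.5, t = 1e4)
  expect_equal(biomass_rate(st, p), -p[["k12"]] * p[["y1_max"]])
  # Monod saturation limit: y2 >> k2, y1 << y1_max, lag gone
  st <- state_vector(y1 = 1e-6, y2 = 1e6, t = 1e4)
  expect_equal(biomass_rate(st, p), (p[["k1"]] - p[["k12"]]) * 1e-6,
               tolerance = 1e-5)
  # overshoot warns but still evaluates
  st_over <- c(y1 = p[["y1_max"]] * 1.01, y2 = 0.5, y3 = 0, y4 = 0,
               y5 = 0, y6 = 0, t = 30)
  expect_warning(biomass_rate(st_over, p), "y1_max")
})

test_that("protein/NPN coupling solves the two-equation linear system exactly", {
  s <- stoichiometry()
  p <- ctrl_params
  st <- state_vector(y2 = 0.563, t = 10)
  for (dy1 in c(0, 0.003, -0.001)) {
    got <- protein_npn_rates(st, dy1, p, s)
    # independent 2x2 linear-algebra oracle: A x = rhs with
    # x = (dy2, dy3)
    a <- p[["cor_bio"]] * s$frac_bio
    b <- p[["cor_NPN"]] * s$frac_npn
    A <- rbind(c(1, b), c(p[["k4"]], 1))
    rhs <- c(-a * dy1 - p[["cor_X"]] * 0.563, p[["k5"]] * 0.563)
    x <- solve(A, rhs)
    expect_equal(unname(got), x, tolerance = 1e-12)
    # substituted back, both equation residuals vanish
    expect_lt(abs(got[["dy2"]] -
                    (-(a * dy1 + b * got[["dy3"]]) - p[["cor_X"]] * 0.563)),
              1e-12)
    expect_lt(abs(got[["dy3"]] -
                    (-p[["k4"]] * got[["dy2"]] + p[["k5"]] * 0.563)), 1e-12)
  }
})

test_that("protein/NPN degenerate cases decouple as expected", {
  s <- stoichiometry()
  st <- state_vector(y2 = 0.4, t = 5)
  # k4 = k5 = 0, dy1 = 0: only the first-order protein loss remains
  p0 <- ferm_params(base = ctrl_params, k4 = 0, k5 = 0)
  got <- protein_npn_rates(st, 0, p0, s)
  expect_equal(got[["dy3"]], 0)
  expect_equal(got[["dy2"]], -p0[["cor_X"]] * 0.4)
  # k4 = 0: one-way coupling, dy3 = k5*y2
  p1 <- ferm_params(base = ctrl_params, k4 = 0)
  got <- protein_npn_rates(st, 0.002, p1, s)
  expect_equal(got[["dy3"]], p1[["k5"]] * 0.4)
  # singular denominator is reported with the offending parameters
  s_bad <- stoichiometry(N_NPN = 1, MW_NPN = 28.014) # frac_npn = 0.5
  p_bad <- ferm_params(base = ctrl_params, cor_NPN = 2, k4 = 1)
  expect_error(protein_npn_rates(st, 0, p_bad, s_bad), "singular")
})

test_that("product and substrate rate laws match scalar arithmetic", {
  p <- ctrl_params
  # lactate: saturation kills the non-growth term; zero product gives k7
  expect_equal(lactate_rate(state_vector(y4 = p[["y4_max"]]), 0, p), 0)
  expect_equal(lactate_rate(state_vector(y4 = 0), 0, p), p[["k7"]])
  expect_equal(lactate_rate(state_vector(y4 = p[["y4_max"]] / 2), 0.001, p),
               0.414 * 0.001 + 0.032)
  # formate mirrors the same contract
  expect_equal(formate_rate(state_vector(y5 = p[["y5_max"]]), 0, p), 0)
  p_k80 <- ferm_params(base = p, k8 = 0)
  expect_equal(formate_rate(state_vector(y5 = 0), 0.01, p_k80), p[["k9"]])
  # glucose
  expect_equal(glucose_rate(state_vector(y4 = p[["y4_max"]]), 0, p), 0)
  expect_equal(glucose_rate(state_vector(y4 = 0), 0, p), -p[["k11"]])
  expect_equal(glucose_rate(state_vector(y4 = 0.75), 0.002, p),
               -(9.855e-3 * 0.002 + 0.101 * 0.5))
})

test_that("assembled rhs equals its components for random states", {
  set.seed(42)
  s <- stoichiometry()
  for (i in 1:100) {
    p <- jitter_params(ctrl_params, sd = 0.3)
    y <- c(runif(1, 0, p[["y1_max"]]), runif(1, 0.05, 0.6),
           runif(1, 0.05, 0.3), runif(1, 0, 1.4), runif(1, 0, 0.19),
           runif(1, 0, 2.5))
    t <- runif(1, 0, 60)
    d <- ferm_rhs(t, y, p, s)
    st <- c(y1 = y[1], y2 = y[2], y3 = y[3], y4 = y[4], y5 = y[5],
            y6 = y[6], t = t)
    dy1 <- biomass_rate(st, p)
    d23 <- protein_npn_rates(st, dy1, p, s)
    expect_equal(unname(d),
                 unname(c(dy1, d23, lactate_rate(st, dy1, p),
                          formate_rate(st, dy1, p),
                          glucose_rate(st, dy1, p))), tolerance = 1e-14)
  }
})

test_that("compiled and interpreted rhs agree", {
  set.seed(7)
  s <- stoichiometry()
  for (i in 1:50) {
    p <- jitter_params(pa_params, sd = 0.3)
    y <- c(runif(1, 0.001, p[["y1_max"]]), runif(5, 0.001, 1))
    t <- runif(1, 0, 60)
    expect_equal(unname(fermkin:::rhs_cpp(t, y, fermkin:::pack_params(p, s))),
                 unname(ferm_rhs(t, y, p, s)), tolerance = 1e-12)
  }
})

test_that("lag property: at t = 0 only lysis acts on biomass", {
  d <- ferm_rhs(0, ctrl_y0, ctrl_params)
  expect_equal(d[["dy1"]], -ctrl_params[["k12"]] * ctrl_y0[["y1"]])
})
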