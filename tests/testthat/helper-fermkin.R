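# Shared fixtures: fast solver configurations and canonical parameter
# sets used across the test files.

ctrl_params <- batch_params("control")
pa_params <- batch_params("p_acidilactici")
ctrl_y0 <- default_initial_conditions("control")
pa_y0 <- default_initial_conditions("p_acidilactici")
obs_times <- c(0, 12, 24, 36, 48, 60)

# moderately refined config, fast enough for loops in tests
quick_solver <- solver_config(n_elements = 10, order = 4, abs_tol = 1e-9)

# a tight reference Runge-Kutta configuration (independent oracle path)
rk_ref <- solver_config(method = "runge_kutta", rel_tol = 1e-11,
                        abs_tol = 1e-13)

# all-zero parameter set (zero vector field) that still passes validation
zero_params <- as_ferm_params(setNames(
  c(rep(0, 15), 0.2, 1.5, 0.2),
  c(paste0("k", 1:12), "cor_bio", "cor_NPN", "cor_X",
    "y1_max", "y4_max", "y5_max")))

# random parameter jitter around a base set (multiplicative lognormal)
jitter_params <- function(base, sd = 0.1) {
  v <- unclass(base)
  v[1:15] <- v[1:15] * exp(rnorm(15, sd = sd))
  as_ferm_params(v)
}
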