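# Scenario sweeps share a few moderately expensive simulations; they are
# computed once here and reused across test blocks.
base_params <- model_parameters()
tau_sweep <- sweep_scenarios(base_params, O0 = 0.5,
                             tau_hours = c(4, 6, 8, 10, 12))
o2_sweep <- sweep_scenarios(base_params, O0 = seq(0.3, 0.8, by = 0.1),
                            tau_hours = 8)

test_that("full oxygen produces no injury and flat biomarkers", {
  s <- run_scenario(base_params, O0 = 1, tau_hours = 8, horizon = 5)
  expect_equal(s$min_healthy_fraction, 1, tolerance = 1e-8)
  expect_equal(s$peak_S, base_params$S_min, tolerance = 1e-6)
  expect_equal(s$peak_L, base_params$L_min, tolerance = 1e-6)
  expect_equal(s$peak_D, base_params$D_min, tolerance = 1e-4)
  expect_false(s$reached_critical)
})

test_that("later treatment means higher peaks and deeper damage", {
  expect_true(all(diff(tau_sweep$peak_S) > 0))
  expect_true(all(diff(tau_sweep$peak_L) > 0))
  expect_true(all(diff(tau_sweep$peak_D) > 0))
  expect_true(all(diff(1 - tau_sweep$min_healthy_fraction) > 0))
})

test_that("more initial oxygen means lower peaks and less damage", {
  expect_true(all(diff(o2_sweep$peak_S) < 0))
  expect_true(all(diff(o2_sweep$peak_L) < 0))
  expect_true(all(diff(o2_sweep$peak_D) < 0))
  expect_true(all(diff(o2_sweep$min_healthy_fraction) > 0))
})

test_that("AST peaks and normalizes before ALT; LDH stays capped", {
  s <- run_scenario(base_params, O0 = 0.5, tau_hours = 8)
  rep <- peak_ordering_report(s)
  expect_true(all(rep))

  # without treatment all biomarkers eventually decay toward baseline
  long <- run_scenario(base_params, O0 = 0.4, tau_hours = Inf, horizon = 30,
                       dt = 0.005)
  traj <- attr(long, "trajectory")
  last <- traj[nrow(traj), ]
  expect_lt(last$S, base_params$S_min + 0.1 * (long$peak_S - base_params$S_min))
  expect_lt(last$L, base_params$L_min + 0.1 * (long$peak_L - base_params$L_min))
  expect_lt(last$D, base_params$D_min + 0.1 * (long$peak_D - base_params$D_min))
})

test_that("interpolated critical time agrees with the first grid crossing", {
  s <- run_scenario(base_params, O0 = 0.3, tau_hours = Inf, horizon = 2)
  traj <- attr(s, "trajectory")
  hfrac <- traj$H / base_params$H_max
  grid_first <- traj$time[which(hfrac <= 0.3)[1]] * 24
  expect_lte(abs(s$time_to_critical_h - grid_first), 0.002 * 24)
})

test_that("the critical-time curve is monotone and well fitted", {
  cv <- critical_time_curve(base_params, O0_grid = seq(0.30, 0.80, by = 0.05))
  expect_equal(nrow(cv$points), 11)
  expect_true(all(diff(cv$points$time_to_critical_h) > 0))
  expect_lt(cv$rmse_days, 0.05)
  expect_gt(cv$fit[["k"]], 0)
  # reference constants are attached for comparison, not imposed on the fit
  expect_false(is.null(attr(cv, "reference_fit")))
})

test_that("the curve fit demands at least three critical crossings", {
  expect_error(
    critical_time_curve(base_params, O0_grid = c(0.90, 0.92, 0.94),
                        horizon = 1),
    "fewer than 3")
})

test_that("critical oxygen moves down when treatment comes earlier", {
  o8 <- find_critical_oxygen(base_params, tau_hours = 8, tol = 2e-3)
  o6 <- find_critical_oxygen(base_params, tau_hours = 6, tol = 2e-3)
  expect_gt(o8, 0.05); expect_lt(o8, 0.95)
  expect_lt(o6, o8)
  # almost no damage allowed: the bracket excludes the root
  expect_error(find_critical_oxygen(base_params, tau_hours = 8,
                                    critical_fraction = 0.999),
               "no sign change")
})

test_that("damage grows monotonically with the reperfusion scale", {
  sw <- reperfusion_sweep(base_params, c_grid = c(0, 0.5, 1), O0 = 0.5,
                          tau_hours = 8, horizon = 10)
  expect_true(all(diff(sw$min_healthy_fraction) < 0))
  # c = 0 reproduces the base scenario exactly
  base <- run_scenario(base_params, O0 = 0.5, tau_hours = 8, horizon = 10)
  expect_equal(sw$peak_S[1], base$peak_S, tolerance = 1e-12)
  expect_equal(sw$min_healthy_fraction[1], base$min_healthy_fraction,
               tolerance = 1e-12)
  expect_warning(reperfusion_sweep(base_params, c_grid = c(0, 3),
                                   horizon = 2), "above 2")
})

test_that("the oxygen-return rate is recovered from self-generated peaks", {
  truth <- tau_sweep[tau_sweep$tau_hours == 8, ]
  fit <- calibrate_epsilon(base_params,
                           targets = c(truth$peak_S, truth$peak_L, truth$peak_D))
  expect_lt(abs(fit$epsilon - 20) / 20, 0.05)
  expect_lt(fit$objective, 1e-4)
})
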