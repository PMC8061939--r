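test_that("the healthy state is an exact fixed point under full oxygen", {
  p <- model_parameters(O0 = 1)
  d <- base_rhs(canonical_state(p), 0, p)
  expect_identical(unname(d), rep(0, 6))
})

test_that("derivatives match hand evaluation at reference arguments", {
  # LDH production at full healthy pool, half oxygen, baseline LDH:
  # dD/dt = 0.5 (beta_D / theta) (1 - D_min/D_max)
  p <- model_parameters(O0 = 0.5)
  d <- base_rhs(canonical_state(p), 0, p)  # untreated: O = 0.5 at t = 0
  expect_equal(d[["D"]], 0.5 * (2e5 / 5) * (1 - 120 / 30000), tolerance = 1e-12)
  # no damaged cells + baseline AST => no AST movement
  expect_equal(d[["S"]], 0, tolerance = 1e-15)
  # ATP balance at A = A_norm, O = 0.5: rho H (O - 1)
  expect_equal(d[["A"]], 1.43 * 1.6e11 * (0.5 - 1), tolerance = 1e-9)
})

test_that("reperfusion RHS reduces to the base RHS when it must", {
  set.seed(401)
  p0 <- model_parameters(O0 = 0.5, tau_hours = 8)  # c_reperfusion = 0
  p1 <- update_params(p0, c_reperfusion = 1.3)
  pu <- update_params(p1, tau = Inf)               # untreated, c > 0
  for (i in 1:1000) {
    st <- rand_state(p0)
    t <- stats::runif(1, 0, 2)
    expect_identical(reperfusion_rhs(st, t, p0), base_rhs(st, t, p0))
    expect_identical(reperfusion_rhs(st, t, pu), base_rhs(st, t, pu))
  }
  # and differs in exactly the hepatocyte transfer when c > 0 and treated
  st <- rand_state(p1)
  tmid <- schedule_from_params(p1)$tau_mid
  d0 <- base_rhs(st, tmid, p1); d1 <- reperfusion_rhs(st, tmid, p1)
  flux <- 1.3 * oxygen_rate_magnitude(schedule_from_params(p1), tmid) * st[["H"]]
  expect_equal(d1[["H"]] - d0[["H"]], -flux, tolerance = 1e-10)
  expect_equal(d1[["Z"]] - d0[["Z"]], flux, tolerance = 1e-10)
  expect_equal(d1[c("A", "S", "L", "D")], d0[c("A", "S", "L", "D")])
})

test_that("the accumulated oxygen-rate forcing equals the oxygen deficit", {
  # |dO/dt| integrates to |1 - O0| over a full return, so the reperfusion
  # kill fraction saturates at 1 - exp(-c |1 - O0|)
  sch <- oxygen_schedule(O0 = 0.5, epsilon = 20, tau = 8 / 24)
  total <- stats::integrate(function(t) oxygen_rate_magnitude(sch, t),
                            0, sch$tau_mid + 2, rel.tol = 1e-10)$value
  expect_equal(total, oxygen_level(sch, sch$tau_mid + 2) - oxygen_level(sch, 0),
               tolerance = 1e-8)
  expect_equal(total, 1 - 0.5, tolerance = 1e-3)

  # even an extreme reperfusion scale cannot push the cell pools negative
  p <- model_parameters(O0 = 0.5, tau_hours = 8, c_reperfusion = 2)
  traj <- simulate_liver(p, horizon = 6, reperfusion = TRUE, dt = 0.005)
  expect_true(all(traj$H >= -1e-8 & traj$Z >= -1e-8))
  expect_true(all(traj$H + traj$Z <= p$H_max * (1 + 1e-10)))
})

test_that("simulation from the healthy state under full oxygen is stationary", {
  p <- model_parameters(O0 = 1)
  traj <- simulate_liver(p, horizon = 14, dt = 0.01)
  y0 <- canonical_state(p)
  for (v in c("A", "H", "Z", "S", "L", "D")) {
    scale <- max(abs(y0[[v]]), 1)
    expect_lt(max(abs(traj[[v]] - y0[[v]])) / scale, 1e-8)
  }
})

test_that("trajectories respect the physical bounds of the model", {
  p <- model_parameters()
  runs <- list(
    simulate_liver(update_params(p, O0 = 0.3), horizon = 6, dt = 0.005),
    simulate_liver(update_params(p, O0 = 0.5, tau_hours = 8), horizon = 10,
                   dt = 0.005),
    simulate_liver(update_params(p, O0 = 0.5, tau_hours = 8,
                                 c_reperfusion = 0.5),
                   horizon = 10, reperfusion = TRUE, dt = 0.005)
  )
  for (traj in runs) {
    tol <- 1e-8
    expect_true(all(traj$H + traj$Z <= p$H_max * (1 + 1e-10)))
    expect_true(all(traj$A <= p$A_norm * (1 + 1e-10)))  # ATP ceiling, O <= 1
    expect_true(all(traj$S >= p$S_min - tol))
    expect_true(all(traj$L >= p$L_min - tol))
    expect_true(all(traj$D >= p$D_min - tol & traj$D <= p$D_max + tol))
    # negative excursions of the cell/ATP pools stay within solver tolerance
    pool_tol <- 10 * 1e-6 * c(p$A_norm, p$H_max, p$H_max)
    expect_true(all(traj$A >= -pool_tol[1] & traj$H >= -pool_tol[2] &
                      traj$Z >= -pool_tol[3]))
  }
})

test_that("refining solver tolerances leaves biomarker peaks unchanged to 0.1%", {
  p <- model_parameters(O0 = 0.5, tau_hours = 8)
  coarse <- simulate_liver(p, horizon = 10)
  fine <- simulate_liver(p, horizon = 10, dt = 0.001, rtol = 1e-9)
  for (v in c("S", "L", "D"))
    expect_equal(max(coarse[[v]]), max(fine[[v]]), tolerance = 1e-3)
})

test_that("inadmissible states are rejected", {
  p <- model_parameters()
  expect_error(liver_state(-1, 1, 1, 1, 1, 1), "nonnegative")
  bad <- canonical_state(p)
  bad[["H"]] <- -0.01 * p$H_max
  expect_error(base_rhs(bad, 0, p), "negative")
})
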