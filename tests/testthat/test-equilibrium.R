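test_that("rho = k yields the exact healthy steady state", {
  p <- model_parameters()
  eq <- steady_state(p)
  expect_equal(eq$lambda, 0)
  expect_equal(eq$feasibility, "healthy")
  expect_equal(unname(unclass(eq$state)),
               c(p$A_norm, p$H_max, 0, p$S_min, p$L_min, p$D_min))
  expect_true(eq$locally_stable)
})

test_that("steady states satisfy the ODEs to near machine precision", {
  set.seed(502)
  for (i in 1:50) {
    p <- rand_params_feasible()
    eq <- steady_state(p)
    expect_equal(eq$feasibility, "feasible_nontrivial")
    f <- base_rhs(eq$state, 0, p)  # O0 = 1, untreated: O = 1
    rel <- abs(f) / pmax(abs(unclass(eq$state)), 1)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("feasibility classification matches brute-force sign checks", {
  set.seed(503)
  for (i in 1:200) {
    p <- rand_params_healthy()
    lam <- stats::runif(1, -1.5, 0.9)
    p <- suppressWarnings(update_params(p, rho = p$k * (1 - lam)))
    eq <- steady_state(p)
    el <- p$eta * eq$lambda
    Hs <- p$H_max * (1 - el / p$r) / (1 + el / p$delta_Z)
    Zs <- (el / p$r) * p$H_max * (p$r - el) / (p$delta_Z + el)
    expected <- if (abs(eq$lambda) < 1e-12) "healthy"
      else if (Hs < 0) "infeasible_negative_H"
      else if (Zs < 0) "infeasible_negative_Z"
      else "feasible_nontrivial"
    expect_equal(eq$feasibility, expected)
  }
})

test_that("the analytic Jacobian matches finite differences of the RHS", {
  set.seed(504)
  p <- model_parameters(O0 = 0.7)  # untreated: O constant 0.7
  for (i in 1:20) {
    st <- rand_state(p)
    J <- jacobian(st, p, O = 0.7)
    Jfd <- matrix(0, 6, 6)
    y <- unclass(st)
    for (j in 1:6) {
      h <- 1e-6 * max(abs(y[j]), 1)
      up <- y; up[j] <- up[j] + h
      dn <- y; dn[j] <- dn[j] - h
      Jfd[, j] <- (base_rhs(up, 0, p) - base_rhs(dn, 0, p)) / (2 * h)
    }
    expect_lt(max(abs(Jfd - J)) / max(abs(J)), 1e-6)
  }
  # AST/ALT rows do not couple to ATP or healthy cells
  J <- jacobian(rand_state(p), p, O = 0.7)
  expect_equal(unname(J[c("S", "L"), c("A", "H")]), matrix(0, 2, 2))
})

test_that("healthy-equilibrium spectrum equals the symbolic eigenvalue list", {
  p <- model_parameters()
  eq <- classify_stability(p)
  # direct substitution of the defaults into the symbolic list
  expect_equal(eq$eigenvalues, sort(c(-0.35, -1, -0.92, -5, -143, -0.459)),
               tolerance = 1e-10)
  expect_true(eq$locally_stable)
  expect_equal(jacobian(canonical_state(p), p, O = 1)["A", "A"], -143,
               tolerance = 1e-12)

  set.seed(505)
  for (i in 1:100) {
    pr <- rand_params_healthy()
    eqr <- classify_stability(pr)
    ref <- attr(eqr, "reference_eigenvalues")
    expect_lt(max(abs((eqr$eigenvalues - ref) / ref)), 1e-8)
    expect_true(eqr$locally_stable)
  }
})

test_that("stability becomes marginal as a clearance rate vanishes", {
  p <- update_params(model_parameters(), delta_L = 1e-9)
  eq <- classify_stability(p)
  expect_lt(max(eq$eigenvalues), 0)
  expect_gt(max(eq$eigenvalues), -1e-8)
})

test_that("classify_stability rejects rho != k", {
  expect_error(classify_stability(update_params(model_parameters(), rho = 1.3)),
               "rho = k")
})

test_that("sensitivity closed form reproduces the classical H*-rho expression", {
  p <- model_parameters()
  # eta rho (delta_Z + r) / (r delta_Z k) at rho = k: 6.381 * 6 / 5
  expect_equal(sensitivity_index("H", "rho", p), 7.6572, tolerance = 1e-10)
  expect_equal(sensitivity_index("H", "rho", p),
               sensitivity_H_rho_reference(p), tolerance = 1e-10)
  p99 <- update_params(p, rho = 0.99 * p$k)
  expect_equal(sensitivity_index("H", "rho", p99),
               sensitivity_H_rho_reference(p99), tolerance = 1e-8)
})

test_that("closed-form and finite-difference indices agree where defined", {
  p <- model_parameters()
  for (lam in c(0.01, 0.05)) {
    plam <- update_params(p, rho = p$k * (1 - lam))
    for (v in c("A", "H", "Z", "S", "L")) {
      for (par in c("rho", "k")) {
        cf <- sensitivity_index(v, par, plam)
        fd <- sensitivity_index(v, par, plam, method = "finite_difference")
        expect_equal(fd, cf, tolerance = 1e-4)
      }
      # lambda depends on rho and k with opposite-signed derivatives
      s_rho <- sensitivity_index(v, "rho", plam)
      s_k <- sensitivity_index(v, "k", plam)
      if (s_rho != 0) expect_lt(s_rho * s_k, 0)
    }
  }
})

test_that("normalized indices are undefined where the equilibrium value is zero", {
  expect_error(sensitivity_index("Z", "rho", model_parameters()),
               "undefined")
})
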