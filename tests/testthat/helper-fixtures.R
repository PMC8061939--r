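# Shared fixtures: random positive parameter draws and admissible states.

# Random positive parameter set with rho = k (healthy equilibrium exists).
rand_params_healthy <- function() {
  k <- stats::runif(1, 0.5, 3)
  model_parameters(
    A_norm = 10^stats::runif(1, 8, 10),
    rho = k, k = k,
    r = stats::runif(1, 0.3, 2),
    eta = stats::runif(1, 2, 8),
    delta_Z = stats::runif(1, 2, 8),
    H_max = 10^stats::runif(1, 10, 12),
    theta = stats::runif(1, 3, 7),
    delta_S = stats::runif(1, 0.3, 2),
    delta_L = stats::runif(1, 0.1, 1),
    delta_D = stats::runif(1, 0.2, 1),
    beta_S = stats::runif(1, 1e4, 5e4),
    beta_L = stats::runif(1, 5e3, 2e4),
    beta_D = stats::runif(1, 1e5, 5e5),
    S_min = stats::runif(1, 5, 20), L_min = stats::runif(1, 5, 15),
    D_min = stats::runif(1, 80, 200), D_max = stats::runif(1, 2e4, 5e4),
    O0 = 1, epsilon = stats::runif(1, 5, 40)
  )
}

# Same but with a feasible nontrivial equilibrium: lambda in (0, 0.9 r/eta).
rand_params_feasible <- function() {
  p <- rand_params_healthy()
  lam <- stats::runif(1, 0.01, 0.9 * min(p$r / p$eta, 0.3))
  update_params(p, rho = p$k * (1 - lam))
}

# Random admissible state drawn within the physical simplex of a params set.
rand_state <- function(p) {
  h <- stats::runif(1, 0, 1)
  z <- stats::runif(1, 0, 1 - h)
  liver_state(
    A = stats::runif(1, 0, p$A_norm),
    H = h * p$H_max, Z = z * p$H_max,
    S = stats::runif(1, p$S_min, 50 * p$S_min),
    L = stats::runif(1, p$L_min, 50 * p$L_min),
    D = stats::runif(1, p$D_min, p$D_max)
  )
}
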