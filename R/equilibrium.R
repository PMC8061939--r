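# Steady states, stability and sensitivity of the constant-oxygen system.
#
# With oxygen saturated (O = 1) the system admits closed-form equilibria
# parameterized by lambda = 1 - rho/k, the imbalance between ATP production
# and consumption. lambda = 0 gives the healthy liver; lambda != 0 gives
# states that are feasible only in a narrow parameter window.

#' Closed-form steady state of the constant-oxygen system
#'
#' Computes `lambda = 1 - rho/k` and the six steady-state values
#' \deqn{H^* = H_{max}\frac{1 - \eta\lambda/r}{1 + \eta\lambda/\delta_Z},\quad
#'       A^* = A_{norm}(1-\lambda),\quad
#'       Z^* = \frac{\eta\lambda}{r} H_{max}\frac{r - \eta\lambda}{\delta_Z + \eta\lambda},}
#' with AST/ALT at their lysis-driven quasi-equilibria and `D* = D_min`
#' (oxygen is full, so LDH production is off). Classifies feasibility by the
#' sign pattern of the expressions:
#' * `healthy` — `lambda = 0`, the healthy liver;
#' * `feasible_nontrivial` — `lambda > 0` and `r/eta > lambda`, all values
#'   nonnegative;
#' * `infeasible_negative_H` / `infeasible_negative_Z` — a hepatocyte pool
#'   would be negative;
#' * `trivial_dead` — the hepatocyte pools vanish.
#'
#' @param params A `liver_params`. Oxygen is treated as constant 1.
#' @return An object of class `equilibrium_point`: list with `lambda`,
#'   `state` (a `liver_state` when feasible, otherwise the raw values),
#'   `feasibility`, `eigenvalues` (of the Jacobian at the state, when
#'   feasible), and `locally_stable`.
#' @examples
#' eq <- steady_state(model_parameters())
#' eq$feasibility  # "healthy"
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "liver_params"))
  if (params$k == 0) stop("k = 0: lambda undefined", call. = FALSE)
  p <- params
  lam <- 1 - p$rho / p$k
  el <- p$eta * lam

  Hs <- p$H_max * (1 - el / p$r) / (1 + el / p$delta_Z)
  As <- p$A_norm * (1 - lam)
  Zs <- (el / p$r) * p$H_max * (p$r - el) / (p$delta_Z + el)
  Ss <- p$S_min + p$delta_Z * p$beta_S / (p$delta_S * p$theta) * Zs / p$H_max
  Ls <- p$L_min + p$delta_Z * p$beta_L / (p$delta_L * p$theta) * Zs / p$H_max
  Ds <- p$D_min
  values <- c(A = As, H = Hs, Z = Zs, S = Ss, L = Ls, D = Ds)

  feas <- classify_feasibility(lam, p)
  feasible <- feas %in% c("healthy", "feasible_nontrivial", "trivial_dead")

  eigenvalues <- NULL
  stable <- NA
  if (feasible && all(is.finite(values)) && all(values >= 0)) {
    st <- liver_state(As, Hs, Zs, Ss, Ls, Ds)
    J <- jacobian(st, p, O = 1)
    eigenvalues <- eigen(J, only.values = TRUE)$values
    stable <- all(Re(eigenvalues) < 0)
    values <- st
  }
  structure(list(lambda = lam, state = values, feasibility = feas,
                 eigenvalues = eigenvalues, locally_stable = stable,
                 params = p),
            class = "equilibrium_point")
}

classify_feasibility <- function(lam, p) {
  if (abs(lam) < 1e-12) return("healthy")
  if (lam < 0) {
    ratio <- p$delta_Z / p$eta
    al <- abs(lam)
    if (abs(ratio - al) < 1e-12) return("trivial_dead")
    if (ratio > al) return("infeasible_negative_Z")
    return("infeasible_negative_H")
  }
  ratio <- p$r / p$eta
  if (abs(ratio - lam) < 1e-12) return("trivial_dead")
  if (ratio > lam) return("feasible_nontrivial")
  "infeasible_negative_H"
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("<equilibrium_point> lambda = %.6g, feasibility = %s\n",
              x$lambda, x$feasibility))
  v <- unclass(x$state)
  cat(sprintf("  A* = %.6g  H* = %.6g  Z* = %.6g\n", v[["A"]], v[["H"]], v[["Z"]]))
  cat(sprintf("  S* = %.6g  L* = %.6g  D* = %.6g\n", v[["S"]], v[["L"]], v[["D"]]))
  if (!is.null(x$eigenvalues))
    cat(sprintf("  max Re(eigenvalue) = %.6g /day; locally stable: %s\n",
                max(Re(x$eigenvalues)), x$locally_stable))
  invisible(x)
}

#' Jacobian of the base system at a state
#'
#' Analytic 6x6 Jacobian of [base_rhs()] with oxygen held constant at `O`.
#' Row/column order: A, H, Z, S, L, D. The AST and ALT rows have zero entries
#' in the A and H columns (their equations involve only Z and themselves).
#'
#' @param state A `liver_state`.
#' @param params A `liver_params`.
#' @param O Constant oxygen fraction.
#' @return A 6x6 numeric matrix (units 1/day) with dimnames.
#' @export
jacobian <- function(state, params, O = 1) {
  p <- params
  x <- as_state_vector(state, p)
  A <- x[[1L]]; H <- x[[2L]]; Z <- x[[3L]]; D <- x[[6L]]
  J <- matrix(0, 6L, 6L, dimnames = list(STATE_NAMES, STATE_NAMES))

  J["A", "A"] <- -p$k * H / p$A_norm
  J["A", "H"] <- p$rho * O - p$k * A / p$A_norm

  J["H", "A"] <- p$eta * H / p$A_norm
  J["H", "H"] <- p$r * (1 - (H + Z) / p$H_max) - p$r * H / p$H_max -
    p$eta * (1 - A / p$A_norm)
  J["H", "Z"] <- -p$r * H / p$H_max

  J["Z", "A"] <- -p$eta * H / p$A_norm
  J["Z", "H"] <- p$eta * (1 - A / p$A_norm)
  J["Z", "Z"] <- -p$delta_Z

  J["S", "Z"] <- p$delta_Z * p$beta_S / (p$theta * p$H_max)
  J["S", "S"] <- -p$delta_S

  J["L", "Z"] <- p$delta_Z * p$beta_L / (p$theta * p$H_max)
  J["L", "L"] <- -p$delta_L

  J["D", "H"] <- p$beta_D / (p$theta * p$H_max) * (1 - O) * (1 - D / p$D_max)
  J["D", "D"] <- -H * p$beta_D / (p$theta * p$H_max) * (1 - O) / p$D_max - p$delta_D
  J
}

#' Eigenvalues and local stability of the healthy equilibrium
#'
#' At the healthy equilibrium (`rho = k`, full oxygen) the spectrum of the
#' Jacobian is exactly \{-delta_L, -r, -delta_S, -delta_Z,
#' -k H_max / A_norm, -delta_D\}; all negative, so the healthy liver is
#' locally stable. This function computes the spectrum numerically, attaches
#' the symbolic reference values, and flags stability.
#'
#' @param params A `liver_params` with `rho == k` (the closed-form eigenvalue
#'   list applies only to the healthy equilibrium).
#' @return An `equilibrium_point` whose `eigenvalues` are sorted by real
#'   part; the symbolic list is attached as attribute
#'   `reference_eigenvalues`.
#' @examples
#' classify_stability(model_parameters())$locally_stable  # TRUE
#' @export
classify_stability <- function(params) {
  stopifnot(inherits(params, "liver_params"))
  if (abs(params$rho - params$k) > 1e-12 * params$k)
    stop("closed-form eigenvalue list applies only to rho = k", call. = FALSE)
  eq <- steady_state(params)
  ref <- sort(c(-params$delta_L, -params$r, -params$delta_S, -params$delta_Z,
                -params$k * params$H_max / params$A_norm, -params$delta_D))
  ev <- sort(Re(eq$eigenvalues))
  eq$eigenvalues <- ev
  eq$locally_stable <- all(ev < 0)
  attr(eq, "reference_eigenvalues") <- ref
  eq
}

# Analytic derivatives of the steady-state map with respect to lambda.
steady_state_dlambda <- function(lam, p) {
  el <- p$eta * lam
  u <- 1 - el / p$r;        du <- -p$eta / p$r
  v <- 1 + el / p$delta_Z;  dv <- p$eta / p$delta_Z
  dH <- p$H_max * (du * v - u * dv) / v^2
  dA <- -p$A_norm
  num <- el * (p$r - el); dnum <- p$eta * p$r - 2 * p$eta * el
  den <- p$delta_Z + el;  dden <- p$eta
  dZ <- (p$H_max / p$r) * (dnum * den - num * dden) / den^2
  dS <- p$delta_Z * p$beta_S / (p$delta_S * p$theta) * dZ / p$H_max
  dL <- p$delta_Z * p$beta_L / (p$delta_L * p$theta) * dZ / p$H_max
  c(A = dA, H = dH, Z = dZ, S = dS, L = dL, D = 0)
}

#' Normalized sensitivity index of an equilibrium value
#'
#' The normalized sensitivity index `SI(X*; p) = (dX*/dp) (p / X*)` measures
#' the percent change of a steady-state value per percent change of a
#' parameter. Because every steady-state expression depends on `rho` and `k`
#' only through `lambda = 1 - rho/k`, the indices with respect to the two
#' rates have opposite signs at any point where they are defined.
#'
#' Two routes are provided: the closed form, obtained by differentiating the
#' steady-state expressions through the chain rule in `lambda`, and a central
#' finite difference on the steady-state map (relative step 1e-6). The two
#' agree to better than 1e-4 wherever the index is defined, and for
#' `(H*, rho)` the closed form coincides with the classical expression
#' `-eta k rho (delta_Z + r) / ((k (delta_Z + eta) - eta rho)(k (eta - r) - eta rho))`.
#'
#' @param variable One of `"A","H","Z","S","L","D"`.
#' @param parameter `"rho"` or `"k"`.
#' @param params A `liver_params` giving the evaluation point (through
#'   `rho/k`); the index is undefined where the steady-state value is 0
#'   (e.g. `Z*` at `lambda = 0`) and an error is raised there.
#' @param method `"closed_form"` (default) or `"finite_difference"`.
#' @return The dimensionless index (a single number).
#' @examples
#' sensitivity_index("H", "rho", model_parameters())
#' @export
sensitivity_index <- function(variable, parameter = c("rho", "k"), params,
                              method = c("closed_form", "finite_difference")) {
  variable <- match.arg(variable, STATE_NAMES)
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  stopifnot(inherits(params, "liver_params"))
  p <- params
  eq <- steady_state(p)
  Xs <- unclass(eq$state)[[variable]]
  if (Xs == 0)
    stop("normalized index undefined: ", variable, "* = 0 at this point",
         call. = FALSE)
  pval <- p[[parameter]]

  if (method == "closed_form") {
    dlam_dp <- if (parameter == "rho") -1 / p$k else p$rho / p$k^2
    dX_dlam <- steady_state_dlambda(eq$lambda, p)[[variable]]
    return(dX_dlam * dlam_dp * pval / Xs)
  }

  h <- 1e-6
  up <- do.call(update_params,
                c(list(p), stats::setNames(list(pval * (1 + h)), parameter)))
  dn <- do.call(update_params,
                c(list(p), stats::setNames(list(pval * (1 - h)), parameter)))
  Xu <- unclass(steady_state(up)$state)[[variable]]
  Xd <- unclass(steady_state(dn)$state)[[variable]]
  (Xu - Xd) / (2 * h * pval) * pval / Xs
}

#' Classical closed form for SI(H*; rho)
#'
#' Direct evaluation of
#' `-eta k rho (delta_Z + r) / ((k (delta_Z + eta) - eta rho)(k (eta - r) - eta rho))`,
#' kept as an independent expression for cross-checking
#' [sensitivity_index()].
#'
#' @param params A `liver_params`.
#' @return The index value.
#' @export
sensitivity_H_rho_reference <- function(params) {
  p <- params
  -p$eta * p$k * p$rho * (p$delta_Z + p$r) /
    ((p$k * (p$delta_Z + p$eta) - p$eta * p$rho) *
       (p$k * (p$eta - p$r) - p$eta * p$rho))
}

#' Table of sensitivity indices
#'
#' Indices of every defined equilibrium variable with respect to `rho` and
#' `k` at the given evaluation point.
#'
#' @param params A `liver_params` (the evaluation point).
#' @param method Passed to [sensitivity_index()].
#' @return A data frame with columns `variable`, `parameter`, `index`;
#'   undefined combinations are dropped.
#' @export
sensitivity_table <- function(params, method = "closed_form") {
  rows <- expand.grid(variable = STATE_NAMES, parameter = c("rho", "k"),
                      stringsAsFactors = FALSE)
  rows$index <- vapply(seq_len(nrow(rows)), function(i) {
    tryCatch(sensitivity_index(rows$variable[i], rows$parameter[i], params,
                               method = method),
             error = function(e) NA_real_)
  }, numeric(1))
  rows[!is.na(rows$index), , drop = FALSE]
}
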