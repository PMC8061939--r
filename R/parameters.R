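#' Model parameters for the ischaemic-hepatitis ODE system
#'
#' Constructs the full parameter set of the six-state liver model: ATP
#' production/consumption, hepatocyte regeneration and necrosis, damaged-cell
#' lysis, biomarker release and clearance, and the oxygen-return schedule.
#' The defaults are the literature-derived reference values used throughout
#' the package; calling `model_parameters()` with no arguments reproduces
#' them exactly.
#'
#' All rates are per day and the internal time unit is days. The treatment
#' time `tau` may be `Inf`, meaning no treatment is ever given and the oxygen
#' fraction stays at `O0` forever.
#'
#' @param A_norm Total ATP in a healthy liver (pmol).
#' @param rho ATP production rate (pmol/cell/day).
#' @param k ATP consumption rate (pmol/cell/day). The healthy equilibrium
#'   requires `rho == k`.
#' @param r Hepatocyte regeneration rate (1/day).
#' @param eta Necrosis rate (1/day); scales death of healthy hepatocytes by
#'   the relative ATP deficit `1 - A/A_norm`.
#' @param delta_Z Damaged-hepatocyte lysis rate (1/day); lysis also releases
#'   AST and ALT into serum.
#' @param H_max Maximum number of hepatocytes in a healthy liver (cells).
#' @param theta Blood volume (L).
#' @param delta_S,delta_L,delta_D Serum clearance rates of AST, ALT, LDH (1/day).
#' @param beta_S,beta_L Total AST and ALT content of a healthy liver (IU).
#' @param beta_D LDH production scale (IU).
#' @param S_min,L_min,D_min Minimum (baseline) serum levels (IU/L).
#' @param D_max Maximum serum LDH level (IU/L); LDH production saturates here.
#' @param O0 Initial (pre-treatment) oxygen fraction, > 0. Values above 1 are
#'   accepted but outside the validated regime.
#' @param epsilon Oxygen-return rate of the logistic treatment response (1/day).
#' @param tau Treatment time in days; `Inf` for no treatment.
#' @param tau_hours Optional convenience: treatment time in hours; overrides
#'   `tau` when given.
#' @param c_reperfusion Reperfusion damage scale (dimensionless). The
#'   reperfusion-extended model transfers `c_reperfusion * |dO/dt| * H`
#'   cells/day from healthy to damaged; over a full oxygen return this kills
#'   roughly the fraction `1 - exp(-c_reperfusion * |1 - O0|)` of the healthy
#'   cells present at treatment.
#'
#' @return An object of class `liver_params`: a named list of validated
#'   parameters with `tau` in days.
#' @examples
#' p <- model_parameters()
#' p$eta
#' p8 <- model_parameters(O0 = 0.5, tau_hours = 8)
#' @export
model_parameters <- function(A_norm = 1.6e9,
                             rho = 1.43,
                             k = 1.43,
                             r = 1,
                             eta = 6.381,
                             delta_Z = 5,
                             H_max = 1.6e11,
                             theta = 5,
                             delta_S = 0.92,
                             delta_L = 0.35,
                             delta_D = 0.459,
                             beta_S = 20000,
                             beta_L = 9000,
                             beta_D = 200000,
                             S_min = 12,
                             L_min = 9,
                             D_min = 120,
                             D_max = 30000,
                             O0 = 0.5,
                             epsilon = 20,
                             tau = Inf,
                             tau_hours = NULL,
                             c_reperfusion = 0) {
  if (!is.null(tau_hours)) tau <- tau_hours / 24
  p <- list(
    A_norm = A_norm, rho = rho, k = k, r = r, eta = eta, delta_Z = delta_Z,
    H_max = H_max, theta = theta, delta_S = delta_S, delta_L = delta_L,
    delta_D = delta_D, beta_S = beta_S, beta_L = beta_L, beta_D = beta_D,
    S_min = S_min, L_min = L_min, D_min = D_min, D_max = D_max,
    O0 = O0, epsilon = epsilon, tau = tau, c_reperfusion = c_reperfusion
  )
  validate_params(p)
  class(p) <- "liver_params"
  p
}

validate_params <- function(p) {
  pos <- c("A_norm", "rho", "k", "r", "eta", "delta_Z", "H_max", "theta",
           "delta_S", "delta_L", "delta_D", "beta_S", "beta_L", "beta_D",
           "D_max", "O0", "epsilon")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  for (nm in c("S_min", "L_min", "D_min", "c_reperfusion")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative number",
           call. = FALSE)
  }
  if (p$D_min >= p$D_max) stop("D_min must be smaller than D_max", call. = FALSE)
  if (!(is.numeric(p$tau) && length(p$tau) == 1L && !is.na(p$tau) && p$tau >= 0))
    stop("tau must be a single nonnegative number (Inf for no treatment)",
         call. = FALSE)
  if (p$O0 > 1)
    warning("O0 > 1 is outside the validated regime of the model",
            call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Convenience update of a `liver_params` object; revalidates the result.
#'
#' @param params A `liver_params` object.
#' @param ... Named parameter replacements, plus optionally `tau_hours`.
#' @return An updated `liver_params` object.
#' @examples
#' p <- update_params(model_parameters(), O0 = 0.3, tau_hours = 8)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "liver_params"))
  upd <- list(...)
  if ("tau_hours" %in% names(upd)) {
    upd$tau <- upd$tau_hours / 24
    upd$tau_hours <- NULL
  }
  unknown <- setdiff(names(upd), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  params[names(upd)] <- upd
  validate_params(params)
  class(params) <- "liver_params"
  params
}

#' @export
print.liver_params <- function(x, ...) {
  cat("<liver_params>\n")
  tau_lab <- if (is.finite(x$tau)) sprintf("%.4g h", x$tau * 24) else "none (Inf)"
  cat(sprintf("  oxygen: O0 = %.3g, epsilon = %.3g /day, treatment = %s\n",
              x$O0, x$epsilon, tau_lab))
  cat(sprintf("  ATP: A_norm = %.3g pmol, rho = %.3g, k = %.3g pmol/cell/day\n",
              x$A_norm, x$rho, x$k))
  cat(sprintf("  hepatocytes: H_max = %.3g cells, r = %.3g, eta = %.3g, delta_Z = %.3g /day\n",
              x$H_max, x$r, x$eta, x$delta_Z))
  cat(sprintf("  biomarkers: beta_S/L/D = %.3g/%.3g/%.3g IU, clearance %.3g/%.3g/%.3g /day\n",
              x$beta_S, x$beta_L, x$beta_D, x$delta_S, x$delta_L, x$delta_D))
  cat(sprintf("  reperfusion scale c = %.3g\n", x$c_reperfusion))
  invisible(x)
}

#' State of the liver model at one time point
#'
#' @param A ATP (pmol).
#' @param H Healthy hepatocytes (cells).
#' @param Z Damaged hepatocytes (cells).
#' @param S Serum AST (IU/L).
#' @param L Serum ALT (IU/L).
#' @param D Serum LDH (IU/L).
#' @return A named numeric vector of class `liver_state` with components
#'   `A, H, Z, S, L, D`, all nonnegative.
#' @export
liver_state <- function(A, H, Z, S, L, D) {
  x <- c(A = A, H = H, Z = Z, S = S, L = L, D = D)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all state components must be finite and nonnegative", call. = FALSE)
  class(x) <- "liver_state"
  x
}

#' Canonical healthy initial state
#'
#' The initial condition used for every simulation unless overridden: full
#' ATP, full healthy hepatocyte pool, no damaged cells, biomarkers at their
#' baseline minima.
#'
#' @param params A `liver_params` object.
#' @return A `liver_state`.
#' @export
canonical_state <- function(params) {
  liver_state(A = params$A_norm, H = params$H_max, Z = 0,
              S = params$S_min, L = params$L_min, D = params$D_min)
}

#' Read / write parameter files
#'
#' Flat key/value YAML with the treatment time given as `tau_hours`. The file
#' shipped at `system.file("extdata", "default_params.yaml", package =
#' "hepasim")` holds the package defaults.
#'
#' @param path File path.
#' @return `read_params()` returns a `liver_params`.
#' @export
read_params <- function(path) {
  kv <- yaml::yaml.load_file(path)
  kv <- lapply(kv, function(v) if (identical(v, ".inf") || identical(v, "Inf")) Inf else v)
  do.call(model_parameters, kv)
}

#' @rdname read_params
#' @param params A `liver_params` to serialize.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "liver_params"))
  kv <- unclass(params)
  kv$tau_hours <- kv$tau * 24
  kv$tau <- NULL
  yaml::write_yaml(kv, path)
  invisible(path)
}
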