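#' Arrhenius damage-kinetics parameters
#'
#' First-order thermal damage: the damage integral accumulates at rate
#' `A * exp(-E_a / (R * T_K))`. The defaults are the classical Henriques
#' protein-coagulation constants, used as configuration stand-ins for
#' patient-specific values; the activation energy is deliberately exposed
#' since damage predictions are sensitive to it.
#'
#' @param A Frequency factor, 1/s.
#' @param E_a Activation energy, J/mol.
#' @return A list with class `litt_arrhenius` (gas constant fixed at 8.314).
#' @export
arrhenius_params <- function(A = 3.1e98, E_a = 6.28e5) {
  stopifnot(A > 0, E_a > 0)
  structure(list(A = A, E_a = E_a, R = 8.314), class = "litt_arrhenius")
}

arrhenius_rate <- function(T_celsius, params) {
  params$A * exp(-params$E_a / (params$R * (T_celsius + 273.15)))
}

#' Accumulate the Arrhenius damage integral over one time step
#'
#' Trapezoid rule between the temperatures at the start and end of the step:
#' `alpha' = alpha + dt/2 * (rate(T_start) + rate(T_end))`, voxel-wise.
#' Temperatures are in deg C and converted to kelvin internally.
#'
#' @param alpha Damage integral (dimensionless, >= 0), vector.
#' @param T_start,T_end Temperatures at step endpoints, deg C.
#' @param params An [arrhenius_params()].
#' @param dt Step length, s.
#' @param rule `"trapezoid"` (default) or `"rectangle"` (left endpoint, for
#'   cross-checks).
#' @return Updated damage integral.
#' @export
accumulate_damage <- function(alpha, T_start, T_end, params = arrhenius_params(),
                              dt = 1, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (rule == "trapezoid")
    alpha + dt * 0.5 * (arrhenius_rate(T_start, params) +
                          arrhenius_rate(T_end, params))
  else
    alpha + dt * arrhenius_rate(T_start, params)
}

#' Damage fraction from the damage integral
#'
#' `Omega = 1 - exp(-alpha)` is the modeled cell-death fraction, so
#' `1 - Omega` is the survival probability. The clinical retraction
#' threshold `Omega >= 0.99` corresponds to `alpha >= -log(0.01) = 4.60517`.
#'
#' @param alpha Damage integral (>= 0).
#' @return Damage fraction in `[0, 1)`.
#' @export
omega <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be non-negative")
  -expm1(-alpha)
}

#' Log survival probability
#'
#' `log(1 - Omega) = -alpha`, the transform under which propagated damage
#' distributions are approximately Gaussian.
#'
#' @param omega_val Damage fraction; values equal to 1 map to `-Inf` with a
#'   warning.
#' @return `log(1 - Omega)`.
#' @export
log_survival <- function(omega_val) {
  if (any(omega_val < 0 | omega_val > 1))
    stop("omega must lie in [0, 1]")
  if (any(omega_val == 1))
    warning("omega = 1 encountered; log survival is -Inf there")
  log1p(-omega_val)
}

#' Damage-dependent perfusion factor
#'
#' Microvascular shutdown: perfusion in the tumor and the peritumoral brain
#' margin is multiplied by `1 - Omega`; elsewhere the factor is 1.
#'
#' @param omega_val Per-cell damage fraction in `[0, 1]`.
#' @param geom Internal geometry (carries the tumor + peritumoral mask,
#'   default margin 5 mm).
#' @return Per-cell multiplicative factor.
#' @export
perfusion_factor <- function(omega_val, geom) {
  if (any(omega_val < 0 | omega_val > 1)) {
    warning("damage fraction outside [0, 1]; clipping")
    omega_val <- pmin(pmax(omega_val, 0), 1)
  }
  fac <- rep(1, geom$n)
  fac[geom$peritumoral] <- 1 - omega_val[geom$peritumoral]
  fac
}
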