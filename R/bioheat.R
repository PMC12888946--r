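#' Solver configuration for the bioheat time stepper
#'
#' @param dt Time step, s. The clinical MR-thermometry cadence of 1 s is the
#'   default and also the controller sampling period.
#' @param scheme `"bdf2"` (second-order backward differences, bootstrapped
#'   with one backward-Euler step) or `"backward_euler"`.
#' @param prop_cap Temperature (deg C) above which the exponential
#'   temperature-dependent properties are frozen at their cap value.
#' @return A list with class `litt_solver_config`.
#' @export
solver_config <- function(dt = 1, scheme = c("bdf2", "backward_euler"),
                          prop_cap = 90) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0)
  structure(list(dt = dt, scheme = scheme, prop_cap = prop_cap),
            class = "litt_solver_config")
}

#' Boundary conditions for the head phantom
#'
#' Robin (third-kind) conditions: the outer skull surface exchanges with the
#' room, and the cooled catheter wall exchanges with the coolant along the
#' active 5 mm tip only (the shaft above the tip is adiabatic).
#'
#' @param h_outer Skull-surface convection coefficient, W/(m^2 K).
#' @param t_outer Ambient temperature, deg C.
#' @param h_catheter Catheter-wall convection coefficient, W/(m^2 K).
#' @param t_catheter Coolant temperature, deg C.
#' @return A list with class `litt_bc`.
#' @export
boundary_conditions <- function(h_outer = 5, t_outer = 20,
                                h_catheter = 100, t_catheter = 20) {
  stopifnot(h_outer >= 0, h_catheter >= 0)
  structure(list(h_outer = h_outer, t_outer = t_outer,
                 h_catheter = h_catheter, t_catheter = t_catheter),
            class = "litt_bc")
}

# Temperature-dependent properties, exponential in (T - 37), frozen at their
# prop_cap value above prop_cap (vaporization-regime decrease not modeled).
cell_conductivity <- function(geom, T, cap = 90) {
  Tc <- pmin(T, cap)
  geom$k0 * exp(geom$coeff_k * (Tc - 37)) * geom$enh
}

cell_heat_capacity <- function(geom, T, cap = 90) {
  Tc <- pmin(T, cap)
  geom$cp0 * exp(geom$coeff_c * (Tc - 37))
}

#' One implicit step of the modified Pennes bioheat equation
#'
#' Advances `rho*Cp dT/dt = div(k grad T) + rho_b*Cp_b*omega*(T_b - T)
#' + Q_laser + Q_met` on the phantom's face graph. Thermal properties are
#' evaluated at the previous temperature (single Picard lag); conductivity in
#' CSF carries the convective-enhancement multiplier; perfusion in tumor and
#' peritumoral cells is scaled by the damage-dependent factor.
#'
#' @param state List with `T` (per-cell temperature, deg C), `t` (s) and
#'   optionally `T_prev` (for BDF2).
#' @param geom Geometry from the internal face-graph builder (created by the
#'   run drivers; see [run_replay()]).
#' @param q_laser Per-cell volumetric laser power, W/m^3 (0 if absent).
#' @param bc A [boundary_conditions()] plus the active tip (`tip_z`, m) used
#'   to gate the catheter Robin faces.
#' @param blood A [blood_properties()].
#' @param perf_factor Per-cell multiplicative perfusion factor (damage
#'   coupling), default 1.
#' @param cfg A [solver_config()].
#' @param tip_z Axial position (m) of the active tip center; `NA` disables
#'   catheter cooling.
#' @param tip_length Active tip length, m.
#' @return List: `state` (updated), `budget` (per-step energy terms, W).
#' @export
bioheat_step <- function(state, geom, q_laser = NULL, bc = boundary_conditions(),
                         blood = blood_properties(), perf_factor = NULL,
                         cfg = solver_config(), tip_z = NA, tip_length = 5e-3) {
  n <- geom$n
  Tn <- state$T
  if (is.null(q_laser)) q_laser <- numeric(n)
  if (is.null(perf_factor)) perf_factor <- rep(1, n)
  dt <- cfg$dt

  k <- cell_conductivity(geom, Tn, cfg$prop_cap)
  cp <- cell_heat_capacity(geom, Tn, cfg$prop_cap)
  rhoc_v <- geom$rho * cp * geom$vol

  f <- geom$faces
  # series (harmonic) conductance across each interior face
  G <- f$area / (f$d / (2 * k[f$a]) + f$d / (2 * k[f$b]))

  bf <- geom$bfaces
  bG <- numeric(nrow(bf))
  bT <- numeric(nrow(bf))
  outer <- bf$kind == "outer"
  if (any(outer)) {
    hs <- bc$h_outer
    bG[outer] <- if (hs > 0)
      bf$area[outer] / (1 / hs + bf$dh[outer] / k[bf$cell[outer]]) else 0
    bT[outer] <- bc$t_outer
  }
  lum <- bf$kind == "lumen"
  if (any(lum) && !is.na(tip_z)) {
    act <- lum & bf$fz >= tip_z - tip_length / 2 & bf$fz <= tip_z + tip_length / 2
    if (any(act)) {
      hc <- bc$h_catheter
      bG[act] <- if (hc > 0)
        bf$area[act] / (1 / hc + bf$dh[act] / k[bf$cell[act]]) else 0
      bT[act] <- bc$t_catheter
    }
  }

  perf <- blood$density * blood$heat_capacity * geom$perf0 * perf_factor *
    geom$vol
  src <- q_laser * geom$vol + geom$qmet * geom$vol

  if (cfg$scheme == "bdf2" && !is.null(state$T_prev)) {
    c0 <- 1.5 * rhoc_v / dt
    rhs_t <- (2 * Tn - 0.5 * state$T_prev) * rhoc_v / dt
  } else {
    c0 <- rhoc_v / dt
    rhs_t <- Tn * rhoc_v / dt
  }

  diag_extra <- c0 + perf
  bsum <- numeric(n)
  if (nrow(bf) > 0) {
    agg <- rowsum(bG, bf$cell)
    bsum[as.integer(rownames(agg))] <- agg[, 1]
  }
  A <- Matrix::sparseMatrix(
    i = c(f$a, f$b, f$a, f$b, seq_len(n)),
    j = c(f$a, f$b, f$b, f$a, seq_len(n)),
    x = c(G, G, -G, -G, diag_extra + bsum),
    dims = c(n, n))
  rhs <- rhs_t + perf * blood$temperature + src
  if (nrow(bf) > 0) {
    radd <- rowsum(bG * bT, bf$cell)
    rhs[as.integer(rownames(radd))] <- rhs[as.integer(rownames(radd))] + radd[, 1]
  }
  Tn1 <- as.numeric(Matrix::solve(Matrix::forceSymmetric(A), rhs))
  if (any(!is.finite(Tn1)))
    stop("linear solve produced non-finite temperatures (residual check failed)")

  budget <- list(
    storage = sum(rhoc_v * (Tn1 - Tn)) / dt,
    boundary = sum(bG * (bT - Tn1[bf$cell])),
    perfusion = sum(perf * (blood$temperature - Tn1)),
    laser = sum(q_laser * geom$vol),
    metabolic = sum(geom$qmet * geom$vol)
  )

  list(state = list(T = Tn1, T_prev = Tn, t = state$t + dt), budget = budget)
}

# 1-D spherically symmetric geometry (finite-volume shells) used by the
# solver verification; reuses bioheat_step through the same face-graph
# contract as the phantom geometries.
sphere_geometry <- function(r_max, dr, k = 0.5, rho_c = 1e5,
                            w_rho_cb = 2000, q_met = 0) {
  nrr <- as.integer(round(r_max / dr))
  r_in <- (seq_len(nrr) - 1) * dr
  r_out <- seq_len(nrr) * dr
  rc <- (r_in + r_out) / 2
  vol <- 4 / 3 * pi * (r_out^3 - r_in^3)
  faces <- data.frame(a = seq_len(nrr - 1), b = 2:nrr,
                      area = 4 * pi * r_out[-nrr]^2, d = dr)
  # outer shell: effectively-Dirichlet Robin face (large h) pinned at T_b
  bfaces <- data.frame(cell = nrr, area = 4 * pi * r_out[nrr]^2, dh = dr / 2,
                       kind = "outer", fz = 0)
  structure(list(
    n = nrr, mode = "spherical_1d", coords = cbind(r = rc), vol = vol,
    label = rep("brain", nrr), faces = faces, bfaces = bfaces,
    grid = list(dr = dr),
    rho = rep(1, nrr), cp0 = rep(rho_c, nrr), k0 = rep(k, nrr),
    enh = rep(1, nrr), perf0 = rep(w_rho_cb, nrr), qmet = rep(q_met, nrr),
    coeff_k = rep(0, nrr), coeff_c = rep(0, nrr),
    tumor = rep(FALSE, nrr), peritumoral = rep(FALSE, nrr)
  ), class = "litt_geometry")
}

#' Closed-form steady temperature of a point source in perfused tissue
#'
#' Steady-state Pennes solution for a constant point source of power `P` in
#' an infinite homogeneous perfused medium:
#' `T(r) = T_b + P * exp(-lambda*r) / (4*pi*k*r)` with
#' `lambda = sqrt(omega*rho_b*Cp_b / k)`.
#'
#' @param r Radius, m (> 0).
#' @param P Source power, W.
#' @param k Conductivity, W/(m K).
#' @param w_rho_cb Perfusion volumetric heat-transfer coefficient
#'   `omega*rho_b*Cp_b`, W/(m^3 K).
#' @param t_b Blood/baseline temperature, deg C.
#' @return Temperature, deg C.
#' @export
analytic_point_source_steady <- function(r, P, k, w_rho_cb = 0, t_b = 37) {
  if (any(r <= 0)) stop("r must be positive (solution is singular at r = 0)")
  lambda <- sqrt(w_rho_cb / k)
  t_b + P * exp(-lambda * r) / (4 * pi * k * r)
}

#' Verify the bioheat solver against the closed-form point-source solution
#'
#' Runs the finite-volume solver on a fine 1-D spherically symmetric grid
#' with a constant point source (deposited in the innermost shell) to steady
#' state, then reports the maximum relative error
#' `|T_num - T_analytic| / (T_analytic - T_b)` over all cell centers in
#' `r_check` (source cell excluded).
#'
#' The relaxation to steady state is independent of the volumetric heat
#' capacity, which is therefore set small so the transient decays in a few
#' hundred 1 s steps.
#'
#' @param dr Grid spacing, m (default 0.1 mm).
#' @param r_max Domain radius, m (far enough that the perfusion-screened
#'   solution has decayed at the boundary).
#' @param P Source power, W.
#' @param k Conductivity, W/(m K).
#' @param w_rho_cb Perfusion coefficient, W/(m^3 K).
#' @param r_check Range (m) of radii over which the error is evaluated.
#' @param cfg A [solver_config()].
#' @param steady_tol Per-step max temperature change (K) declaring steady
#'   state.
#' @param max_steps Step budget.
#' @return List: `max_rel_error_pct`, and a tibble `profile` with columns
#'   `r`, `T_num`, `T_analytic`.
#' @export
verify_solver <- function(dr = 1e-4, r_max = 0.15, P = 1, k = 0.5,
                          w_rho_cb = 2000, r_check = c(3e-3, 15e-3),
                          cfg = solver_config(), steady_tol = 1e-9,
                          max_steps = 20000L) {
  t_b <- 37
  geom <- sphere_geometry(r_max, dr, k = k, rho_c = 1e5, w_rho_cb = w_rho_cb)
  # pin the outer face at the analytic far-field value via a huge film
  # coefficient (equals T_b to ~1e-5 for perfused media, and keeps the
  # pure-conduction 1/r limit exact on a finite domain)
  t_pin <- analytic_point_source_steady(r_max, P, k, w_rho_cb, t_b)
  bc <- boundary_conditions(h_outer = 1e12, t_outer = t_pin,
                            h_catheter = 0, t_catheter = t_pin)
  blood <- blood_properties(density = 1, heat_capacity = 1, temperature = t_b)
  q <- numeric(geom$n)
  q[1] <- P / geom$vol[1]
  state <- list(T = rep(t_b, geom$n), T_prev = NULL, t = 0)
  for (s in seq_len(max_steps)) {
    out <- bioheat_step(state, geom, q_laser = q, bc = bc, blood = blood,
                        cfg = cfg)
    delta <- max(abs(out$state$T - state$T))
    state <- out$state
    if (delta < steady_tol) break
  }
  rc <- geom$coords[, "r"]
  sel <- rc >= r_check[1] & rc <= r_check[2]
  sel[1] <- FALSE
  Ta <- analytic_point_source_steady(rc[sel], P, k, w_rho_cb, t_b)
  err <- abs(state$T[sel] - Ta) / (Ta - t_b)
  list(max_rel_error_pct = 100 * max(err),
       steps = s,
       profile = tibble::tibble(r = rc[sel], T_num = state$T[sel],
                                T_analytic = Ta))
}
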