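# Treatment run drivers: shared physics loop, clinical-log replay, and the
# closed-loop PID + fuzzy-retraction controller.

sim_setup <- function(phantom, materials = default_materials(),
                      blood = blood_properties(),
                      optics = optical_model(),
                      damage = arrhenius_params(),
                      solver = solver_config(),
                      bc = boundary_conditions(),
                      probes = NULL, peritumoral_margin = 5e-3) {
  geom <- phantom_geometry(phantom, materials, peritumoral_margin)
  if (is.null(probes)) probes <- place_probes(phantom)
  pcells <- lapply(probes, function(p) list(
    cp = mask_cells(geom, p$cp), bp = mask_cells(geom, p$bp)))
  list(phantom = phantom, geom = geom, blood = blood, optics = optics,
       damage = damage, solver = solver, bc = bc, probes = probes,
       pcells = pcells)
}

probe_read <- function(geom, values, cells) {
  sum(values[cells] * geom$vol[cells]) / sum(geom$vol[cells])
}

# One physics step shared by both drivers: deposition (cached), bioheat,
# damage, couplings. `sim` carries mutable caches in `env`.
physics_step <- function(env, setup, power, tip_z) {
  geom <- setup$geom
  mu <- mueff_field(setup$optics, env$omega_cells, geom)
  need <- is.null(env$dep_unit) || !identical(env$dep_tip, tip_z) ||
    (max(abs(mu - env$dep_mu) / pmax(env$dep_mu, 1e-12)) > env$recompute_tol)
  if (need) {
    src <- laser_source(env$source_model, power = 1, tip_z = tip_z,
                        n_sub = env$n_sub)
    env$dep_unit <- compute_deposition(src, mu, geom)
    env$dep_tip <- tip_z
    env$dep_mu <- mu
  }
  q <- env$dep_unit$q * power
  pf <- perfusion_factor(env$omega_cells, geom)
  out <- bioheat_step(env$state, geom, q_laser = q, bc = setup$bc,
                      blood = setup$blood, perf_factor = pf,
                      cfg = setup$solver, tip_z = tip_z)
  T_old <- env$state$T
  env$state <- out$state
  env$alpha <- accumulate_damage(env$alpha, T_old, env$state$T,
                                 setup$damage, setup$solver$dt)
  env$omega_cells <- omega(env$alpha)
  invisible(out$budget)
}

new_sim_env <- function(setup, source_model = "pslh", n_sub = 10L,
                        recompute_tol = 0.01, t_init = 37) {
  env <- new.env(parent = emptyenv())
  env$state <- list(T = rep(t_init, setup$geom$n), T_prev = NULL, t = 0)
  env$alpha <- numeric(setup$geom$n)
  env$omega_cells <- numeric(setup$geom$n)
  env$dep_unit <- NULL; env$dep_tip <- NULL
  env$dep_mu <- rep(1, setup$geom$n)
  env$source_model <- source_model
  env$n_sub <- n_sub
  env$recompute_tol <- recompute_tol
  env
}

probe_row <- function(env, setup) {
  g <- setup$geom
  tc <- vapply(setup$pcells, function(p) probe_read(g, env$state$T, p$cp),
               numeric(1))
  tb <- vapply(setup$pcells, function(p) probe_read(g, env$state$T, p$bp),
               numeric(1))
  ob <- vapply(setup$pcells, function(p) probe_read(g, env$omega_cells, p$bp),
               numeric(1))
  list(t_cp = tc, t_bp = tb, omega_bp = ob)
}

milestones_update <- function(ms, pr, t, t_setpoint, omega_setpoint) {
  for (j in 1:3) {
    if (is.na(ms$t_setpoint_s[j]) && pr$t_bp[j] >= t_setpoint)
      ms$t_setpoint_s[j] <- t
    if (is.na(ms$omega_setpoint_s[j]) && pr$omega_bp[j] >= omega_setpoint)
      ms$omega_setpoint_s[j] <- t
  }
  ms
}

finalize_run <- function(env, setup, series_rows, metrics_extra, kind) {
  series <- dplyr::bind_rows(series_rows)
  g <- setup$geom
  lc <- lesion_coverage_cells(env$omega_cells, g)
  metrics <- c(list(
    lc_percent = lc,
    total_time_s = env$state$t,
    energy_J = sum(series$power_W) * setup$solver$dt,
    max_cp_C = max(series$t_cp1, series$t_cp2, series$t_cp3)
  ), metrics_extra)
  structure(list(kind = kind, series = series, metrics = metrics,
                 final = list(T = env$state$T, alpha = env$alpha,
                              omega = env$omega_cells),
                 setup = setup),
            class = "litt_run")
}

series_row <- function(env, setup, power, tip_z, stage, pr, extra = NULL) {
  row <- tibble::tibble(
    t_s = env$state$t, power_W = power, tip_z_mm = tip_z * 1e3,
    stage = stage,
    t_cp1 = pr$t_cp[1], t_cp2 = pr$t_cp[2], t_cp3 = pr$t_cp[3],
    t_bp1 = pr$t_bp[1], t_bp2 = pr$t_bp[2], t_bp3 = pr$t_bp[3],
    omega_bp1 = pr$omega_bp[1], omega_bp2 = pr$omega_bp[2],
    omega_bp3 = pr$omega_bp[3])
  if (!is.null(extra)) row <- dplyr::bind_cols(row, tibble::as_tibble(extra))
  row
}

#' Replay a clinical-style laser log through the simulator (open loop)
#'
#' Drives the laser power and tip position from the log breakpoints (power
#' interpolated linearly, tip stepwise) and advances the full physics:
#' deposition, bioheat, Arrhenius damage, damage-dependent perfusion and
#' (in `"vop"` mode) damage-dependent attenuation.
#'
#' @param phantom A `litt_phantom`.
#' @param log A `litt_laser_log` (see [read_laser_log()],
#'   [make_fixture_log()]). Tip positions are in mm.
#' @param materials,blood,optics,damage,solver,bc Physics configuration; see
#'   [default_materials()], [blood_properties()], [optical_model()],
#'   [arrhenius_params()], [solver_config()], [boundary_conditions()].
#' @param source_model `"pslh"` or `"dphs"`.
#' @param n_sub DPHS sub-source count.
#' @param t_end Simulation end, s; defaults to the log's last breakpoint
#'   (the log must span the window).
#' @param recompute_tol Maximum relative attenuation drift before the
#'   deposition field is recomputed.
#' @param peritumoral_margin Width (m) of the brain margin around the tumor
#'   subject to damage-dependent perfusion shutdown.
#' @return A `litt_run`: tibble time series (`series`), outcome `metrics`
#'   (lesion coverage, energy, milestones), final fields.
#' @export
run_replay <- function(phantom, log, materials = default_materials(),
                       blood = blood_properties(), optics = optical_model(),
                       damage = arrhenius_params(), solver = solver_config(),
                       bc = boundary_conditions(), source_model = "pslh",
                       n_sub = 10L, t_end = NULL, recompute_tol = 0.01,
                       peritumoral_margin = 5e-3) {
  validate_laser_log(log)
  if (is.null(t_end)) t_end <- max(log$t_s)
  if (t_end > max(log$t_s))
    stop("laser log ends at ", max(log$t_s), " s, before t_end = ", t_end)
  setup <- sim_setup(phantom, materials, blood, optics, damage, solver, bc,
                     peritumoral_margin = peritumoral_margin)
  env <- new_sim_env(setup, source_model, n_sub, recompute_tol)
  dt <- solver$dt
  nsteps <- ceiling(t_end / dt)
  rows <- vector("list", nsteps)
  ms <- list(t_setpoint_s = rep(NA_real_, 3),
             omega_setpoint_s = rep(NA_real_, 3))
  for (s in seq_len(nsteps)) {
    tm <- (s - 0.5) * dt
    cmd <- log_at(log, tm)
    tip_z <- cmd$tip_z_mm * 1e-3
    stage <- match(cmd$tip_z_mm, sort(unique(log$tip_z_mm)))
    physics_step(env, setup, cmd$power_W, tip_z)
    pr <- probe_row(env, setup)
    ms <- milestones_update(ms, pr, env$state$t, 60, 0.99)
    rows[[s]] <- series_row(env, setup, cmd$power_W, tip_z, stage, pr)
  }
  extra <- list(milestones = ms, energy_commanded_J = log_energy(log, t_end),
                complete = TRUE)
  run <- finalize_run(env, setup, rows, extra, kind = "replay")
  run$metrics$energy_J <- extra$energy_commanded_J
  run
}

#' Run the automated PID + fuzzy-retraction treatment (closed loop)
#'
#' Per 1 s controller tick: read the virtual MRTi probe voxels; regulate the
#' hottest monitored boundary probe to the temperature setpoint with the PID
#' law; gate the commanded power to zero while any monitored center probe is
#' at the 100 degree cap (latched with hysteresis); deposit, advance the
#' bioheat equation and accumulate damage; then let the fuzzy retraction
#' controller act on the active boundary-probe damage: at the 0.99 setpoint
#' the probe retracts 5 mm (stages 1 and 2, PID integral reset) or the
#' treatment stops (stage 3).
#'
#' @inheritParams run_replay
#' @param control A [pid_config()].
#' @param t_max Step budget, s; reaching it before STOP flags the run
#'   incomplete.
#' @param feedback_delay_steps Optional MRTi acquisition lag, in controller
#'   ticks (0 = ideal feedback).
#' @return A `litt_run` with controller columns in the series.
#' @export
run_controlled <- function(phantom, materials = default_materials(),
                           blood = blood_properties(),
                           optics = optical_model(),
                           damage = arrhenius_params(),
                           solver = solver_config(),
                           bc = boundary_conditions(),
                           control = pid_config(), source_model = "pslh",
                           n_sub = 10L, t_max = 7200, recompute_tol = 0.01,
                           feedback_delay_steps = 0L,
                           peritumoral_margin = 5e-3) {
  setup <- sim_setup(phantom, materials, blood, optics, damage, solver, bc,
                     peritumoral_margin = peritumoral_margin)
  env <- new_sim_env(setup, source_model, n_sub, recompute_tol)
  dt <- solver$dt
  track <- phantom$track
  stage <- 1L
  tip_z <- track$stage_z[1]
  pid <- pid_state()
  gate <- safety_gate_state()
  rows <- list()
  ms <- list(t_setpoint_s = rep(NA_real_, 3),
             omega_setpoint_s = rep(NA_real_, 3))
  retraction_times <- numeric(0)
  complete <- FALSE
  delay_buf <- list()
  pr <- probe_row(env, setup)
  nsteps <- ceiling(t_max / dt)
  for (s in seq_len(nsteps)) {
    # feedback (optionally delayed by the MRTi acquisition lag)
    fb <- pr
    if (feedback_delay_steps > 0) {
      delay_buf[[length(delay_buf) + 1]] <- pr
      if (length(delay_buf) > feedback_delay_steps) {
        fb <- delay_buf[[1]]
        delay_buf <- delay_buf[-1]
      } else fb <- probe_row(env, setup)  # warm-up: latest available
    }
    ref <- select_reference(fb$t_bp, stage)
    e <- control$t_setpoint - ref
    ps <- pid_step(control, pid, e, dt)
    pid <- ps$state
    gs <- safety_gate(gate, ps$power, fb$t_cp[seq_len(stage)],
                      cap = control$t_cap, hysteresis = control$hysteresis)
    gate <- gs$gate
    power <- gs$power
    physics_step(env, setup, power, tip_z)
    pr <- probe_row(env, setup)
    ms <- milestones_update(ms, pr, env$state$t, control$t_setpoint,
                            control$omega_setpoint)
    rows[[s]] <- series_row(env, setup, power, tip_z, stage, pr,
                            extra = list(reference_C = ref,
                                         gate_latched = gate$latched))
    decision <- fuzzy_decision(pr$omega_bp[stage], stage)
    if (decision == "retract") {
      stage <- stage + 1L
      tip_z <- track$stage_z[stage]
      pid <- pid_state()        # new plant after retraction
      retraction_times <- c(retraction_times, env$state$t)
    } else if (decision == "stop") {
      complete <- TRUE
      break
    }
  }
  extra <- list(milestones = ms, retraction_times_s = retraction_times,
                n_retractions = length(retraction_times),
                complete = complete)
  finalize_run(env, setup, rows[!vapply(rows, is.null, logical(1))],
               extra, kind = "controlled")
}

lesion_coverage_cells <- function(omega_cells, geom, threshold = 0.99) {
  tum <- geom$tumor
  if (!any(tum)) stop("phantom has no tumor voxels")
  100 * sum(geom$vol[tum][omega_cells[tum] >= threshold]) /
    sum(geom$vol[tum])
}

#' Lesion coverage
#'
#' Percentage of the tumor volume whose damage fraction reaches the
#' threshold (volume-weighted; ring volumes in axisymmetric mode).
#'
#' @param run A `litt_run`, or a per-cell damage vector (then `geom` is
#'   required).
#' @param threshold Damage-fraction threshold (default 0.99).
#' @param geom Internal geometry when `run` is a bare vector.
#' @return Coverage, percent.
#' @export
lesion_coverage <- function(run, threshold = 0.99, geom = NULL) {
  if (inherits(run, "litt_run"))
    lesion_coverage_cells(run$final$omega, run$setup$geom, threshold)
  else lesion_coverage_cells(run, geom, threshold)
}

#' Compare a controlled run against a log replay on the same phantom
#'
#' @param controlled,replay `litt_run` objects from [run_controlled()] and
#'   [run_replay()].
#' @return A one-row tibble: lesion coverage of each run, their difference,
#'   treatment times and energies.
#' @export
compare_runs <- function(controlled, replay) {
  tibble::tibble(
    lc_controlled = controlled$metrics$lc_percent,
    lc_replay = replay$metrics$lc_percent,
    lc_difference = controlled$metrics$lc_percent - replay$metrics$lc_percent,
    time_controlled_s = controlled$metrics$total_time_s,
    time_replay_s = replay$metrics$total_time_s,
    energy_controlled_J = controlled$metrics$energy_J,
    energy_replay_J = replay$metrics$energy_J
  )
}

#' @export
print.litt_run <- function(x, ...) {
  cat("<litt_run> kind:", x$kind, "\n")
  cat("  steps:", nrow(x$series), " end:", x$metrics$total_time_s, "s",
      if (isTRUE(x$metrics$complete)) " (complete)" else " (INCOMPLETE)", "\n")
  cat("  lesion coverage:", round(x$metrics$lc_percent, 2), "%\n")
  cat("  energy:", round(x$metrics$energy_J), "J  max CP:",
      round(x$metrics$max_cp_C, 1), "C\n")
  invisible(x)
}
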