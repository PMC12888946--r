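#' PID controller configuration
#'
#' Gains and setpoints of the boundary-temperature regulator: the controller
#' output `U = Kp*e + Ki*I + Kd*de/dt` is interpreted in watts and clamped to
#' `[0, p_max]` (set `output_mode = "normalized"` to instead treat `U` as a
#' duty fraction multiplied by `p_max`). The error is
#' `e = t_setpoint - T_reference` with the reference boundary probe chosen by
#' [select_reference()].
#'
#' @param kp Proportional gain, W/K.
#' @param ki Integral gain, W/(K s).
#' @param kd Derivative gain, W s/K.
#' @param t_setpoint Boundary-probe temperature setpoint, deg C.
#' @param t_cap Center-probe safety cap, deg C.
#' @param omega_setpoint Boundary damage setpoint triggering retraction.
#' @param p_max Laser power ceiling, W.
#' @param output_mode `"watts"` or `"normalized"`.
#' @param hysteresis Safety-gate release band, K.
#' @return A list with class `litt_pid_config`.
#' @export
pid_config <- function(kp = 7.5, ki = 0.5, kd = 0, t_setpoint = 60,
                       t_cap = 100, omega_setpoint = 0.99, p_max = 15,
                       output_mode = c("watts", "normalized"),
                       hysteresis = 2) {
  output_mode <- match.arg(output_mode)
  if (any(c(kp, ki, kd) < 0)) stop("PID gains must be non-negative")
  if (!(t_setpoint > 0 && t_setpoint < t_cap))
    stop("t_setpoint must lie strictly below t_cap")
  stopifnot(p_max > 0, hysteresis >= 0, omega_setpoint > 0, omega_setpoint < 1)
  structure(list(kp = kp, ki = ki, kd = kd, t_setpoint = t_setpoint,
                 t_cap = t_cap, omega_setpoint = omega_setpoint,
                 p_max = p_max, output_mode = output_mode,
                 hysteresis = hysteresis),
            class = "litt_pid_config")
}

#' Fresh PID internal state
#' @return List: integral accumulator (K s), previous error (K), saturation
#'   flag.
#' @export
pid_state <- function() {
  list(integral = 0, e_prev = NA_real_, saturated = FALSE)
}

#' One discrete PID update
#'
#' Conditional-integration anti-windup: the integral accumulator is frozen
#' whenever the unclamped output is saturated and the error would drive it
#' further into saturation.
#'
#' @param cfg A [pid_config()].
#' @param state A [pid_state()].
#' @param e Error `t_setpoint - T_reference`, K.
#' @param dt Sampling period, s.
#' @return List: `power` (W, clamped), `state` (updated).
#' @export
pid_step <- function(cfg, state, e, dt) {
  stopifnot(dt > 0)
  deriv <- if (is.na(state$e_prev)) 0 else (e - state$e_prev) / dt
  i_try <- state$integral + e * dt
  u_of <- function(i) cfg$kp * e + cfg$ki * i + cfg$kd * deriv
  u <- u_of(i_try)
  scale <- if (cfg$output_mode == "watts") 1 else cfg$p_max
  hi <- cfg$p_max / scale
  saturated <- u > hi || u < 0
  if (saturated && ((u > hi && e > 0) || (u < 0 && e < 0))) {
    i_try <- state$integral  # freeze: integrating would deepen saturation
    u <- u_of(i_try)
  }
  power <- min(max(u * scale, 0), cfg$p_max)
  list(power = power,
       state = list(integral = i_try, e_prev = e, saturated = saturated))
}

#' Reference boundary temperature for regulation
#'
#' Regulates on the hottest monitored boundary probe: the maximum of
#' `T_BPj` over planes `j <= stage`. This generalizes the clinical choice of
#' holding to BP1 whenever it stays hotter than the newly active plane,
#' protecting already-treated tissue from exceeding the setpoint.
#'
#' @param t_bp Numeric length-3 boundary-probe temperatures, deg C.
#' @param stage Current stage (1-3).
#' @return Reference temperature, deg C.
#' @export
select_reference <- function(t_bp, stage) {
  stopifnot(stage %in% 1:3)
  max(t_bp[seq_len(stage)])
}

#' Fresh safety-gate state
#' @return List with the latch flag.
#' @export
safety_gate_state <- function() list(latched = FALSE)

#' Center-probe 100 degree safety gate
#'
#' Forces the laser power to zero whenever any monitored center probe is at
#' or above the cap, and latches: power stays at zero until every monitored
#' center probe has fallen below `cap - hysteresis` (chatter protection).
#'
#' @param gate A [safety_gate_state()].
#' @param power Commanded power, W.
#' @param t_cp Monitored center-probe temperatures, deg C.
#' @param cap Cap temperature, deg C.
#' @param hysteresis Release band, K.
#' @return List: `power` (gated), `gate` (updated).
#' @export
safety_gate <- function(gate, power, t_cp, cap = 100, hysteresis = 2) {
  hot <- any(t_cp >= cap)
  if (hot) gate$latched <- TRUE
  else if (gate$latched && all(t_cp < cap - hysteresis)) gate$latched <- FALSE
  list(power = if (gate$latched) 0 else power, gate = gate)
}

# Membership functions of the retraction controller. BELOW is a trapezoid
# (certain below Omega = 0.95, impossible above 0.98); REACHED ramps from 0
# at 0.98 through 0.5 at the 0.99 setpoint to 1 at saturation, so with the
# 0.5 activation threshold the fired rule reproduces the crisp
# "retract/stop at Omega >= 0.99" automaton exactly.
membership_below <- function(om) pmin(pmax((0.98 - om) / 0.03, 0), 1)
membership_reached <- function(om) pmin(pmax((om - 0.98) / 0.02, 0), 1)

#' Fuzzy retraction decision
#'
#' Fuzzifies the active boundary-probe damage fraction, fires the rule base
#' (REACHED and stage < 3 -> RETRACT; REACHED and stage 3 -> STOP;
#' otherwise HOLD) and defuzzifies by maximum membership with a 0.5
#' activation threshold. Behaviourally identical to the crisp
#' threshold automaton "retract/stop when Omega >= 0.99".
#'
#' @param omega_active Damage fraction at the active boundary probe.
#' @param stage Current stage (1-3).
#' @param threshold Activation threshold on the REACHED membership.
#' @return One of `"hold"`, `"retract"`, `"stop"`.
#' @export
fuzzy_decision <- function(omega_active, stage, threshold = 0.5) {
  stopifnot(stage %in% 1:3, omega_active >= 0, omega_active <= 1)
  fire_reached <- membership_reached(omega_active) >= threshold
  if (!fire_reached) return("hold")
  if (stage < 3) "retract" else "stop"
}
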