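#' Default run configuration
#'
#' The complete nested configuration a run needs, with the controller
#' defaults of the clinical design (Kp 7.5 W/K, Ki 0.5 W/(K s), Kd 0,
#' boundary setpoint 60 deg C, center cap 100 deg C, damage setpoint 0.99),
#' solver defaults (1 s BDF2), Robin boundary conditions (skull 5, catheter
#' 100 W/(m^2 K), both to 20 deg C ambients) and the phantom, optics,
#' damage and UQ sections. Units are encoded in the key names.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "litt_out",
    phantom = list(
      tumor_radius_mm = 10, spacing_mm = 0.5,
      shells_mm = list(brain = 15, csf_general = 3, skull = 7),
      stage_z_mm = c(-5, 0, 5)),
    materials = list(),   # per-label overrides of default_materials()
    blood = list(density = 1050, heat_capacity = 3617, temperature_C = 37),
    optics = list(
      mu_native_per_mm = list(brain = 0.35, tumor = 0.35, skull = 0,
                              csf_general = 0, csf_ventricle = 0),
      coagulation_factor = 1.5, mode = "cop", recompute_tol = 0.01),
    damage = list(A_per_s = 3.1e98, Ea_J_per_mol = 6.28e5,
                  peritumoral_margin_mm = 5),
    controller = list(kp = 7.5, ki = 0.5, kd = 0, t_setpoint_C = 60,
                      t_cap_C = 100, omega_setpoint = 0.99, p_max_W = 15,
                      output_mode = "watts", hysteresis_C = 2,
                      feedback_delay_steps = 0L),
    solver = list(dt_s = 1, scheme = "bdf2", prop_cap_C = 90),
    bc = list(h_outer = 5, t_outer_C = 20, h_catheter = 100,
              t_catheter_C = 20),
    laser = list(source_model = "pslh", n_sub = 10L),
    treat = list(t_max_s = 7200),
    uq = list(n_train = 20L, n_verify = 10L, n_base = 32768L, spread = 0.2,
              n_propagate = 2000L, spacing_mm = 1)
  )
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- c(path, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste(here, collapse = "."))
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])) && length(base[[nm]]) > 0 &&
        !identical(nm, "materials"))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  ctl <- cfg$controller
  if (any(unlist(ctl[c("kp", "ki", "kd")]) < 0))
    stop("configuration error: controller gains (kp/ki/kd) must be >= 0")
  if (!(ctl$t_setpoint_C > 0 && ctl$t_setpoint_C < ctl$t_cap_C))
    stop("configuration error: t_setpoint_C must lie below t_cap_C")
  if (cfg$solver$dt_s <= 0) stop("configuration error: dt_s must be > 0")
  if (cfg$phantom$spacing_mm <= 0)
    stop("configuration error: spacing_mm must be > 0")
  if (any(unlist(cfg$optics$mu_native_per_mm) < 0))
    stop("configuration error: mu_native_per_mm must be >= 0")
  if (cfg$damage$A_per_s <= 0 || cfg$damage$Ea_J_per_mol <= 0)
    stop("configuration error: Arrhenius A_per_s and Ea_J_per_mol must be > 0")
  if (any(c(cfg$bc$h_outer, cfg$bc$h_catheter) < 0))
    stop("configuration error: convection coefficients must be >= 0")
  invisible(cfg)
}

#' Load a YAML run configuration
#'
#' Reads the file, merges it over [default_config()] (unknown keys are
#' rejected with the offending key named), and validates the physical
#' constraints. An empty file yields the full defaults. The merged
#' (effective) configuration round-trips through [write_config()]
#' idempotently.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The effective configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Instantiate simulation objects from a configuration
#'
#' Converts the effective configuration into the objects the run drivers
#' take: phantom, materials table, blood, optics, damage parameters,
#' controller, solver and boundary conditions.
#'
#' @param cfg Configuration from [load_config()].
#' @return Named list of constructed objects.
#' @export
config_objects <- function(cfg) {
  mats <- default_materials()
  for (lbl in names(cfg$materials)) {
    if (!lbl %in% mats$label)
      stop("materials override for unknown label: ", lbl)
    for (fld in names(cfg$materials[[lbl]])) {
      if (!fld %in% names(mats))
        stop("unknown material field: ", fld)
      mats[mats$label == lbl, fld] <- cfg$materials[[lbl]][[fld]]
    }
  }
  validate_materials(mats)
  ph <- cfg$phantom
  track <- probe_track(stage_z = ph$stage_z_mm * 1e-3)
  phantom <- build_concentric_phantom(
    tumor_radius = ph$tumor_radius_mm * 1e-3,
    shell_thicknesses = c(brain = ph$shells_mm$brain * 1e-3,
                          csf_general = ph$shells_mm$csf_general * 1e-3,
                          skull = ph$shells_mm$skull * 1e-3),
    spacing = ph$spacing_mm * 1e-3, track = track)
  mu <- unlist(cfg$optics$mu_native_per_mm) * 1e3   # 1/mm -> 1/m
  list(
    phantom = phantom,
    materials = mats,
    blood = blood_properties(cfg$blood$density, cfg$blood$heat_capacity,
                             cfg$blood$temperature_C),
    optics = optical_model(mu_native = mu,
                           coagulation_factor = cfg$optics$coagulation_factor,
                           mode = cfg$optics$mode),
    damage = arrhenius_params(A = cfg$damage$A_per_s,
                              E_a = cfg$damage$Ea_J_per_mol),
    control = pid_config(kp = cfg$controller$kp, ki = cfg$controller$ki,
                         kd = cfg$controller$kd,
                         t_setpoint = cfg$controller$t_setpoint_C,
                         t_cap = cfg$controller$t_cap_C,
                         omega_setpoint = cfg$controller$omega_setpoint,
                         p_max = cfg$controller$p_max_W,
                         output_mode = cfg$controller$output_mode,
                         hysteresis = cfg$controller$hysteresis_C),
    solver = solver_config(dt = cfg$solver$dt_s, scheme = cfg$solver$scheme,
                           prop_cap = cfg$solver$prop_cap_C),
    bc = boundary_conditions(cfg$bc$h_outer, cfg$bc$t_outer_C,
                             cfg$bc$h_catheter, cfg$bc$t_catheter_C),
    peritumoral_margin = cfg$damage$peritumoral_margin_mm * 1e-3,
    source_model = cfg$laser$source_model,
    n_sub = cfg$laser$n_sub,
    recompute_tol = cfg$optics$recompute_tol
  )
}
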