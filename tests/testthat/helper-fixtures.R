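# Shared fixtures: small, fast phantoms and memoised expensive runs.

.litt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .litt_cache))
    assign(key, force(expr), envir = .litt_cache)
  get(key, envir = .litt_cache)
}

# Small axisymmetric phantom (7 mm tumor, 1 mm grid) for fast physics tests.
small_phantom <- function() {
  build_concentric_phantom(
    tumor_radius = 7e-3,
    shell_thicknesses = c(brain = 8e-3, csf_general = 2e-3, skull = 3e-3),
    spacing = 1e-3)
}

# Coarse full-size phantom (10 mm tumor, 1 mm grid) for UQ-style tests.
coarse_phantom <- function() {
  build_concentric_phantom(spacing = 1e-3)
}

small_geometry <- function() {
  cached("small_geometry", phantom_geometry(small_phantom()))
}

# Short constant-power log at the stage-1 tip.
constant_log <- function(power = 8, t_end = 60, tip_mm = -5) {
  tibble::new_tibble(
    tibble::tibble(t_s = c(0, 1, t_end), power_W = c(0, power, power),
                   tip_z_mm = rep(tip_mm, 3)),
    class = "litt_laser_log")
}

# Memoised small controlled run (fast event-ordering checks).
small_controlled_run <- function() {
  cached("small_controlled_run",
         run_controlled(small_phantom(), t_max = 900))
}

small_replay_run <- function() {
  cached("small_replay_run",
         run_replay(small_phantom(), make_fixture_log(seed = 1)))
}
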