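test_that("uniform body-temperature state with no sources is an equilibrium", {
  g <- small_geometry()
  bc <- boundary_conditions(h_outer = 0, h_catheter = 0)
  st <- list(T = rep(37, g$n), T_prev = NULL, t = 0)
  blood <- blood_properties()
  out <- bioheat_step(st, g, q_laser = NULL, bc = bc, blood = blood,
                      cfg = solver_config(scheme = "backward_euler"))
  # perfusion pins to 37 and metabolism adds a small offset; with both off:
  g0 <- g; g0$perf0 <- rep(0, g$n); g0$qmet <- rep(0, g$n)
  out0 <- bioheat_step(st, g0, q_laser = NULL, bc = bc, blood = blood,
                       cfg = solver_config(scheme = "backward_euler"))
  expect_equal(out0$state$T, rep(37, g$n), tolerance = 1e-10)
})

test_that("perfusion relaxes an offset toward blood temperature like the ODE", {
  # conduction suppressed: every cell follows dT/dt = w*(Tb - T)/(rho*C)
  g <- small_geometry()
  g$k0 <- rep(1e-9, g$n)
  wb <- 2000  # omega*rho_b*cp_b, W/(m^3 K)
  g$perf0 <- rep(wb, g$n)
  g$qmet <- rep(0, g$n)
  g$coeff_k <- g$coeff_c <- rep(0, g$n)
  g$rho <- rep(1000, g$n); g$cp0 <- rep(3600, g$n)
  blood <- blood_properties(1, 1, 37)   # perf0 already carries rho_b*cp_b
  bc <- boundary_conditions(h_outer = 0, h_catheter = 0)
  st <- list(T = rep(47, g$n), T_prev = NULL, t = 0)
  dt <- 0.25
  cfg <- solver_config(dt = dt, scheme = "bdf2")
  for (s in 1:80) st <- bioheat_step(st, g, bc = bc, blood = blood,
                                     cfg = cfg)$state
  tau <- 1000 * 3600 / wb
  expect_equal(max(st$T), 37 + 10 * exp(-20 / tau), tolerance = 1e-3)
})

test_that("analytic point-source solution has the right limits", {
  expect_equal(analytic_point_source_steady(5e-3, 1, 0.5, 0),
               37 + 1 / (4 * pi * 0.5 * 5e-3))
  expect_equal(analytic_point_source_steady(10, 1, 0.5, 2000), 37,
               tolerance = 1e-6)
  expect_error(analytic_point_source_steady(0, 1, 0.5), "singular")
  # quadrature oracle: solve the radial ODE k*(T'' + 2T'/r) = w*(T-Tb)
  # outward from a matched inner boundary and compare
  k <- 0.5; w <- 2000; P <- 1
  lam <- sqrt(w / k)
  rs <- seq(3e-3, 15e-3, by = 1e-4)
  f <- analytic_point_source_steady(rs, P, k, w) - 37
  # finite-difference residual of the governing ODE must vanish
  d2 <- diff(f, differences = 2) / (1e-4)^2
  d1 <- (f[-(1:2)] - f[1:(length(f) - 2)]) / (2 * 1e-4)
  resid <- k * (d2 + 2 * d1 / rs[2:(length(rs) - 1)]) - w * f[2:(length(f) - 1)]
  expect_lt(max(abs(resid)) / max(abs(w * f)), 1e-4)
})

test_that("solver verification error is small and second-order in dr", {
  v1 <- verify_solver(dr = 4e-4, r_max = 0.12, max_steps = 4000)
  v2 <- verify_solver(dr = 2e-4, r_max = 0.12, max_steps = 4000)
  expect_lt(v2$max_rel_error_pct, v1$max_rel_error_pct / 1.8)
  # zero-perfusion variant against the pure conduction closed form
  v0 <- verify_solver(dr = 2e-4, r_max = 0.12, w_rho_cb = 0, max_steps = 6000)
  expect_lt(v0$max_rel_error_pct, 0.1)
})

test_that("temperature-dependent properties are frozen above the cap", {
  g <- small_geometry()
  k90 <- littsim:::cell_conductivity(g, rep(90, g$n))
  k120 <- littsim:::cell_conductivity(g, rep(120, g$n))
  expect_identical(k90, k120)
  c90 <- littsim:::cell_heat_capacity(g, rep(90, g$n))
  c120 <- littsim:::cell_heat_capacity(g, rep(120, g$n))
  expect_identical(c90, c120)
  # below the cap brain properties grow, skull/CSF stay constant
  k50 <- littsim:::cell_conductivity(g, rep(50, g$n))
  k37 <- littsim:::cell_conductivity(g, rep(37, g$n))
  expect_true(all(k50[g$label == "brain"] > k37[g$label == "brain"]))
  expect_identical(k50[g$label == "skull"], k37[g$label == "skull"])
})

test_that("free cooling toward a common ambient dissipates monotonically", {
  g <- small_geometry()
  g$perf0 <- rep(0, g$n); g$qmet <- rep(0, g$n)
  bc <- boundary_conditions(h_outer = 5, t_outer = 37,
                            h_catheter = 100, t_catheter = 37)
  set.seed(42)
  st <- list(T = 37 + 10 * runif(g$n), T_prev = NULL, t = 0)
  blood <- blood_properties()
  prev <- max(abs(st$T - 37))
  for (s in 1:10) {
    st <- bioheat_step(st, g, bc = bc, blood = blood,
                       cfg = solver_config(scheme = "backward_euler"),
                       tip_z = -5e-3)$state
    cur <- max(abs(st$T - 37))
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("per-step energy budget closes for the implicit scheme", {
  g <- small_geometry()
  mu <- mueff_field(optical_model(), numeric(g$n), g)
  dep <- compute_deposition(laser_source("pslh", 8, -5e-3), mu, g)
  st <- list(T = rep(37, g$n), T_prev = NULL, t = 0)
  blood <- blood_properties()
  cfg <- solver_config(scheme = "backward_euler")
  for (s in 1:5) {
    out <- bioheat_step(st, g, q_laser = dep$q, bc = boundary_conditions(),
                        blood = blood, cfg = cfg, tip_z = -5e-3)
    b <- out$budget
    resid <- b$storage - (b$boundary + b$perfusion + b$laser + b$metabolic)
    scale <- max(abs(unlist(b)))
    expect_lt(abs(resid) / scale, 0.005)
    st <- out$state
  }
})

test_that("BDF2 and backward Euler converge to each other as dt shrinks", {
  g <- small_geometry()
  mu <- mueff_field(optical_model(), numeric(g$n), g)
  dep <- compute_deposition(laser_source("pslh", 5, -5e-3), mu, g)
  blood <- blood_properties()
  horizon <- 8
  run_scheme <- function(scheme, dt) {
    st <- list(T = rep(37, g$n), T_prev = NULL, t = 0)
    cfg <- solver_config(dt = dt, scheme = scheme)
    for (s in seq_len(horizon / dt))
      st <- bioheat_step(st, g, q_laser = dep$q, bc = boundary_conditions(),
                         blood = blood, cfg = cfg, tip_z = -5e-3)$state
    st$T
  }
  d1 <- max(abs(run_scheme("bdf2", 1) - run_scheme("backward_euler", 1)))
  d2 <- max(abs(run_scheme("bdf2", 0.5) - run_scheme("backward_euler", 0.5)))
  expect_lt(d2, d1)
})

test_that("the 3-D Cartesian geometry holds equilibrium too", {
  dims <- c(8L, 8L, 8L)
  arr <- array(1L, dims)
  tmp <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), tmp)
  ph <- load_label_map(tmp, list(brain = 1L))
  g <- phantom_geometry(ph)
  g$perf0 <- rep(0, g$n); g$qmet <- rep(0, g$n)
  bc <- boundary_conditions(h_outer = 5, t_outer = 37, h_catheter = 0)
  st <- list(T = rep(37, g$n), T_prev = NULL, t = 0)
  out <- bioheat_step(st, g, bc = bc, blood = blood_properties(),
                      cfg = solver_config(scheme = "backward_euler"))
  expect_equal(out$state$T, rep(37, g$n), tolerance = 1e-9)
})
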