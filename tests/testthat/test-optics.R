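geom_small <- function() small_geometry()

test_that("damage-dependent attenuation interpolates native to coagulated", {
  g <- geom_small()
  om <- optical_model(coagulation_factor = 1.5, mode = "vop")
  mu0 <- mueff_field(om, numeric(g$n), g)
  expect_equal(mu0, unname(om$mu_native[g$label]))
  mu1 <- mueff_field(om, rep(1, g$n), g)
  expect_equal(mu1, 1.5 * mu0)
  muh <- mueff_field(om, rep(0.5, g$n), g)
  expect_equal(muh, 1.25 * mu0)
  expect_warning(mueff_field(om, rep(1.2, g$n), g), "clipping")
})

test_that("cop mode ignores damage and equals vop at zero damage exactly", {
  g <- geom_small()
  cop <- optical_model(mode = "cop"); vop <- optical_model(mode = "vop")
  mu_c <- mueff_field(cop, rep(0.7, g$n), g)
  mu_v0 <- mueff_field(vop, numeric(g$n), g)
  expect_identical(mu_c, mu_v0)
  d1 <- compute_deposition(laser_source("pslh", 5, -5e-3), mu_c, g)
  d2 <- compute_deposition(laser_source("pslh", 5, -5e-3), mu_v0, g)
  expect_identical(d1$q, d2$q)
})

test_that("deposition matches the homogeneous closed form and conserves energy", {
  # fill the lumen so the medium is homogeneous around the source
  ph <- build_concentric_phantom(spacing = 0.5e-3)
  ph$label[ph$label == "probe_lumen"] <- "tumor"
  ph$label[ph$label %in% c("skull", "csf_general")] <- "brain"
  g <- phantom_geometry(ph)
  mu <- mueff_field(optical_model(), numeric(g$n), g)
  P <- 10
  dep <- compute_deposition(laser_source("pslh", P, -5e-3), mu, g)
  expect_lte(dep$total_deposited, P)
  d <- sqrt(g$coords[, "r"]^2 + (g$coords[, "z"] + 5e-3)^2)
  for (R in c(4e-3, 8e-3, 15e-3)) {
    expect_equal(deposited_power(dep, g, which(d <= R)),
                 P * (1 - exp(-350 * R)), tolerance = 0.02)
  }
  # additivity over a partition
  half <- which(g$coords[, "z"] > -5e-3)
  other <- setdiff(seq_len(g$n), half)
  expect_equal(deposited_power(dep, g, half) + deposited_power(dep, g, other),
               deposited_power(dep, g), tolerance = 1e-12)
  expect_equal(deposited_power(dep, g, integer(0)), 0)
})

test_that("zero attenuation deposits nothing", {
  g <- geom_small()
  mu0 <- rep(0, g$n)
  dep <- compute_deposition(laser_source("pslh", 10, -5e-3), mu0, g)
  expect_equal(dep$total_deposited, 0)
})

test_that("single-sub-source DPHS is bit-identical to PSLH", {
  g <- geom_small()
  mu <- mueff_field(optical_model(), numeric(g$n), g)
  dp <- compute_deposition(laser_source("pslh", 7, -5e-3), mu, g)
  dd <- compute_deposition(laser_source("dphs", 7, -5e-3, n_sub = 1), mu, g)
  expect_identical(dp$q, dd$q)
})

test_that("PSLH and DPHS agree in the far field for weak attenuation", {
  ph <- build_concentric_phantom(spacing = 0.5e-3)
  ph$label[ph$label == "probe_lumen"] <- "tumor"
  ph$label[ph$label %in% c("skull", "csf_general")] <- "brain"
  g <- phantom_geometry(ph)
  om <- optical_model(mu_native = c(brain = 20, tumor = 20, skull = 0,
                                    csf_general = 0, csf_ventricle = 0))
  mu <- mueff_field(om, numeric(g$n), g)
  dp <- compute_deposition(laser_source("pslh", 10, -5e-3), mu, g)
  dd <- compute_deposition(laser_source("dphs", 10, -5e-3, n_sub = 10), mu, g)
  d <- sqrt(g$coords[, "r"]^2 + (g$coords[, "z"] + 5e-3)^2)
  far <- d >= 24.5e-3 & d <= 25.5e-3
  expect_lt(max(abs(dd$q[far] - dp$q[far]) / dp$q[far]), 0.02)
})

test_that("scaling to a reference deposited power is exact and linear", {
  g <- geom_small()
  mu <- mueff_field(optical_model(), numeric(g$n), g)
  dep <- compute_deposition(laser_source("pslh", 10, -5e-3), mu, g)
  actual <- deposited_power(dep, g)
  same <- scale_to_reference_deposition(dep, actual, g)
  expect_equal(attr(same, "scale_factor"), 1)
  expect_equal(same$q, dep$q)
  dbl <- scale_to_reference_deposition(dep, 2 * actual, g)
  expect_equal(attr(dbl, "scale_factor"), 2)
  expect_equal(deposited_power(dbl, g), 2 * actual, tolerance = 1e-12)
  zero <- dep; zero$q <- rep(0, g$n)
  expect_error(scale_to_reference_deposition(zero, 1, g), "zero")
})

test_that("cop and vop fields scaled to a common reference deposit equally", {
  g <- geom_small()
  om_v <- optical_model(mode = "vop")
  omg <- pmin(pmax(g$coords[, "r"] * 50, 0), 1)   # synthetic damage field
  mu_c <- mueff_field(optical_model(), omg, g)
  mu_v <- mueff_field(om_v, omg, g)
  dc <- compute_deposition(laser_source("pslh", 10, -5e-3), mu_c, g)
  dv <- compute_deposition(laser_source("pslh", 10, -5e-3), mu_v, g)
  ref <- deposited_power(dc, g)
  dv2 <- scale_to_reference_deposition(dv, ref, g)
  expect_equal(deposited_power(dv2, g), ref, tolerance = 1e-10)
})
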