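test_that("zero-power treatment heats nothing and is flagged incomplete", {
  ph <- small_phantom()
  run <- run_controlled(ph, control = pid_config(kp = 0, ki = 0, kd = 0,
                                                 p_max = 1e-9),
                        t_max = 10)
  expect_false(run$metrics$complete)
  expect_equal(run$metrics$lc_percent, 0)
  expect_equal(run$metrics$n_retractions, 0)
  expect_true(all(run$series$power_W < 1e-6))
})

test_that("an all-zero-power log replay produces zero lesion coverage", {
  ph <- small_phantom()
  log <- tibble::new_tibble(
    tibble::tibble(t_s = c(0, 20), power_W = c(0, 0), tip_z_mm = c(-5, -5)),
    class = "litt_laser_log")
  run <- run_replay(ph, log)
  expect_equal(run$metrics$lc_percent, 0)
  expect_equal(run$metrics$energy_J, 0)
})

test_that("lesion coverage counts tumor volume above threshold", {
  g <- small_geometry()
  expect_equal(lesion_coverage(rep(1, g$n), geom = g), 100)
  expect_equal(lesion_coverage(rep(0, g$n), geom = g), 0)
  # constructed half-volume field: flag tumor cells in volume order until
  # half the tumor volume is covered
  tum <- which(g$tumor)
  v <- g$vol[tum]
  ord <- order(g$coords[tum, "z"])
  csum <- cumsum(v[ord]) / sum(v)
  k <- which.min(abs(csum - 0.5))
  om <- numeric(g$n)
  om[tum[ord[seq_len(k)]]] <- 1
  expect_equal(lesion_coverage(om, geom = g), 100 * csum[k], tolerance = 1e-9)
})

test_that("controlled treatment retracts twice on damage and then stops", {
  run <- small_controlled_run()
  m <- run$metrics
  expect_true(m$complete)
  expect_equal(m$n_retractions, 2)
  s <- run$series
  expect_equal(sort(unique(s$stage)), 1:3)
  # total retraction = 10 mm
  expect_equal(max(s$tip_z_mm) - min(s$tip_z_mm), 10)
  # the active boundary probe crosses the damage setpoint strictly before
  # each retraction, never after
  first_ret <- m$retraction_times_s[1]
  expect_gte(s$omega_bp1[s$t_s == first_ret], 0.99)
  expect_lt(s$omega_bp1[1], 0.99)   # threshold crossed during stage 1
  # stage sequence is monotone
  expect_true(all(diff(s$stage) >= 0))
})

test_that("gated power is zero whenever a monitored center probe reads hot", {
  run <- small_controlled_run()
  s <- run$series
  # reading available to the controller at step k is the probe state at k-1
  cp_prev <- pmax(dplyr::lag(s$t_cp1), ifelse(s$stage >= 2,
                                              dplyr::lag(s$t_cp2), -Inf),
                  ifelse(s$stage >= 3, dplyr::lag(s$t_cp3), -Inf))
  hot <- which(!is.na(cp_prev) & cp_prev >= 100)
  expect_true(all(s$power_W[hot] == 0))
})

test_that("controlled treatment covers more of the tumor than the replay", {
  rc <- small_controlled_run()
  rr <- small_replay_run()
  expect_gt(rc$metrics$lc_percent, rr$metrics$lc_percent)
  cmpr <- compare_runs(rc, rr)
  expect_equal(cmpr$lc_difference,
               cmpr$lc_controlled - cmpr$lc_replay)
})

test_that("identical configuration gives bit-identical time series", {
  ph <- small_phantom()
  log <- make_fixture_log(seed = 3)
  r1 <- run_replay(ph, log, t_end = 40)
  r2 <- run_replay(ph, log, t_end = 40)
  expect_identical(r1$series, r2$series)
  c1 <- run_controlled(ph, t_max = 30)
  c2 <- run_controlled(ph, t_max = 30)
  expect_identical(c1$series, c2$series)
})

test_that("damage fraction never decreases across a full trace", {
  run <- small_replay_run()
  s <- run$series
  for (col in c("omega_bp1", "omega_bp2", "omega_bp3"))
    expect_true(all(diff(s[[col]]) >= -1e-15))
})

test_that("replay requires the log to span the simulation window", {
  ph <- small_phantom()
  log <- constant_log(t_end = 30)
  expect_error(run_replay(ph, log, t_end = 60), "ends at")
})

test_that("tidiers and autoplot work on runs", {
  run <- small_replay_run()
  long <- tidy(run)
  expect_true(all(c("signal", "plane", "value") %in% names(long)))
  expect_equal(nrow(long), nrow(run$series) * 9)
  g <- glance(run)
  expect_equal(g$lc_percent, run$metrics$lc_percent)
  p <- ggplot2::ggplot_build(autoplot(run))
  expect_s3_class(p$plot, "ggplot")
  ps <- ggplot2::ggplot_build(autoplot(small_phantom()))
  expect_s3_class(ps$plot, "ggplot")
})
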