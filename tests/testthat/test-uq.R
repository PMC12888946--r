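unit_params <- function(d = 2) {
  lapply(seq_len(d), function(i)
    uncertain_parameter(paste0("x", i), 0, 1))
}

test_that("single-input models get full first-order and total indices", {
  p <- unit_params(1)
  s <- saltelli_sobol(function(x) 2 * x[, 1] + 1, p, n_base = 256, seed = 1)
  expect_lt(abs(s$indices$s1 - 1), 0.05)
  expect_lt(abs(s$indices$st - 1), 0.05)
})

test_that("additive model indices match the analytic 9/10 and 1/10 split", {
  p <- unit_params(2)
  s <- saltelli_sobol(function(x) 3 * x[, 1] + x[, 2], p,
                      n_base = 1024, seed = 7)
  i1 <- s$indices[s$indices$parameter == "x1", ]
  i2 <- s$indices[s$indices$parameter == "x2", ]
  expect_lt(abs(i1$s1 - 0.9), 0.05)
  expect_lt(abs(i2$s1 - 0.1), 0.05)
  expect_lt(abs(i1$st - 0.9), 0.05)
  expect_lt(abs(i2$st - 0.1), 0.05)
})

test_that("interactions push total above first-order indices", {
  p <- unit_params(2)
  s <- saltelli_sobol(function(x) x[, 1] * x[, 2], p, n_base = 2048, seed = 5)
  # analytic: S1 = 3/7, ST = 4/7 for both inputs
  expect_lt(max(abs(s$indices$s1 - 3 / 7)), 0.06)
  expect_lt(max(abs(s$indices$st - 4 / 7)), 0.06)
  expect_true(all(s$indices$st > s$indices$s1))
})

test_that("estimator error shrinks with the sample size", {
  p <- unit_params(2)
  err_at <- function(n) {
    s <- saltelli_sobol(function(x) 3 * x[, 1] + x[, 2], p, n, seed = 11)
    max(abs(s$indices$s1 - c(0.9, 0.1)))
  }
  expect_lt(err_at(4096), max(err_at(256), 0.01) * 3)
})

test_that("doubling convergence is small for a linear model and seed-stable", {
  p <- unit_params(2)
  cc <- convergence_check(function(x) 3 * x[, 1] + x[, 2], p,
                          n_base = 512, seed = 3)
  expect_lt(cc$max_delta, 0.02)
  s1 <- saltelli_sobol(function(x) x[, 1] + x[, 2], p, 128, seed = 9)
  s2 <- saltelli_sobol(function(x) x[, 1] + x[, 2], p, 128, seed = 9)
  expect_identical(s1$indices, s2$indices)
})

test_that("zero-variance QoIs are flagged undefined", {
  p <- unit_params(1)
  expect_warning(s <- saltelli_sobol(function(x) rep(1, nrow(x)), p,
                                     n_base = 64, seed = 1),
                 "zero variance")
  expect_true(all(is.na(s$indices$s1)))
})

test_that("polynomial surrogates reproduce polynomial models exactly", {
  p <- unit_params(2)
  set.seed(4)
  x <- matrix(runif(80), 40, 2)
  y <- 1 + 2 * x[, 1] - x[, 2] + 3 * x[, 1]^2 + x[, 1] * x[, 2]
  sur <- surrogate_fit(x, y, p, degree = 2)
  expect_lt(max(sur$rel_error), 1e-10)
  expect_true(sur$accepted)
  # verification points are held out of training
  expect_equal(sur$n_train + sur$n_verify, 40)
  # surrogate Sobol indices agree with direct estimation
  model <- function(m) 1 + 2 * m[, 1] - m[, 2] + 3 * m[, 1]^2 + m[, 1] * m[, 2]
  sd_dir <- saltelli_sobol(model, p, 2048, seed = 2)
  sd_sur <- saltelli_sobol(function(m) as.vector(sur$predict(m)), p,
                           2048, seed = 2)
  expect_lt(max(abs(sd_sur$indices$s1 - sd_dir$indices$s1)), 0.05)
})

test_that("a model the basis cannot represent is rejected by verification", {
  p <- unit_params(1)
  set.seed(8)
  x <- matrix(runif(40), 40, 1)
  y <- sin(20 * x[, 1])
  sur <- surrogate_fit(x, y, p, degree = 2)
  expect_false(sur$accepted)
})

test_that("propagation reports consistent order statistics", {
  p <- unit_params(1)
  pr <- propagate(function(x) x[, 1], p, n = 4000, seed = 2)
  s <- pr$summary
  expect_equal(s$p10, 0.1, tolerance = 0.02)
  expect_equal(s$p90, 0.9, tolerance = 0.02)
  expect_true(s$min <= s$p10 && s$p90 <= s$max)
  expect_true(s$lower95 <= s$p10 && s$p90 <= s$upper95)
  const <- propagate(function(x) rep(2, nrow(x)), p, n = 50, seed = 1)
  expect_equal(const$summary$sd, 0)
  expect_equal(const$summary$p10, const$summary$p90)
})

test_that("log survival of Gaussian damage integrals passes normality", {
  set.seed(21)
  alpha <- abs(rnorm(300, mean = 3, sd = 0.5))  # -alpha is Gaussian
  om <- omega(alpha)
  d <- survival_normality_diagnostic(om)
  expect_gt(d$shapiro_p, 0.05)
  # symmetric samples have ~zero skewness
  sym <- survival_normality_diagnostic(
    pmin(pmax(0.5 + c(-(1:99), 1:99) / 400, 0), 0.9))
  expect_lt(abs(sym$skewness), 0.1)
  # omega = 1 samples are excluded and counted
  d2 <- survival_normality_diagnostic(c(om, 1, 1))
  expect_equal(d2$n_excluded, 2)
})
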