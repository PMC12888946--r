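#' Uncertain parameter with a uniform distribution
#'
#' @param name Parameter name (e.g. `"mu_eff_native"`).
#' @param lo,hi Bounds of the uniform distribution (`lo < hi`). Parameters
#'   are mutually independent.
#' @return A list with class `litt_uparam`.
#' @export
uncertain_parameter <- function(name, lo, hi) {
  if (!(lo < hi)) stop("uncertain parameter needs lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "litt_uparam")
}

scale_unit <- function(u, params) {
  lo <- vapply(params, `[[`, numeric(1), "lo")
  hi <- vapply(params, `[[`, numeric(1), "hi")
  sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
}

eval_model <- function(model, x, params) {
  y <- model(x)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (is.null(colnames(y))) colnames(y) <- paste0("qoi", seq_len(ncol(y)))
  y
}

#' Sobol sensitivity indices by Saltelli sampling
#'
#' Variance-based global sensitivity analysis: generates the Saltelli
#' A/B/AB design (`n_base * (d + 2)` model evaluations for `d` parameters)
#' and estimates first-order (`S1`, main effect) and total (`ST`, including
#' interactions) indices with the Jansen estimators. Reproducible under a
#' fixed seed.
#'
#' @param model Function mapping an `n x d` matrix of parameter values to a
#'   vector (one QoI) or an `n x q` matrix (several QoIs). Must be
#'   deterministic given its inputs.
#' @param params List of [uncertain_parameter()]s.
#' @param n_base Base sample size (>= 8).
#' @param seed Integer seed.
#' @return A `litt_sobol` object: tibble `indices` (columns `qoi`,
#'   `parameter`, `s1`, `st`), plus `n_base`, `seed`, per-QoI variance.
#' @export
saltelli_sobol <- function(model, params, n_base = 256L, seed = 1L) {
  d <- length(params)
  stopifnot(n_base >= 8, d >= 1)
  set.seed(as.integer(seed))
  A <- matrix(stats::runif(n_base * d), n_base, d)
  B <- matrix(stats::runif(n_base * d), n_base, d)
  fA <- eval_model(model, scale_unit(A, params), params)
  fB <- eval_model(model, scale_unit(B, params), params)
  q <- ncol(fA)
  vary <- apply(rbind(fA, fB), 2, stats::var)
  rows <- list()
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- eval_model(model, scale_unit(ABi, params), params)
    for (k in seq_len(q)) {
      if (vary[k] <= .Machine$double.eps) {
        warning("QoI ", colnames(fA)[k],
                " has zero variance; indices undefined")
        s1 <- NA_real_; st <- NA_real_
      } else {
        s1 <- unname((vary[k] - mean((fB[, k] - fABi[, k])^2) / 2) / vary[k])
        st <- unname(mean((fA[, k] - fABi[, k])^2) / 2 / vary[k])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        qoi = colnames(fA)[k], parameter = params[[i]]$name,
        s1 = s1, st = st)
    }
  }
  structure(list(indices = dplyr::bind_rows(rows), n_base = n_base,
                 seed = seed, variance = vary),
            class = "litt_sobol")
}

#' @export
print.litt_sobol <- function(x, ...) {
  cat("<litt_sobol> n_base:", x$n_base, " seed:", x$seed, "\n")
  print(x$indices)
  invisible(x)
}

#' Sobol convergence check by sample doubling
#'
#' Estimates the indices at `n_base` and `2 * n_base` (same seed) and
#' returns the maximum absolute change over all first-order and total
#' indices — the convergence criterion used with variance-based analyses.
#'
#' @inheritParams saltelli_sobol
#' @return List: `max_delta`, and both `litt_sobol` results.
#' @export
convergence_check <- function(model, params, n_base = 256L, seed = 1L) {
  s1 <- saltelli_sobol(model, params, n_base, seed)
  s2 <- saltelli_sobol(model, params, 2L * n_base, seed)
  stopifnot(identical(dim(s1$indices), dim(s2$indices)))
  max_delta <- max(abs(c(s1$indices$s1 - s2$indices$s1,
                         s1$indices$st - s2$indices$st)), na.rm = TRUE)
  list(max_delta = max_delta, at_n = s1, at_2n = s2)
}

# Total-degree Legendre basis on inputs scaled to [-1, 1].
legendre_basis <- function(x01, degree) {
  z <- 2 * x01 - 1
  d <- ncol(z)
  polys <- lapply(seq_len(d), function(j) {
    P <- matrix(1, nrow(z), degree + 1)
    if (degree >= 1) P[, 2] <- z[, j]
    if (degree >= 2) for (k in 2:degree)
      P[, k + 1] <- ((2 * k - 1) * z[, j] * P[, k] - (k - 1) * P[, k - 1]) / k
    P
  })
  degs <- expand.grid(rep(list(0:degree), d))
  degs <- degs[rowSums(degs) <= degree, , drop = FALSE]
  out <- matrix(1, nrow(z), nrow(degs))
  for (m in seq_len(nrow(degs)))
    for (j in seq_len(d))
      out[, m] <- out[, m] * polys[[j]][, degs[m, j] + 1]
  list(B = out, degs = degs)
}

#' Fit a polynomial surrogate with held-out verification
#'
#' Least-squares total-degree Legendre polynomial on inputs scaled to the
#' parameter box, validated against held-out verification points that are
#' never part of the training set. The surrogate is rejected (flag
#' `accepted = FALSE`) when the maximum relative verification error exceeds
#' `rel_tol` of the QoI range; callers then fall back to the direct model.
#' A rank-deficient fit auto-reduces the degree with a warning.
#'
#' @param x `n x d` matrix of sampled parameter values.
#' @param y QoI vector (length `n`) or `n x q` matrix.
#' @param params List of [uncertain_parameter()]s (for input scaling).
#' @param degree Total polynomial degree (<= 3 by default).
#' @param n_verify Number of held-out verification points (default 10).
#' @param rel_tol Acceptance tolerance relative to each QoI's range.
#' @return A `litt_surrogate`: `predict(newx)`, per-QoI `verification_error`
#'   (max abs error on held-out points), `rel_error`, `accepted`.
#' @export
surrogate_fit <- function(x, y, params, degree = 3L, n_verify = 10L,
                          rel_tol = 0.001) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (is.null(colnames(y))) colnames(y) <- paste0("qoi", seq_len(ncol(y)))
  n <- nrow(x)
  stopifnot(n > n_verify + 1)
  lo <- vapply(params, `[[`, numeric(1), "lo")
  hi <- vapply(params, `[[`, numeric(1), "hi")
  to01 <- function(m) sweep(sweep(m, 2, lo, `-`), 2, hi - lo, `/`)
  ver <- seq(n - n_verify + 1, n)       # verification points held out
  tr <- setdiff(seq_len(n), ver)
  x01 <- to01(x)
  deg <- degree
  repeat {
    bb <- legendre_basis(x01[tr, , drop = FALSE], deg)
    if (length(tr) > ncol(bb$B)) {
      fit <- stats::lm.fit(bb$B, y[tr, , drop = FALSE])
      if (fit$rank == ncol(bb$B)) break
    }
    if (deg == 0) stop("surrogate fit is degenerate even at degree 0")
    warning("rank-deficient surrogate basis; reducing degree to ", deg - 1)
    deg <- deg - 1
  }
  coefs <- as.matrix(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  predict_fun <- function(newx) {
    nb <- legendre_basis(to01(newx), deg)$B
    out <- nb %*% coefs
    colnames(out) <- colnames(y)
    out
  }
  pv <- predict_fun(x[ver, , drop = FALSE])
  verr <- apply(abs(pv - y[ver, , drop = FALSE]), 2, max)
  rng <- apply(y, 2, function(v) diff(range(v)))
  rel <- ifelse(rng > 0, verr / rng, 0)
  structure(list(predict = predict_fun, degree = deg,
                 verification_error = verr, rel_error = rel,
                 accepted = all(rel <= rel_tol),
                 n_train = length(tr), n_verify = n_verify),
            class = "litt_surrogate")
}

#' Monte-Carlo uncertainty propagation
#'
#' Samples the parameter box, evaluates the model (or an accepted
#' surrogate), and summarizes each QoI: mean, standard deviation, min, max,
#' 10th/90th percentiles, 95 % interval bounds and — when a surrogate is
#' used — its verification error as the model error.
#'
#' @inheritParams saltelli_sobol
#' @param n Monte-Carlo sample count (>= 20).
#' @param surrogate Optional `litt_surrogate` used in place of the model
#'   when `accepted` (or `force_surrogate = TRUE`).
#' @param force_surrogate Use the surrogate even if its verification error
#'   exceeded the acceptance tolerance.
#' @return A `litt_propagation`: tibble `summary`, matrix `samples`.
#' @export
propagate <- function(model, params, n = 200L, seed = 1L, surrogate = NULL,
                      force_surrogate = FALSE) {
  stopifnot(n >= 20)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(n * length(params)), n, length(params))
  x <- scale_unit(u, params)
  use_sur <- !is.null(surrogate) && (surrogate$accepted || force_surrogate)
  y <- if (use_sur) surrogate$predict(x) else eval_model(model, x, params)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  summ <- lapply(seq_len(ncol(y)), function(k) {
    v <- y[, k]
    qs <- stats::quantile(v, c(0.1, 0.9, 0.025, 0.975), names = FALSE)
    tibble::tibble(
      qoi = colnames(y)[k], mean = mean(v), sd = stats::sd(v),
      min = min(v), max = max(v), p10 = qs[1], p90 = qs[2],
      lower95 = qs[3], upper95 = qs[4],
      model_error = if (use_sur) unname(surrogate$verification_error[k])
                    else NA_real_)
  })
  structure(list(summary = dplyr::bind_rows(summ), samples = y, n = n,
                 seed = seed, surrogate_used = use_sur),
            class = "litt_propagation")
}

#' @export
print.litt_propagation <- function(x, ...) {
  cat("<litt_propagation> n:", x$n, " surrogate:", x$surrogate_used, "\n")
  print(x$summary)
  invisible(x)
}

#' Normality diagnostic of the log survival probability
#'
#' Checks the empirical observation that `log(1 - Omega)` of propagated
#' boundary-probe damage is approximately Gaussian while `Omega` itself is
#' right-skewed (kernel-density mode above the median).
#'
#' @param omega_samples Damage-fraction samples in `[0, 1]`; exact ones are
#'   excluded (count reported).
#' @return A tibble: skewness of `Omega`, mode and median of `Omega`,
#'   Shapiro-Wilk statistic and p-value of the log-survival transform,
#'   number of excluded samples.
#' @export
survival_normality_diagnostic <- function(omega_samples) {
  excl <- sum(omega_samples >= 1)
  om <- omega_samples[omega_samples < 1]
  if (length(om) < 3) stop("need at least 3 samples with omega < 1")
  ls <- log_survival(om)
  m <- mean(om); s <- stats::sd(om)
  skew <- if (s > 0) mean((om - m)^3) / s^3 else 0
  dens <- stats::density(om)
  sh <- stats::shapiro.test(ls)
  tibble::tibble(
    skewness = skew,
    mode = dens$x[which.max(dens$y)],
    median = stats::median(om),
    shapiro_w = unname(sh$statistic),
    shapiro_p = sh$p.value,
    n_excluded = excl)
}

#' Build the LITT uncertainty-quantification model
#'
#' Returns the deterministic parameter-to-QoI map used by the Sobol and
#' propagation analyses: given native and coagulated effective attenuation
#' coefficients, replay the pulsed laser-log fixture on a coarse phantom in
#' damage-dependent ("vop") optics mode and report the end-of-treatment
#' damage fraction at the three boundary probes.
#'
#' @param phantom A coarse `litt_phantom` (1 mm spacing keeps each
#'   evaluation at a few seconds).
#' @param log A `litt_laser_log` (the bundled pulsed fixture by default).
#' @param ... Passed to [run_replay()] (materials, solver, ...).
#' @return Function: `n x 2` matrix `(mu_native, mu_coagulated)` -> `n x 3`
#'   matrix of BP damage fractions.
#' @export
litt_uq_model <- function(phantom, log = make_fixture_log(), ...) {
  force(phantom); force(log); dots <- list(...)
  function(x) {
    out <- matrix(NA_real_, nrow(x), 3,
                  dimnames = list(NULL, c("omega_bp1", "omega_bp2",
                                          "omega_bp3")))
    for (i in seq_len(nrow(x))) {
      mu_n <- x[i, 1]; mu_c <- x[i, 2]
      om <- optical_model(
        mu_native = c(brain = mu_n, tumor = mu_n, skull = 0,
                      csf_general = 0, csf_ventricle = 0),
        coagulation_factor = max(mu_c / mu_n, 1), mode = "vop")
      run <- do.call(run_replay, c(list(phantom = phantom, log = log,
                                        optics = om), dots))
      last <- run$series[nrow(run$series), ]
      out[i, ] <- c(last$omega_bp1, last$omega_bp2, last$omega_bp3)
    }
    out
  }
}

#' Default uncertain optical parameters
#'
#' Native and coagulated effective attenuation coefficients, each uniform
#' within +/- 20 % of its nominal value (coagulated nominal = 1.5 x native).
#'
#' @param mu_nominal Nominal native attenuation, 1/m.
#' @param spread Half-width of the uniform range, fraction of nominal.
#' @param coagulation_factor Nominal coagulated / native ratio.
#' @return List of two [uncertain_parameter()]s.
#' @export
default_optical_uncertainty <- function(mu_nominal = 350, spread = 0.2,
                                        coagulation_factor = 1.5) {
  list(
    uncertain_parameter("mu_eff_native", (1 - spread) * mu_nominal,
                        (1 + spread) * mu_nominal),
    uncertain_parameter("mu_eff_coagulated",
                        (1 - spread) * coagulation_factor * mu_nominal,
                        (1 + spread) * coagulation_factor * mu_nominal))
}

#' Surrogate-accelerated Sobol analysis of the LITT model
#'
#' The full pipeline of the optical-parameter uncertainty study: draw a
#' Latin-hypercube training design (plus held-out verification points), run
#' the simulator at each point, fit the polynomial surrogate, and estimate
#' Sobol indices and the doubling-convergence diagnostic on the surrogate,
#' where the Saltelli design is cheap.
#'
#' @param phantom Coarse phantom for the QoI model.
#' @param params Uncertain parameters ([default_optical_uncertainty()]).
#' @param log Laser-log fixture.
#' @param n_train Training-sample count for the surrogate (default 20).
#' @param n_verify Held-out verification points (default 10).
#' @param n_base Saltelli base sample on the surrogate (cheap there, so
#'   large enough for the doubling-convergence criterion).
#' @param seed Integer seed for all sampling.
#' @param ... Passed to [run_replay()] via [litt_uq_model()].
#' @return List: `sobol` (`litt_sobol`), `convergence` (max index change on
#'   doubling), `surrogate`, `propagation`, `training` (x, y).
#' @export
litt_uq_study <- function(phantom, params = default_optical_uncertainty(),
                          log = make_fixture_log(), n_train = 20L,
                          n_verify = 10L, n_base = 32768L, seed = 1L, ...) {
  model <- litt_uq_model(phantom, log, ...)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_train + n_verify, length(params))
  x <- scale_unit(u, params)
  y <- model(x)
  sur <- surrogate_fit(x, y, params, degree = 3L, n_verify = n_verify)
  smodel <- function(m) sur$predict(m)
  conv <- convergence_check(smodel, params, n_base = n_base, seed = seed)
  prop <- propagate(smodel, params, n = 2000L, seed = seed)
  prop$summary$model_error <- unname(sur$verification_error)
  list(sobol = conv$at_2n, convergence = conv, surrogate = sur,
       propagation = prop, training = list(x = x, y = y))
}
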