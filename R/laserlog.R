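#' Read a clinical-style laser log
#'
#' Delimited text with header `t_s,power_W,tip_z_mm`: breakpoints of a
#' piecewise-linear laser power schedule and a stepwise tip position (the
#' tip holds its value until the next breakpoint; position changes are
#' retractions).
#'
#' @param path CSV file path.
#' @return A tibble with class `litt_laser_log` (columns `t_s`, `power_W`,
#'   `tip_z_mm`).
#' @export
read_laser_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "power_W", "tip_z_mm")
  if (!identical(names(raw)[seq_along(need)], need))
    stop("laser log must have header ", paste(need, collapse = ","))
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0)
      stop("laser log parse error at line ", bad[1] + 1,
           ": non-numeric ", col)
    raw[[col]] <- as.numeric(raw[[col]])
  }
  validate_laser_log(raw)
  tibble::new_tibble(tibble::as_tibble(raw[need]),
                     class = "litt_laser_log")
}

validate_laser_log <- function(log) {
  if (nrow(log) < 2) stop("laser log needs at least two breakpoints")
  dup <- which(diff(log$t_s) <= 0)
  if (length(dup) > 0)
    stop("laser log parse error at line ", dup[1] + 2,
         ": breakpoint times must be strictly increasing")
  neg <- which(log$power_W < 0)
  if (length(neg) > 0)
    stop("laser log parse error at line ", neg[1] + 1, ": negative power")
  rev <- which(diff(log$tip_z_mm) < 0)
  if (length(rev) > 0)
    stop("laser log parse error at line ", rev[1] + 2,
         ": tip position reverses (insertion); only retraction is allowed")
  invisible(log)
}

#' Write a laser log to CSV
#' @param log A `litt_laser_log` (or data frame with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_laser_log <- function(log, path) {
  utils::write.csv(log[, c("t_s", "power_W", "tip_z_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a laser log at arbitrary times
#'
#' Power is interpolated linearly between breakpoints; tip position is held
#' constant from the previous breakpoint (stepwise retraction).
#'
#' @param log A `litt_laser_log`.
#' @param t Times, s.
#' @return A tibble with `t_s`, `power_W`, `tip_z_mm`.
#' @export
log_at <- function(log, t) {
  p <- stats::approx(log$t_s, log$power_W, xout = t, rule = 2)$y
  z <- stats::approx(log$t_s, log$tip_z_mm, xout = t, method = "constant",
                     f = 0, rule = 2)$y
  tibble::tibble(t_s = t, power_W = p, tip_z_mm = z)
}

#' Commanded energy of a laser log
#'
#' Trapezoid integral of the piecewise-linear power schedule (exact for the
#' log's own breakpoints), J.
#'
#' @param log A `litt_laser_log`.
#' @param t_end Optional truncation time, s.
#' @return Energy, J.
#' @export
log_energy <- function(log, t_end = NULL) {
  t <- log$t_s; p <- log$power_W
  if (!is.null(t_end)) {
    keep <- t < t_end
    t <- c(t[keep], t_end)
    p <- c(p[keep], stats::approx(log$t_s, log$power_W, xout = t_end,
                                  rule = 2)$y)
  }
  sum(diff(t) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Retraction events encoded in a laser log
#' @param log A `litt_laser_log`.
#' @return Tibble: `t_s` and `delta_mm` of each tip move.
#' @export
log_retractions <- function(log) {
  d <- diff(log$tip_z_mm)
  ev <- which(d != 0)
  tibble::tibble(t_s = log$t_s[ev + 1], delta_mm = d[ev])
}

#' Generate the synthetic pulsed clinical laser log fixture
#'
#' A deterministic stand-in for a de-identified clinical laser log: three
#' pulse trains (one per stage plane) of short on pulses with longer cooling
#' gaps — the duty cycle physicians use to stay clear of the 100 degree
#' vaporization limit under MRTi guidance — separated by two stepwise 5 mm
#' retractions. Durations carry a small seed-controlled jitter (+/- 1 s) so
#' different seeds give different but reproducible schedules.
#'
#' @param style Only `"pulsed_clinical"`.
#' @param seed Integer seed; same seed, same log.
#' @param power Pulse plateau power, W.
#' @param n_pulses Pulses per stage.
#' @param t_on,t_off Nominal pulse on/off durations, s.
#' @param stage_z_mm Tip position (mm) per stage.
#' @param path Optional path; if given the log is also written there.
#' @return A `litt_laser_log`.
#' @export
make_fixture_log <- function(style = "pulsed_clinical", seed = 1L,
                             power = 8, n_pulses = 6L, t_on = 4, t_off = 16,
                             stage_z_mm = c(-5, 0, 5), path = NULL) {
  style <- match.arg(style)
  set.seed(as.integer(seed))
  rows <- list(); t <- 0
  add <- function(t, p, z) rows[[length(rows) + 1]] <<- c(t, p, z)
  add(t, 0, stage_z_mm[1])
  for (stg in 1:3) {
    z <- stage_z_mm[stg]
    for (pu in seq_len(n_pulses)) {
      on <- t_on + sample(-1:1, 1)
      off <- t_off + sample(-1:1, 1)
      add(t + 1, power, z)        # 1 s ramp up
      t <- t + on
      add(t, power, z)
      add(t + 1, 0, z)            # 1 s ramp down
      t <- t + 1 + off
      add(t, 0, z)
    }
    if (stg < 3) add(t + 1, 0, stage_z_mm[stg + 1])  # retraction, laser off
    t <- t + 1
  }
  m <- do.call(rbind, rows)
  log <- tibble::new_tibble(
    tibble::tibble(t_s = m[, 1], power_W = m[, 2], tip_z_mm = m[, 3]),
    class = "litt_laser_log")
  validate_laser_log(log)
  if (!is.null(path)) write_laser_log(log, path)
  log
}
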