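# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a treatment run into its long time series
#'
#' One row per second per probe signal: columns `t_s`, `signal`
#' (`t_cp*`/`t_bp*`/`omega_bp*`), `plane`, `value`, plus the commanded
#' power, stage and tip position.
#'
#' @param x A `litt_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.litt_run <- function(x, ...) {
  x$series |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(t_cp|t_bp|omega_bp)[123]$"),
      names_to = "signal", values_to = "value") |>
    dplyr::mutate(
      plane = as.integer(sub(".*([123])$", "\\1", .data$signal)),
      signal = sub("[123]$", "", .data$signal))
}

#' One-row summary of a treatment run
#'
#' @param x A `litt_run`.
#' @param ... Unused.
#' @return A tibble: lesion coverage, total time, energy, max center-probe
#'   temperature, retraction count, completion flag.
#' @export
glance.litt_run <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    kind = x$kind,
    lc_percent = m$lc_percent,
    total_time_s = m$total_time_s,
    energy_J = m$energy_J,
    max_cp_C = m$max_cp_C,
    n_retractions = m$n_retractions %||% nrow(log_retractions_from_series(x)),
    complete = isTRUE(m$complete))
}

log_retractions_from_series <- function(x) {
  d <- diff(x$series$tip_z_mm)
  tibble::tibble(t_s = x$series$t_s[which(d != 0) + 1],
                 delta_mm = d[d != 0])
}

#' @export
tidy.litt_sobol <- function(x, ...) x$indices

#' @export
glance.litt_sobol <- function(x, ...) {
  tibble::tibble(n_base = x$n_base, seed = x$seed,
                 n_qoi = length(x$variance))
}

#' @export
tidy.litt_propagation <- function(x, ...) x$summary

#' Plot the probe temperatures, damage and laser power of a run
#'
#' Three stacked panels against time: commanded/gated laser power, center-
#' and boundary-probe temperatures (with the 60 and 100 deg C guides), and
#' boundary-probe damage fractions (with the 0.99 retraction threshold).
#'
#' @param object A `litt_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.litt_run <- function(object, ...) {
  long <- tidy(object)
  temps <- dplyr::filter(long, .data$signal %in% c("t_cp", "t_bp")) |>
    dplyr::mutate(panel = "temperature [C]",
                  series = paste0(toupper(sub("t_", "", .data$signal)),
                                  .data$plane))
  dmg <- dplyr::filter(long, .data$signal == "omega_bp") |>
    dplyr::mutate(panel = "damage fraction", series = paste0("BP", .data$plane))
  pow <- object$series |>
    dplyr::transmute(t_s = .data$t_s, value = .data$power_W,
                     panel = "power [W]", series = "laser")
  dat <- dplyr::bind_rows(temps[c("t_s", "value", "panel", "series")],
                          dmg[c("t_s", "value", "panel", "series")], pow)
  guides <- tibble::tibble(
    panel = c("temperature [C]", "temperature [C]", "damage fraction"),
    y = c(60, 100, 0.99))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(data = guides, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Sobol sensitivity indices
#'
#' @param object A `litt_sobol`.
#' @param ... Unused.
#' @return A ggplot object (grouped bars of S1 and ST per parameter and
#'   QoI).
#' @export
autoplot.litt_sobol <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$indices, c("s1", "st"),
                             names_to = "index", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$parameter, y = .data$value,
                                    fill = toupper(.data$index))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$qoi)) +
    ggplot2::labs(x = NULL, y = "Sobol index", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phantom's tissue labels in the r-z half plane
#'
#' @param object A `litt_phantom` (axisymmetric mode).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.litt_phantom <- function(object, ...) {
  stopifnot(object$mode == "axisymmetric_rz")
  dat <- expand.grid(r = object$r, z = object$z)
  dat$label <- as.vector(object$label)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z * 1e3, y = .data$r * 1e3,
                                    fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z [mm]", y = "r [mm]", fill = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
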