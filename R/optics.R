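#' Optical attenuation model
#'
#' Single-parameter damage-dependent optics: each tissue label carries a
#' native effective attenuation coefficient `mu_eff` (1/m), and coagulated
#' tissue attenuates more strongly by the factor `coagulation_factor`.
#' In `"cop"` (constant optical properties) mode the field never changes;
#' in `"vop"` (variable) mode the local coefficient interpolates linearly
#' between native and coagulated with the damage fraction:
#' `mu(x) = mu_native(x) * (1 + Omega(x) * (f_c - 1))`.
#'
#' Default native values (0.35 /mm for brain and tumor at 980 nm) are
#' configuration placeholders, not measured patient values; override them for
#' any quantitative claim about real tissue. Skull and CSF deposition is
#' disabled by default (`mu = 0`).
#'
#' @param mu_native Named numeric, 1/m, per tissue label.
#' @param coagulation_factor Ratio of coagulated to native attenuation
#'   (>= 1; default 1.5).
#' @param mode `"cop"` or `"vop"`.
#' @return A list with class `litt_optics`.
#' @export
optical_model <- function(mu_native = c(brain = 350, tumor = 350,
                                        skull = 0, csf_general = 0,
                                        csf_ventricle = 0),
                          coagulation_factor = 1.5,
                          mode = c("cop", "vop")) {
  mode <- match.arg(mode)
  if (any(mu_native < 0)) stop("mu_native must be non-negative")
  if (coagulation_factor < 1) stop("coagulation_factor must be >= 1")
  structure(list(mu_native = mu_native,
                 coagulation_factor = coagulation_factor, mode = mode),
            class = "litt_optics")
}

#' Damage-dependent effective attenuation field
#'
#' @param model An [optical_model()].
#' @param omega Per-cell damage fraction in `[0, 1]` (values outside are
#'   clipped with a warning). Ignored in `"cop"` mode.
#' @param geom Internal geometry (per-cell labels).
#' @return Per-cell `mu_eff`, 1/m.
#' @export
mueff_field <- function(model, omega, geom) {
  mu0 <- model$mu_native[geom$label]
  if (any(is.na(mu0)))
    stop("optical model lacks mu_native for labels: ",
         paste(unique(geom$label[is.na(mu0)]), collapse = ", "))
  mu0 <- unname(mu0)
  if (model$mode == "cop") return(mu0)
  if (any(omega < 0 | omega > 1)) {
    warning("damage fraction outside [0, 1]; clipping")
    omega <- pmin(pmax(omega, 0), 1)
  }
  mu0 * (1 + omega * (model$coagulation_factor - 1))
}

#' Laser source description
#'
#' @param model `"pslh"` (single point source at the tip center) or `"dphs"`
#'   (`n_sub` point sub-sources spread uniformly along the tip, each carrying
#'   `power / n_sub`).
#' @param power Laser power, W (>= 0).
#' @param tip_z Axial position of the tip center, m (probe on the r = 0 axis
#'   in axisymmetric mode).
#' @param tip_length Tip length, m.
#' @param n_sub Number of sub-sources for `"dphs"`.
#' @return A list with class `litt_laser`.
#' @export
laser_source <- function(model = c("pslh", "dphs"), power = 10,
                         tip_z = -5e-3, tip_length = 5e-3, n_sub = 10L) {
  model <- match.arg(model)
  stopifnot(power >= 0, tip_length > 0, n_sub >= 1)
  structure(list(model = model, power = power, tip_z = tip_z,
                 tip_length = tip_length, n_sub = as.integer(n_sub)),
            class = "litt_laser")
}

source_positions <- function(source) {
  if (source$model == "pslh") return(source$tip_z)
  k <- seq_len(source$n_sub)
  source$tip_z + ((k - 0.5) / source$n_sub - 0.5) * source$tip_length
}

# mu lookup grid: per-voxel mu with 0 in lumen/exterior, plus samplers.
mu_grid <- function(geom, mu_cells) {
  g <- array(0, dim = dim(geom$cell_id))
  ok <- !is.na(geom$cell_id)
  g[ok] <- mu_cells[geom$cell_id[ok]]
  g
}

#' Compute the volumetric laser deposition field
#'
#' Single-parameter light-deposition kernel: each point sub-source `k` at
#' `x_k` with power `P_k` contributes
#' `Q(x) = P_k * mu(x) * exp(-tau_k(x)) / (4*pi*|x - x_k|^2)`, with the
#' optical depth `tau_k` accumulated by midpoint ray sampling of `mu` on the
#' voxel grid between source and target. The kernel conserves energy in a
#' homogeneous medium (total deposited power `P*(1 - exp(-mu*R))` inside
#' radius `R`) and uses only the effective attenuation coefficient, as the
#' single-optical-parameter model requires.
#'
#' @param source A [laser_source()].
#' @param mu Per-cell attenuation, 1/m (from [mueff_field()]).
#' @param geom Internal geometry.
#' @param n_ray Ray-sampling points per cell (midpoint rule).
#' @return A `litt_deposition`: per-cell `q` (W/m^3), `total_deposited` (W),
#'   `power` (W).
#' @export
compute_deposition <- function(source, mu, geom, n_ray = 64L) {
  if (geom$mode == "spherical_1d")
    stop("deposition is defined on phantom geometries only")
  co <- geom$coords
  axisym <- geom$mode == "axisymmetric_rz"
  if (!axisym && is.null(geom$grid$dims))
    stop("unsupported geometry for deposition")
  gmu <- mu_grid(geom, mu)
  gr <- geom$grid
  sample_mu <- if (axisym) {
    function(pr, pz) {
      i <- pmin(pmax(ceiling(pr / gr$dr), 1L), gr$nr)
      j <- ceiling((pz - gr$z0) / gr$dz)
      ok <- j >= 1 & j <= gr$nz
      out <- numeric(length(pr))
      out[ok] <- gmu[cbind(i[ok], j[ok])]
      out
    }
  } else {
    function(px, py, pz) {
      i <- ceiling((px - gr$x0) / gr$sp[1])
      j <- ceiling((py - gr$y0) / gr$sp[2])
      k <- ceiling((pz - gr$z0) / gr$sp[3])
      ok <- i >= 1 & i <= gr$dims[1] & j >= 1 & j <= gr$dims[2] &
        k >= 1 & k <= gr$dims[3]
      out <- numeric(length(px))
      out[ok] <- gmu[cbind(i[ok], j[ok], k[ok])]
      out
    }
  }
  zs <- source_positions(source)
  # source must lie inside the grid
  zmin <- gr$z0
  zmax <- gr$z0 + (if (axisym) gr$nz * gr$dz else gr$dims[3] * gr$sp[3])
  if (any(zs < zmin | zs > zmax)) stop("laser tip lies outside the grid")
  pk <- source$power / length(zs)

  sp_max <- if (axisym) max(gr$dr, gr$dz) else max(gr$sp)
  q <- numeric(geom$n)
  if (source$power > 0) {
    frac <- (seq_len(n_ray) - 0.5) / n_ray
    for (zk in zs) {
      if (axisym) {
        rc <- co[, "r"]; zc <- co[, "z"]
        d <- sqrt(rc^2 + (zc - zk)^2)
        tau <- numeric(geom$n)
        for (s in frac) tau <- tau + sample_mu(s * rc, zk + s * (zc - zk))
        tau <- tau * d / n_ray
      } else {
        # 3-D: source on the probe axis through the volume center
        xc0 <- mean(range(co[, "x"])); yc0 <- mean(range(co[, "y"]))
        dx <- co[, "x"] - xc0; dy <- co[, "y"] - yc0; dzv <- co[, "z"] - zk
        d <- sqrt(dx^2 + dy^2 + dzv^2)
        tau <- numeric(geom$n)
        for (s in frac)
          tau <- tau + sample_mu(xc0 + s * dx, yc0 + s * dy, zk + s * dzv)
        tau <- tau * d / n_ray
      }
      qk <- pk * mu * exp(-tau) / (4 * pi * pmax(d, 1e-9)^2)

      # Near-source cells: midpoint evaluation of the 1/d^2 kernel is poor
      # within a few cells of the sub-source; subsample those cells (with
      # volume weights) and give the cell holding the source its analytic
      # equal-volume-sphere absorption.
      near <- which(d < 4 * sp_max & mu > 0)
      if (length(near) > 0) {
        ns <- if (axisym) 16L else 8L
        off <- ((seq_len(ns) - 0.5) / ns - 0.5)
        for (ci in near) {
          if (!axisym && d[ci] < 0.5 * min(gr$sp)) {
            # cell holding the source: analytic equal-volume-sphere absorption
            r_eq <- (3 * geom$vol[ci] / (4 * pi))^(1 / 3)
            qk[ci] <- pk * (1 - exp(-mu[ci] * r_eq)) / geom$vol[ci]
            next
          }
          if (axisym) {
            rs <- co[ci, "r"] + off * gr$dr
            zss <- co[ci, "z"] + off * gr$dz
            pts <- expand.grid(r = rs, z = zss)
            w <- pts$r  # ring volume weight
            ds <- pmax(sqrt(pts$r^2 + (pts$z - zk)^2), 1e-9)
          } else {
            xs <- co[ci, "x"] + off * gr$sp[1]
            ys <- co[ci, "y"] + off * gr$sp[2]
            zss <- co[ci, "z"] + off * gr$sp[3]
            pts <- expand.grid(x = xs, y = ys, z = zss)
            w <- rep(1, nrow(pts))
            ds <- pmax(sqrt((pts$x - xc0)^2 + (pts$y - yc0)^2 +
                              (pts$z - zk)^2), 1e-9)
          }
          # local optical depth scales ~ linearly with distance
          tau_s <- if (d[ci] > 0) tau[ci] * ds / d[ci] else mu[ci] * ds
          kern <- pk * mu[ci] * exp(-tau_s) / (4 * pi * ds^2)
          qk[ci] <- sum(w * kern) / sum(w)
        }
      }
      q <- q + qk
    }
  }
  dep <- structure(list(q = q, power = source$power,
                        total_deposited = sum(q * geom$vol),
                        source = source),
                   class = "litt_deposition")
  dep
}

#' Power deposited in a region
#'
#' Volume integral of the deposition field over a set of cells (the whole
#' domain by default). The whole-domain value never exceeds the source power.
#'
#' @param deposition A `litt_deposition`.
#' @param geom Internal geometry.
#' @param cells Optional integer cell ids (e.g. from a probe mask); `NULL`
#'   for the whole domain.
#' @return Power, W.
#' @export
deposited_power <- function(deposition, geom, cells = NULL) {
  if (is.null(cells)) return(sum(deposition$q * geom$vol))
  if (length(cells) == 0) return(0)
  sum(deposition$q[cells] * geom$vol[cells])
}

#' Rescale a deposition field to a reference deposited power
#'
#' Multiplies the field by `reference / actual` so that runs with different
#' optical fields (e.g. constant vs damage-dependent) deposit equal total
#' power in the domain; the factor is recorded on the result.
#'
#' @param deposition A `litt_deposition` with positive deposited power.
#' @param reference_deposited Target whole-domain deposited power, W.
#' @param geom Internal geometry.
#' @return The scaled `litt_deposition`, with attribute `scale_factor`.
#' @export
scale_to_reference_deposition <- function(deposition, reference_deposited,
                                          geom) {
  actual <- deposited_power(deposition, geom)
  if (actual <= 0) stop("deposition field has zero deposited power")
  fac <- reference_deposited / actual
  deposition$q <- deposition$q * fac
  deposition$total_deposited <- actual * fac
  attr(deposition, "scale_factor") <- fac
  deposition
}
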