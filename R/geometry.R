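# Face-graph geometry shared by the axisymmetric and 3-D Cartesian solvers.
# The bioheat step is dimension-agnostic: it only sees cells (volumes,
# material labels), interior faces (area, center distance) and boundary
# faces (area, half-distance, kind). Finite-volume conductances built on
# this graph keep the discrete scheme conservative, which the per-step
# energy-budget check relies on.

phantom_geometry <- function(phantom, materials = default_materials(),
                             peritumoral_margin = 5e-3) {
  validate_materials(materials)
  lab <- phantom$label
  tissue <- lab %in% labels_tissue_only()
  cell_id <- array(NA_integer_, dim = dim(lab))
  cell_id[tissue] <- seq_len(sum(tissue))
  n <- sum(tissue)
  if (n == 0) stop("phantom contains no tissue voxels")

  faces_acc <- list(); bfaces_acc <- list()
  push_faces <- function(a, b, lab_a, lab_b, area, d, fz) {
    both <- !is.na(a) & !is.na(b)
    if (any(both))
      faces_acc[[length(faces_acc) + 1]] <<- data.frame(
        a = a[both], b = b[both], area = area[both], d = d)
    h1 <- !is.na(a) & is.na(b)
    if (any(h1))
      bfaces_acc[[length(bfaces_acc) + 1]] <<- data.frame(
        cell = a[h1], area = area[h1], dh = d / 2,
        kind = ifelse(lab_b[h1] == "probe_lumen", "lumen", "outer"),
        fz = fz[h1])
    h2 <- is.na(a) & !is.na(b)
    if (any(h2))
      bfaces_acc[[length(bfaces_acc) + 1]] <<- data.frame(
        cell = b[h2], area = area[h2], dh = d / 2,
        kind = ifelse(lab_a[h2] == "probe_lumen", "lumen", "outer"),
        fz = fz[h2])
  }
  push_edge <- function(ids, labs, area, dh, fz) {
    ok <- !is.na(ids)
    if (any(ok))
      bfaces_acc[[length(bfaces_acc) + 1]] <<- data.frame(
        cell = ids[ok], area = area[ok], dh = dh, kind = "outer", fz = fz[ok])
  }

  if (phantom$mode == "axisymmetric_rz") {
    nr <- length(phantom$r); nz <- length(phantom$z)
    dr <- phantom$dr; dz <- phantom$dz
    rg <- matrix(phantom$r, nr, nz)
    zg <- matrix(phantom$z, nr, nz, byrow = TRUE)
    coords <- cbind(r = rg[tissue], z = zg[tissue])
    vol <- phantom$vol[tissue]

    # radial faces (i,j)-(i+1,j): cylinder at radius i*dr
    a <- cell_id[-nr, , drop = FALSE]; b <- cell_id[-1, , drop = FALSE]
    push_faces(a, b, lab[-nr, , drop = FALSE], lab[-1, , drop = FALSE],
               matrix(2 * pi * (seq_len(nr - 1) * dr) * dz, nr - 1, nz),
               dr, zg[-nr, , drop = FALSE])
    # axial faces (i,j)-(i,j+1): annulus 2*pi*r*dr
    a <- cell_id[, -nz, drop = FALSE]; b <- cell_id[, -1, drop = FALSE]
    push_faces(a, b, lab[, -nz, drop = FALSE], lab[, -1, drop = FALSE],
               matrix(2 * pi * phantom$r * dr, nr, nz - 1),
               dz, (zg[, -nz, drop = FALSE] + zg[, -1, drop = FALSE]) / 2)
    # grid edges: outer radius and both z ends (axis face has zero area)
    push_edge(cell_id[nr, ], lab[nr, ],
              rep(2 * pi * (nr * dr) * dz, nz), dr / 2, phantom$z)
    push_edge(cell_id[, 1], lab[, 1],
              2 * pi * phantom$r * dr, dz / 2,
              rep(phantom$z[1] - dz / 2, nr))
    push_edge(cell_id[, nz], lab[, nz],
              2 * pi * phantom$r * dr, dz / 2,
              rep(phantom$z[nz] + dz / 2, nr))
    grid <- list(nr = nr, nz = nz, dr = dr, dz = dz,
                 z0 = phantom$z[1] - dz / 2)
  } else if (phantom$mode == "cartesian_3d") {
    dims <- dim(lab); sp <- phantom$spacing
    axl <- list(phantom$x, phantom$y, phantom$z3)
    cg <- lapply(1:3, function(k) {
      perm <- array(0, dims)
      sweep(perm, k, axl[[k]], `+`)
    })
    coords <- cbind(x = cg[[1]][tissue], y = cg[[2]][tissue],
                    z = cg[[3]][tissue])
    vol <- phantom$vol[tissue]
    sub <- function(x, k, idx) {
      ix <- lapply(dims, seq_len); ix[[k]] <- idx
      do.call(`[`, c(list(x), ix, drop = FALSE))
    }
    for (k in 1:3) {
      lo <- seq_len(dims[k] - 1); hi <- 2:dims[k]
      a <- sub(cell_id, k, lo); b <- sub(cell_id, k, hi)
      la <- sub(lab, k, lo); lb <- sub(lab, k, hi)
      fz <- (sub(cg[[3]], k, lo) + sub(cg[[3]], k, hi)) / 2
      area <- array(prod(sp[-k]), dim = dim(a))
      push_faces(a, b, la, lb, area, sp[k], fz)
      for (end in c(1L, dims[k])) {
        e <- sub(cell_id, k, end); le <- sub(lab, k, end)
        fze <- sub(cg[[3]], k, end) +
          (if (end == 1L) -sp[k] / 2 else sp[k] / 2) * (k == 3)
        push_edge(e, le, array(prod(sp[-k]), dim = dim(e)), sp[k] / 2, fze)
      }
    }
    grid <- list(dims = dims, sp = sp,
                 x0 = phantom$x[1] - sp[1] / 2,
                 y0 = phantom$y[1] - sp[2] / 2,
                 z0 = phantom$z3[1] - sp[3] / 2)
  } else stop("unknown phantom mode: ", phantom$mode)

  faces <- do.call(rbind, faces_acc)
  bfaces <- if (length(bfaces_acc) > 0) do.call(rbind, bfaces_acc) else
    data.frame(cell = integer(), area = numeric(), dh = numeric(),
               kind = character(), fz = numeric())

  labv <- lab[tissue]
  m <- materials[match(labv, materials$label), ]
  if (any(is.na(m$density)))
    stop("materials table lacks rows for labels: ",
         paste(unique(labv[is.na(m$density)]), collapse = ", "))

  geom <- list(
    n = n, mode = phantom$mode, cell_id = cell_id, coords = coords,
    vol = vol, label = labv, faces = faces, bfaces = bfaces, grid = grid,
    rho = m$density, cp0 = m$heat_capacity, k0 = m$conductivity,
    enh = m$csf_enhancement, perf0 = m$perfusion, qmet = m$q_met,
    coeff_k = m$temp_coeff_k, coeff_c = m$temp_coeff_c,
    tumor = labv == "tumor"
  )
  geom$peritumoral <- peritumoral_cells(phantom, geom,
                                        margin = peritumoral_margin)
  class(geom) <- "litt_geometry"
  geom
}

# Brain cells within `margin` of the tumor, found by dilating the tumor mask
# on the voxel grid. Used for damage-dependent perfusion shutdown.
peritumoral_cells <- function(phantom, geom, margin = 5e-3) {
  lab <- phantom$label
  tum <- lab == "tumor"
  if (!any(tum)) return(rep(FALSE, geom$n))
  sp <- if (phantom$mode == "axisymmetric_rz") min(phantom$dr, phantom$dz)
        else min(phantom$spacing)
  steps <- max(0L, as.integer(round(margin / sp)))
  grown <- tum
  dims <- dim(lab)
  for (s in seq_len(steps)) {
    g2 <- grown
    if (length(dims) == 2) {
      g2[-1, ] <- g2[-1, ] | grown[-dims[1], ]
      g2[-dims[1], ] <- g2[-dims[1], ] | grown[-1, ]
      g2[, -1] <- g2[, -1] | grown[, -dims[2]]
      g2[, -dims[2]] <- g2[, -dims[2]] | grown[, -1]
    } else {
      g2[-1, , ] <- g2[-1, , ] | grown[-dims[1], , ]
      g2[-dims[1], , ] <- g2[-dims[1], , ] | grown[-1, , ]
      g2[, -1, ] <- g2[, -1, ] | grown[, -dims[2], ]
      g2[, -dims[2], ] <- g2[, -dims[2], ] | grown[, -1, ]
      g2[, , -1] <- g2[, , -1] | grown[, , -dims[3]]
      g2[, , -dims[3]] <- g2[, , -dims[3]] | grown[, , -1]
    }
    grown <- g2
  }
  peri <- (grown & lab == "brain") | tum
  peri[!lab %in% labels_tissue_only()] <- FALSE
  out <- rep(FALSE, geom$n)
  ids <- geom$cell_id[peri & !is.na(geom$cell_id)]
  out[ids] <- TRUE
  out
}

# Convert a grid logical mask into tissue-cell ids.
mask_cells <- function(geom, mask) {
  ids <- geom$cell_id[mask]
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0) stop("mask covers no tissue cells")
  sort(ids)
}

# Scatter a per-cell vector back onto the voxel grid (NA off-tissue).
cells_to_grid <- function(geom, values) {
  out <- array(NA_real_, dim = dim(geom$cell_id))
  out[!is.na(geom$cell_id)] <- values[geom$cell_id[!is.na(geom$cell_id)]]
  out
}
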