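#' Tissue labels used by the head phantom
#'
#' The five anatomical domains of the simulated head (skull, general CSF,
#' brain, CSF ventricles, tumor) plus the carved probe lumen and the
#' exterior (air) region. Lumen and exterior voxels are excluded from the
#' tissue heat-transfer domain.
#'
#' @return Character vector of label names, in code order.
#' @export
tissue_labels <- function() {
  c("skull", "csf_general", "brain", "csf_ventricle", "tumor",
    "probe_lumen", "exterior")
}

labels_tissue_only <- function() {
  c("skull", "csf_general", "brain", "csf_ventricle", "tumor")
}

#' Default material property table
#'
#' One row per tissue label: density (kg/m^3), heat capacity (J/kg/K),
#' thermal conductivity (W/m/K), blood perfusion rate (1/s), metabolic heat
#' (W/m^3), exponential temperature coefficients for k and Cp (1/K, zero for
#' skull and CSF which are modeled with constant properties), and the
#' convective-enhancement multiplier applied to CSF conductivity.
#'
#' Values are representative literature figures for brain tissue at 37 deg C
#' and are configuration, not measurements; override any of them via the
#' `materials` section of the run configuration.
#'
#' @return A tibble with one row per tissue label.
#' @export
default_materials <- function() {
  tibble::tibble(
    label         = c("skull", "csf_general", "brain", "csf_ventricle", "tumor"),
    density       = c(1908, 1007, 1043, 1007, 1045),
    heat_capacity = c(1312, 4096, 3680, 4096, 3760),
    conductivity  = c(0.32, 0.57, 0.51, 0.57, 0.55),
    perfusion     = c(5e-4, 0, 8.3e-3, 0, 2e-3),
    q_met         = c(70, 0, 16700, 0, 25000),
    temp_coeff_k  = c(0, 0, 2e-3, 0, 2e-3),
    temp_coeff_c  = c(0, 0, 2e-3, 0, 2e-3),
    csf_enhancement = c(1, 10, 1, 10, 1)
  )
}

#' Blood properties for the perfusion heat sink
#'
#' @param density Blood density, kg/m^3.
#' @param heat_capacity Blood specific heat, J/(kg K).
#' @param temperature Arterial blood temperature, deg C; equals the baseline
#'   initial tissue temperature.
#' @return A list with class `litt_blood`.
#' @export
blood_properties <- function(density = 1050, heat_capacity = 3617,
                             temperature = 37) {
  stopifnot(density > 0, heat_capacity > 0)
  structure(list(density = density, heat_capacity = heat_capacity,
                 temperature = temperature), class = "litt_blood")
}

validate_materials <- function(materials) {
  need <- c("label", "density", "heat_capacity", "conductivity", "perfusion",
            "q_met", "temp_coeff_k", "temp_coeff_c", "csf_enhancement")
  miss <- setdiff(need, names(materials))
  if (length(miss) > 0)
    stop("materials table is missing columns: ", paste(miss, collapse = ", "))
  if (any(materials$density <= 0) || any(materials$heat_capacity <= 0) ||
      any(materials$conductivity <= 0))
    stop("density, heat_capacity and conductivity must be strictly positive")
  if (any(materials$perfusion < 0) || any(materials$q_met < 0))
    stop("perfusion and q_met must be non-negative")
  fixed <- materials$label %in% c("skull", "csf_general", "csf_ventricle")
  if (any(materials$temp_coeff_k[fixed] != 0) ||
      any(materials$temp_coeff_c[fixed] != 0))
    stop("skull and CSF labels must have zero temperature coefficients ",
         "(constant thermal properties)")
  invisible(materials)
}

#' Probe track geometry
#'
#' Describes the laser catheter: tip diameter and length, the three stage
#' planes (one per heat-source position, separated by the 5 mm retraction
#' increment, stage 1 deepest), and the current stage.
#'
#' @param stage_z Numeric length-3, z coordinates (m) of the stage planes in
#'   increasing order; consecutive planes must be separated by `increment`.
#' @param tip_diameter Laser tip diameter, m.
#' @param tip_length Laser tip length, m.
#' @param increment Retraction increment, m.
#' @return A list with class `litt_probe_track`.
#' @export
probe_track <- function(stage_z = c(-5e-3, 0, 5e-3),
                        tip_diameter = 1.65e-3, tip_length = 5e-3,
                        increment = 5e-3) {
  stopifnot(length(stage_z) == 3, tip_diameter > 0, tip_length > 0)
  gaps <- diff(stage_z)
  if (any(abs(gaps - increment) > 1e-12))
    stop("stage planes must be separated by exactly the retraction increment")
  structure(list(stage_z = stage_z, tip_diameter = tip_diameter,
                 tip_length = tip_length, increment = increment, stage = 1L),
            class = "litt_probe_track")
}

#' Build a concentric-shell head phantom (axisymmetric r-z grid)
#'
#' Generates the synthetic stand-in for a segmented patient head: a spherical
#' tumor at the origin surrounded by concentric brain, general-CSF and skull
#' shells, with the laser probe lumen carved along the z axis down to the
#' stage-1 tip, and an optional CSF-ventricle ring inside the brain shell.
#' The probe axis coincides with r = 0.
#'
#' @param tumor_radius Tumor sphere radius, m. May be 0 (no tumor voxels).
#' @param shell_thicknesses Named numeric: thickness (m) of `brain`,
#'   `csf_general` and `skull` shells, inside out.
#' @param spacing Grid spacing, m (isotropic; default 0.5 mm).
#' @param track A [probe_track()].
#' @param ventricle Either `NULL` (no ventricle) or a list with
#'   `r = c(r1, r2)`, `z = c(z1, z2)` (m) describing a CSF-ventricle ring
#'   carved out of the brain shell.
#' @return A `litt_phantom` object (mode `"axisymmetric_rz"`).
#' @export
build_concentric_phantom <- function(tumor_radius = 10e-3,
                                     shell_thicknesses = c(brain = 15e-3,
                                                           csf_general = 3e-3,
                                                           skull = 7e-3),
                                     spacing = 0.5e-3,
                                     track = probe_track(),
                                     ventricle = list(r = NULL, z = NULL)) {
  stopifnot(tumor_radius >= 0, spacing > 0)
  if (spacing > track$tip_diameter)
    stop("grid spacing ", spacing, " m exceeds the probe diameter ",
         track$tip_diameter, " m: the probe lumen is unresolvable")
  if (tumor_radius > 0 && tumor_radius <= track$tip_diameter / 2)
    stop("tumor_radius must exceed the probe tip radius")
  th <- shell_thicknesses
  r_brain <- tumor_radius + th[["brain"]]
  r_csf   <- r_brain + th[["csf_general"]]
  r_skull <- r_csf + th[["skull"]]

  dr <- spacing; dz <- spacing
  nr <- ceiling(r_skull / dr)
  nz2 <- ceiling(r_skull / dz)
  r <- (seq_len(nr) - 0.5) * dr
  z <- (seq(-nz2, nz2 - 1) + 0.5) * dz
  nz <- length(z)

  rg <- matrix(r, nr, nz)
  zg <- matrix(z, nr, nz, byrow = TRUE)
  rho <- sqrt(rg^2 + zg^2)

  lab <- matrix("exterior", nr, nz)
  lab[rho < r_skull] <- "skull"
  lab[rho < r_csf]   <- "csf_general"
  lab[rho < r_brain] <- "brain"
  lab[rho < tumor_radius] <- "tumor"

  if (!is.null(ventricle$r) && !is.null(ventricle$z)) {
    vent <- rg >= ventricle$r[1] & rg <= ventricle$r[2] &
            zg >= ventricle$z[1] & zg <= ventricle$z[2] & lab == "brain"
    lab[vent] <- "csf_ventricle"
  }

  # Lumen: carved along the axis from the stage-1 tip bottom up through the
  # top of the head (catheter entry).
  lumen_z_min <- track$stage_z[1] - track$tip_length / 2
  lumen_r <- track$tip_diameter / 2
  lum <- rg < lumen_r & zg >= lumen_z_min & lab != "exterior"
  lab[lum] <- "probe_lumen"

  vol <- 2 * pi * rg * dr * dz

  structure(list(
    mode = "axisymmetric_rz", label = lab, r = r, z = z, dr = dr, dz = dz,
    vol = vol, tumor_radius = tumor_radius,
    shell_radii = c(tumor = tumor_radius, brain = r_brain,
                    csf_general = r_csf, skull = r_skull),
    track = track, lumen_radius = lumen_r, lumen_z_min = lumen_z_min
  ), class = "litt_phantom")
}

#' @export
print.litt_phantom <- function(x, ...) {
  dims <- if (x$mode == "axisymmetric_rz")
    paste0(length(x$r), " x ", length(x$z), " (r x z)")
  else paste(dim(x$label), collapse = " x ")
  cat("<litt_phantom> mode:", x$mode, " grid:", dims,
      " spacing:", format(x$dr * 1e3), "mm\n")
  tab <- label_counts(x)
  cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Voxel counts per tissue label
#' @param phantom A `litt_phantom`.
#' @return Named integer vector over [tissue_labels()].
#' @export
label_counts <- function(phantom) {
  table(factor(phantom$label, levels = tissue_labels()))
}

#' Voxelized volume of a label region
#'
#' Sum of voxel volumes carrying `label` (ring volumes `2*pi*r*dr*dz` in
#' axisymmetric mode, `dx*dy*dz` in 3-D mode).
#'
#' @param phantom A `litt_phantom`.
#' @param label A tissue label name.
#' @return Volume in m^3.
#' @export
label_volume <- function(phantom, label) {
  sum(phantom$vol[phantom$label == label])
}

#' Place the virtual MR-thermometry probe voxels
#'
#' For each of the three stage planes, builds the center-probe (CP) mask
#' (annular cylinder hugging the lumen: inner diameter 1.65 mm, wall 1 mm,
#' height 3 mm) and the boundary-probe (BP) mask (1 x 1 x 3 mm cuboid, or its
#' r-z ring equivalent in axisymmetric mode, touching the tumor boundary from
#' inside at radius `sqrt(R^2 - z_j^2)`).
#'
#' @param phantom A `litt_phantom` built by [build_concentric_phantom()].
#' @param track A [probe_track()]; defaults to the phantom's.
#' @param wall CP annulus wall thickness, m (the MRTi voxel edge).
#' @param height Probe voxel height, m.
#' @return A list of three elements (one per plane), each with logical masks
#'   `cp` and `bp` on the phantom grid and the BP touch radius `bp_radius`.
#' @export
place_probes <- function(phantom, track = phantom$track,
                         wall = 1e-3, height = 3e-3) {
  stopifnot(phantom$mode == "axisymmetric_rz")
  R <- phantom$tumor_radius
  rg <- matrix(phantom$r, length(phantom$r), length(phantom$z))
  zg <- matrix(phantom$z, length(phantom$r), length(phantom$z), byrow = TRUE)
  out <- vector("list", 3)
  for (j in 1:3) {
    zj <- track$stage_z[j]
    if (abs(zj) >= R)
      stop("stage plane ", j, " (z = ", zj, " m) lies outside the tumor")
    in_plane <- abs(zg - zj) <= height / 2
    r_in <- track$tip_diameter / 2
    cp <- in_plane & rg >= r_in & rg <= r_in + wall &
      phantom$label %in% labels_tissue_only()
    rb <- sqrt(R^2 - zj^2)
    bp <- in_plane & rg >= rb - wall & rg <= rb & phantom$label == "tumor"
    if (!any(cp)) stop("CP mask empty at plane ", j, "; refine the grid")
    if (!any(bp)) stop("BP mask empty at plane ", j, "; refine the grid")
    out[[j]] <- list(cp = cp, bp = bp, bp_radius = rb, z = zj)
  }
  class(out) <- "litt_probes"
  out
}

#' Volume-weighted average of a field over a probe mask
#'
#' Emulates the voxel averaging of MR temperature imaging: the probe reading
#' is the volume-weighted mean of the field over the mask (ring-volume
#' weights `2*pi*r*dr*dz` in axisymmetric mode).
#'
#' @param field Numeric matrix/array on the phantom grid.
#' @param mask Logical mask of the same shape.
#' @param phantom The `litt_phantom` providing voxel volumes.
#' @return Scalar average.
#' @export
probe_average <- function(field, mask, phantom) {
  if (!any(mask)) stop("probe mask is empty")
  sum(field[mask] * phantom$vol[mask]) / sum(phantom$vol[mask])
}

#' Load a labelled 3-D voxel map from NIfTI
#'
#' Reads an integer-valued NIfTI volume and a label dictionary mapping
#' integer codes to [tissue_labels()] names, returning a 3-D Cartesian
#' `litt_phantom` with spacings taken from the NIfTI header.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param label_dict Named integer vector or list: names are tissue labels,
#'   values the integer codes in the volume. All codes present in the volume
#'   must be mapped.
#' @param tumor_radius Optional nominal tumor radius (m) carried as metadata.
#' @return A `litt_phantom` with mode `"cartesian_3d"`.
#' @export
load_label_map <- function(path, label_dict, tumor_radius = NA_real_) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (any(abs(arr - round(arr)) > 1e-9))
    stop("label map must be integer-valued")
  arr <- round(arr)
  codes <- sort(unique(as.vector(arr)))
  dict <- unlist(label_dict)
  bad_names <- setdiff(names(dict), tissue_labels())
  if (length(bad_names) > 0)
    stop("unknown label names in dictionary: ", paste(bad_names, collapse = ", "))
  unmapped <- setdiff(codes, unname(dict))
  if (length(unmapped) > 0)
    stop("unmapped label codes in volume: ", paste(unmapped, collapse = ", "))
  lab <- array("exterior", dim = dim(arr))
  for (nm in names(dict)) lab[arr == dict[[nm]]] <- nm
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0)) pd <- rep(1, 3)
  sp <- pd * 1e-3  # NIfTI pixdim in mm -> m
  dims <- dim(arr)
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * sp[k])
  vol <- array(prod(sp), dim = dims)
  structure(list(
    mode = "cartesian_3d", label = lab,
    x = ax[[1]], y = ax[[2]], z3 = ax[[3]],
    spacing = sp, dr = sp[1], dz = sp[3], vol = vol,
    tumor_radius = tumor_radius, affine = structure(RNifti::xform(img)),
    track = NULL
  ), class = "litt_phantom")
}

#' Save a 3-D phantom label map to NIfTI
#'
#' Inverse of [load_label_map()]: writes the integer-coded label volume.
#'
#' @param phantom A `litt_phantom` with mode `"cartesian_3d"`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param label_dict Named integer mapping as in [load_label_map()].
#' @return `path`, invisibly.
#' @export
save_label_map <- function(phantom, path, label_dict) {
  stopifnot(phantom$mode == "cartesian_3d")
  dict <- unlist(label_dict)
  arr <- array(0L, dim = dim(phantom$label))
  for (nm in names(dict)) arr[phantom$label == nm] <- as.integer(dict[[nm]])
  img <- RNifti::asNifti(arr, internal = FALSE)
  img <- RNifti::`pixdim<-`(img, phantom$spacing * 1e3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
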