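test_that("concentric phantom labels partition the grid exactly once", {
  ph <- small_phantom()
  counts <- label_counts(ph)
  expect_equal(sum(counts), length(ph$label))
  expect_true(all(ph$label %in% tissue_labels()))
})

test_that("zero tumor radius gives zero tumor voxels", {
  ph <- build_concentric_phantom(
    tumor_radius = 0,
    shell_thicknesses = c(brain = 10e-3, csf_general = 2e-3, skull = 3e-3),
    spacing = 1e-3)
  expect_equal(unname(label_counts(ph)[["tumor"]]), 0)
})

test_that("voxelized tumor volume approaches the analytic sphere volume", {
  # lumen carving removes a small known cylinder; add it back for the check
  vol_with_lumen <- function(spacing) {
    ph <- build_concentric_phantom(tumor_radius = 10e-3, spacing = spacing)
    in_tumor_lumen <- ph$label == "probe_lumen" &
      outer(ph$r^2, ph$z^2, `+`) < ph$tumor_radius^2
    label_volume(ph, "tumor") + sum(ph$vol[in_tumor_lumen])
  }
  v_true <- 4 / 3 * pi * (10e-3)^3
  expect_lt(abs(vol_with_lumen(0.5e-3) - v_true) / v_true, 0.02)
  # voxelization error oscillates; across a 4x refinement it must shrink
  err_coarse <- abs(vol_with_lumen(1e-3) - v_true) / v_true
  err_fine <- abs(vol_with_lumen(0.25e-3) - v_true) / v_true
  expect_lt(err_fine, err_coarse / 2)
})

test_that("spacing larger than the probe diameter is rejected", {
  expect_error(build_concentric_phantom(spacing = 2e-3), "unresolvable")
})

test_that("probe masks sit on sphere geometry and stay inside the tumor", {
  ph <- build_concentric_phantom(tumor_radius = 10e-3, spacing = 0.5e-3)
  pr <- place_probes(ph)
  expect_equal(vapply(pr, `[[`, numeric(1), "bp_radius"),
               c(sqrt(75e-6), 10e-3, sqrt(75e-6)), tolerance = 1e-12)
  for (p in pr) {
    expect_true(all(ph$label[p$bp] == "tumor"))
    expect_true(all(ph$label[p$cp] %in%
                      c("tumor", "brain", "csf_general", "csf_ventricle")))
  }
})

test_that("stage plane outside the tumor raises an error naming the plane", {
  ph <- build_concentric_phantom(
    tumor_radius = 4e-3,
    shell_thicknesses = c(brain = 8e-3, csf_general = 2e-3, skull = 3e-3),
    spacing = 0.5e-3)
  expect_error(place_probes(ph), "plane 1")
})

test_that("probe_average is a volume-weighted mean", {
  ph <- small_phantom()
  pr <- place_probes(ph)
  const <- array(50, dim = dim(ph$label))
  for (p in pr) {
    expect_equal(probe_average(const, p$cp, ph), 50)
    expect_equal(probe_average(const, p$bp, ph), 50)
  }
  # field = r over the CP annulus: check against an explicit weighted sum
  rfield <- matrix(ph$r, length(ph$r), length(ph$z))
  m <- pr[[2]]$cp
  expect_equal(probe_average(rfield, m, ph),
               sum(rfield[m] * ph$vol[m]) / sum(ph$vol[m]))
  # single-voxel mask returns that voxel's value
  one <- array(FALSE, dim = dim(ph$label))
  one[which(m)[1]] <- TRUE
  expect_equal(probe_average(rfield, one, ph), rfield[which(m)[1]])
  expect_error(probe_average(rfield, array(FALSE, dim(ph$label)), ph),
               "empty")
})

test_that("retraction stages must be spaced by the increment", {
  expect_error(probe_track(stage_z = c(-5e-3, 0, 4e-3)), "increment")
})

test_that("NIfTI label maps round-trip and honor anisotropic spacing", {
  dims <- c(12L, 10L, 8L)
  arr <- array(1L, dim = dims)               # brain everywhere
  arr[5:8, 4:7, 3:6] <- 2L                   # tumor block
  arr[1, , ] <- 3L                           # skull slab
  tmp <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 2, 3)          # mm, anisotropic
  RNifti::writeNifti(img, tmp)
  dict <- list(brain = 1L, tumor = 2L, skull = 3L)
  ph <- load_label_map(tmp, dict)
  expect_equal(ph$mode, "cartesian_3d")
  expect_equal(dim(ph$label), dims)
  expect_equal(sum(ph$label == "tumor"), 4L * 4L * 4L)
  # anisotropic voxel volume honored: 1x2x3 mm = 6e-9 m^3 per voxel
  expect_equal(label_volume(ph, "tumor"), 64 * 6e-9, tolerance = 1e-9)
  tmp2 <- tempfile(fileext = ".nii.gz")
  save_label_map(ph, tmp2, dict)
  ph2 <- load_label_map(tmp2, dict)
  expect_identical(ph2$label, ph$label)
  # unmapped code errors and names the code
  expect_error(load_label_map(tmp, list(brain = 1L, tumor = 2L)), "3")
})
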