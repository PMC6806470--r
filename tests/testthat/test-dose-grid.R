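test_that("trilinear interpolation matches a loop-based oracle", {
  set.seed(42)
  g <- dose_grid(c(-5, -4, -3), c(1, 2, 1.5),
                 array(runif(6 * 5 * 7, 0, 100), dim = c(6, 5, 7)))
  pts <- cbind(runif(50, -5, 0), runif(50, -4, 4), runif(50, -3, 6))
  got <- interp_dose(g, pts)
  want <- apply(pts, 1, function(p) naive_trilinear(g, p))
  expect_equal(got, want, tolerance = 1e-12)
  # exact at grid nodes
  expect_equal(interp_dose(g, matrix(c(-4, -2, 0), 1)), g$values[2, 2, 3])
  # outside the box is an error, not zero-fill
  expect_error(interp_dose(g, matrix(c(50, 0, 0), 1)), "outside")
})

test_that("dose grid validates spacing and nonnegativity", {
  expect_error(dose_grid(c(0, 0, 0), c(1, -1, 1), array(1, c(2, 2, 2))),
               "positive")
  expect_error(dose_grid(c(0, 0, 0), c(1, 1, 1), array(-1, c(2, 2, 2))),
               "nonnegative")
})

test_that("ASCII NRRD round-trips a dose grid", {
  g <- dose_grid(c(-1.5, 0, 2), c(1, 1.25, 2),
                 array(seq(0, 10, length.out = 24), dim = c(2, 3, 4)))
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(g, path)
  g2 <- read_nrrd(path)
  expect_equal(g2$origin_mm, g$origin_mm)
  expect_equal(g2$spacing_mm, g$spacing_mm)
  expect_equal(g2$values, g$values, tolerance = 1e-10)
  expect_error(read_nrrd(withr::local_tempfile(lines = "not a grid")),
               "NRRD")
})

test_that("layer grid is separable with correct on-axis depth profile", {
  sf <- small_field()
  g1 <- build_layer_dose_grid(1, sf$model, sf$layers, field_geometry("-x"),
                              sf$ctv, grid_spacing_mm = 2, pad_mm = 18)
  ax <- protonInterplay:::grid_axes(g1)
  # on the beam axis (CTV centre line) the profile equals the pristine
  # depth-dose evaluated at the water-equivalent depth of each x
  iy <- which.min(abs(ax[[2]])); iz <- which.min(abs(ax[[3]]))
  x_distal <- -(sf$ctv$semi_axes_mm[1] + 5)  # -x beam: distal edge + margin
  depth <- sf$layers$range_gcm2 - (ax[[1]] - x_distal) / 10
  want <- bragg_depth_dose(sf$model, pmax(depth, 0))
  lat0 <- g1$values[1, iy, iz] / want[1]
  expect_equal(g1$values[, iy, iz], want * lat0, tolerance = 1e-9)
  expect_gt(lat0, 0.99)  # centre of the aperture is in the flat region
  # more than 3 penumbra widths outside the aperture the dose vanishes
  g_sharp <- build_layer_dose_grid(1, sf$model, sf$layers,
                                   field_geometry("-x", penumbra_80_20_mm = 3),
                                   sf$ctv, grid_spacing_mm = 2, pad_mm = 18)
  far <- matrix(c(0, max(ax[[2]]), 0), 1)  # 10 mm = 3.3 widths past the edge
  expect_lt(interp_dose(g_sharp, far) / max(g_sharp$values), 1e-4)
  # mirror symmetry in the non-beam axes for the symmetric CTV
  expect_equal(g1$values, g1$values[, rev(seq_along(ax[[2]])), ],
               tolerance = 1e-12)
  expect_equal(g1$values, g1$values[, , rev(seq_along(ax[[3]]))],
               tolerance = 1e-12)
})

test_that("composed beam equals the weighted voxelwise sum of layers", {
  sf <- small_field(normalize = "center")
  comp <- sf$field$composed
  scale <- attr(comp, "norm_scale")
  # independent voxel loop over a thinned index set
  d <- dim(comp$values)
  idx <- expand.grid(i = seq(1, d[1], by = 3), j = seq(1, d[2], by = 3),
                     k = seq(1, d[3], by = 3))
  for (r in seq_len(nrow(idx))) {
    s <- 0
    for (k in seq_along(sf$field$layer_grids))
      s <- s + sf$layers$weights[k] *
        sf$field$layer_grids[[k]]$values[idx$i[r], idx$j[r], idx$k[r]]
    expect_equal(comp$values[idx$i[r], idx$j[r], idx$k[r]], s * scale,
                 tolerance = 1e-12)
  }
  # identity-basis weights return a scaled copy of that layer
  g2 <- compose_beam_dose(sf$field$layer_grids,
                          c(0, 1, rep(0, length(sf$field$layer_grids) - 2)))
  expect_equal(g2$values, sf$field$layer_grids[[2]]$values)
  # normalization contract: dose at the requested point is exactly 100
  g3 <- compose_beam_dose(sf$field$layer_grids, sf$layers$weights,
                          norm_point_mm = c(0, 0, 0))
  expect_equal(interp_dose(g3, matrix(0, 1, 3)), 100, tolerance = 1e-9)
  # mismatched grids are rejected
  bad <- sf$field$layer_grids[[1]]
  bad$origin_mm <- bad$origin_mm + 1
  expect_error(compose_beam_dose(list(sf$field$layer_grids[[1]], bad),
                                 c(0.5, 0.5)), "share")
})

test_that("plan normalization covers the CTV with the prescription isodose", {
  sf <- small_field()  # default ctv_min normalization
  st <- interp_dose(sf$field$composed, sf$ctv$voxels_mm)
  expect_equal(min(st), 100, tolerance = 1e-9)
  expect_true(all(st >= 100 - 1e-9))
})
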