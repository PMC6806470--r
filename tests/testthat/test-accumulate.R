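# delivery accumulation on the small fixture field (4 layers, 2 mm grid)

test_that("zero motion reproduces the static plan for both techniques", {
  sf <- small_field()
  zt <- const_trace(c(0, 0, 0), 40)
  tl_ds <- build_timeline("ds", 1, 2, sf$layers, delay_s = 2)
  tl_us <- build_timeline("us", 1, 2, sf$layers, delay_s = 2, switch_s = 0.5)
  st <- interp_dose(sf$field$composed, sf$ctv$voxels_mm)
  ds <- accumulate_fraction(sf$field, tl_ds, zt)
  us <- accumulate_fraction(sf$field, tl_us, zt)
  expect_equal(ds$dose_pct, st, tolerance = 1e-9)
  # layer-by-layer delivery telescopes to the composed beam
  expect_equal(us$dose_pct, ds$dose_pct, tolerance = 1e-6)
  expect_equal(us$dose_pct, st, tolerance = 1e-9)
})

test_that("constant offset equals the static dose at shifted points", {
  sf <- small_field()
  off <- c(1.5, 2, -1)  # (lr, si, ap)
  tl <- build_timeline("us", 1, 2, sf$layers, delay_s = 2, switch_s = 0.5)
  tr <- const_trace(off, ceiling(attr(tl, "end_s")) + 1)
  fd <- accumulate_fraction(sf$field, tl, tr)
  shifted <- cbind(sf$ctv$voxels_mm[, 1] + off[1],
                   sf$ctv$voxels_mm[, 2] + off[3],
                   sf$ctv$voxels_mm[, 3] + off[2])
  expect_equal(fd$dose_pct, interp_dose(sf$field$composed, shifted),
               tolerance = 1e-9)
})

test_that("vectorized accumulation matches the brute-force oracle", {
  sf <- small_field(voxel_mm = 4)   # ~25 voxel CTV, 30 s timeline
  tl <- build_timeline("us", 1, 2, sf$layers, delay_s = 1.5, switch_s = 0.5)
  tr <- downsample_trace(generate_trace(
    motion_params(drift_rate_mm_per_min = c(3, 2, 2),
                  jitter_sd_mm = c(0.5, 1, 1)),
    ceiling(attr(tl, "end_s")) + 2, 10, seed = 13))
  got <- accumulate_fraction(sf$field, tl, tr)
  want <- naive_accumulate(sf$field, tl, tr)
  expect_equal(got$dose_pct, want, tolerance = 1e-9)
})

test_that("in-plane motion within the aperture margin conserves mean dose", {
  # sharp 3 mm penumbra so the flat region reaches close to the aperture
  # edge; the 2.5 mm SI/AP offset then keeps every CTV voxel in flat dose
  sb <- small_beam()
  ctv <- ctv_geometry(c(8, 7, 7.5), voxel_mm = 3)
  field <- build_field(sb$model, sb$layers,
                       field_geometry("-x", penumbra_80_20_mm = 3), ctv,
                       grid_spacing_mm = 2, pad_mm = 18)
  tl <- build_timeline("us", 1, 2, sb$layers, delay_s = 2, switch_s = 0.5)
  tr <- const_trace(c(0, 2.5, -2.5), ceiling(attr(tl, "end_s")) + 1)
  fd <- accumulate_fraction(field, tl, tr)
  st <- interp_dose(field$composed, ctv$voxels_mm)
  expect_lt(abs(mean(fd$dose_pct) - mean(st)) / mean(st), 0.01)
})

test_that("DS dose is invariant under time reversal of the trace; US is not", {
  sf <- small_field()
  tl_ds <- build_timeline("ds", 1, 2, sf$layers, delay_s = 0)
  tl_us <- build_timeline("us", 1, 2, sf$layers, delay_s = 0, switch_s = 0)
  tr <- downsample_trace(generate_trace(
    motion_params(drift_rate_mm_per_min = c(2, 1, 1),
                  jitter_sd_mm = c(0.3, 0.6, 0.6)), 40, 10, seed = 9))
  # reverse the 30 beam-on seconds actually consumed
  d <- tr$disp_mm; d[1:30, ] <- d[30:1, ]
  trR <- motion_trace(tr$times_s, d, 1)
  a <- accumulate_fraction(sf$field, tl_ds, tr)
  b <- accumulate_fraction(sf$field, tl_ds, trR)
  expect_equal(a$dose_pct, b$dose_pct, tolerance = 1e-12)
  au <- accumulate_fraction(sf$field, tl_us, tr)
  bu <- accumulate_fraction(sf$field, tl_us, trR)
  expect_gt(max(abs(au$dose_pct - bu$dose_pct)), 0.1)
})

test_that("accumulation rejects uncovered or unsuitable traces", {
  sf <- small_field()
  tl <- build_timeline("ds", 1, 2, sf$layers, delay_s = 2)
  expect_error(accumulate_fraction(sf$field, tl, const_trace(c(0, 0, 0), 10)),
               "does not cover")
  tr10hz <- generate_trace(motion_params(jitter_sd_mm = c(1, 1, 1)), 40, 10,
                           seed = 1)
  expect_error(accumulate_fraction(sf$field, tl, tr10hz), "1 Hz")
  # motion beyond the padded grid is an error, not silent zero-fill
  big <- const_trace(c(0, 40, 0), 40)
  expect_error(accumulate_fraction(sf$field, tl, big), "outside")
})

test_that("course dose is the mean of its fraction doses with alternating fields", {
  sb <- small_beam()
  ctv <- ctv_geometry(c(8, 7, 7.5), voxel_mm = 3)
  fields <- list(
    lao = build_field(sb$model, sb$layers, field_geometry("-x"), ctv,
                      grid_spacing_mm = 2, pad_mm = 18),
    rao = build_field(sb$model, sb$layers, field_geometry("+x"), ctv,
                      grid_spacing_mm = 2, pad_mm = 18))
  tl <- build_timeline("ds", 1, 2, sb$layers, delay_s = 2)
  traces <- lapply(1:4, function(f) downsample_trace(generate_trace(
    motion_params(jitter_sd_mm = c(0.5, 1, 1)), 40, 10, seed = 40 + f)))
  cd <- simulate_course(fields, traces, tl, 4)
  expect_equal(cd$fields, c("lao", "rao", "lao", "rao"))
  per_frac <- vapply(cd$fractions, function(fr) fr$dose_pct,
                     numeric(nrow(ctv$voxels_mm)))
  expect_equal(cd$dose_pct, rowMeans(per_frac), tolerance = 1e-12)
  # zero motion: course equals the static plan in percent terms
  zt <- lapply(1:4, function(f) const_trace(c(0, 0, 0), 40))
  cd0 <- simulate_course(fields, zt, tl, 4)
  st_mix <- (interp_dose(fields$lao$composed, ctv$voxels_mm) +
             interp_dose(fields$rao$composed, ctv$voxels_mm)) / 2
  expect_equal(cd0$dose_pct, st_mix, tolerance = 1e-9)
  expect_error(simulate_course(fields, traces[1:2], tl, 4), "traces")
})

test_that("fraction averaging shrinks across-seed dose variance", {
  sf <- small_field(voxel_mm = 4)
  tl <- build_timeline("us", 1, 2, sf$layers, delay_s = 1, switch_s = 0.5)
  n_frac <- 4
  p <- motion_params(drift_rate_mm_per_min = c(2, 1.5, 1.5),
                     jitter_sd_mm = c(0.5, 1, 1))
  single <- c(); course <- c()
  v <- which.max(abs(sf$ctv$voxels_mm[, 1]))  # an edge voxel, motion-sensitive
  for (s in 1:30) {
    doses <- vapply(1:n_frac, function(f) {
      tr <- downsample_trace(generate_trace(p, 40, 10, seed = 1000 * s + f))
      accumulate_fraction(sf$field, tl, tr)$dose_pct[v]
    }, numeric(1))
    single <- c(single, doses[1])
    course <- c(course, mean(doses))
  }
  # i.i.d. fraction motion: course variance ~ single variance / n_fractions,
  # with slack for the sampling error of both variance estimates
  expect_lt(var(course), var(single) / n_frac * 3)
})
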