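test_that("trace generation honours regime semantics and determinism", {
  # all-zero parameters give an identically zero trace
  z <- generate_trace(motion_params(jitter_sd_mm = c(0, 0, 0)), 60, 10,
                      seed = 1)
  expect_true(all(z$disp_mm == 0))
  expect_equal(length(z$times_s), 601L)
  # pure drift: 2 mm/min AP over 300 s ends at exactly 10 mm
  dr <- generate_trace(motion_params(drift_rate_mm_per_min = c(0, 0, 2)),
                       300, 10, seed = 1)
  expect_equal(unname(dr$disp_mm[nrow(dr$disp_mm), "ap"]), 10)
  expect_equal(unname(dr$disp_mm[1, "ap"]), 0)
  # same seed reproduces; different seed differs
  p <- motion_params(jitter_sd_mm = c(0.5, 1, 1),
                     excursion_amplitude_mm = 3, excursion_rate_per_min = 0.5)
  a <- generate_trace(p, 120, 10, seed = 7)
  b <- generate_trace(p, 120, 10, seed = 7)
  c <- generate_trace(p, 120, 10, seed = 8)
  expect_identical(a$disp_mm, b$disp_mm)
  expect_false(identical(a$disp_mm, c$disp_mm))
  expect_error(generate_trace(p, -5, 10), "positive")
})

test_that("transient excursions return to baseline; persistent offsets hold", {
  tr <- generate_trace(motion_params(excursion_amplitude_mm = 5,
                                     excursion_duration_s = 20,
                                     excursion_rate_per_min = 1),
                       300, 10, seed = 3)
  mag <- sqrt(rowSums(tr$disp_mm^2))
  expect_gt(max(mag), 1)            # excursions happened
  expect_lt(min(mag[-1]), 0.5)      # and returned to baseline between events
  pe <- generate_trace(motion_params(persistent_offset_mm = c(0, 2, 3)),
                       300, 10, seed = 4)
  final <- pe$disp_mm[nrow(pe$disp_mm), ]
  expect_equal(unname(final), c(0, 2, 3), tolerance = 0.05)
})

test_that("SI-AP correlation of jitter has the configured sign", {
  for (rho in c(0.7, -0.7)) {
    tr <- generate_trace(motion_params(jitter_sd_mm = c(0.5, 1, 1),
                                       si_ap_correlation = rho),
                         300, 10, seed = 11)
    r <- cor(tr$disp_mm[, "si"], tr$disp_mm[, "ap"])
    expect_equal(sign(r), sign(rho))
    expect_gt(abs(r), 0.3)
  }
})

test_that("down-sampling averages one-second windows", {
  # constant trace stays constant
  ct <- const_trace(c(1, -2, 3), 30)
  expect_true(all(abs(sweep(downsample_trace(ct)$disp_mm, 2,
                            c(1, -2, 3))) < 1e-12))
  # a window holding AP values 0..9 averages to 4.5
  tr <- motion_trace(seq(0, 0.9, by = 0.1), cbind(0, 0, 0:9), 10)
  expect_error(downsample_trace(tr), "shorter than one window")
  tr <- motion_trace(seq(0, 1.9, by = 0.1), cbind(0, 0, c(0:9, rep(0, 10))),
                     10)
  expect_equal(unname(downsample_trace(tr)$disp_mm[1, "ap"]), 4.5)
  # 91 s at 10 Hz gives 91 output samples at 1 Hz
  tr91 <- generate_trace(motion_params(jitter_sd_mm = c(0.3, 0.5, 0.5)),
                         91, 10, seed = 2)
  ds <- downsample_trace(tr91)
  expect_equal(length(ds$times_s), 91L)
  expect_equal(ds$rate_hz, 1)
  # mean preserved exactly when duration is a whole number of windows
  n <- 120
  vals <- matrix(rnorm(3 * n), n, 3)
  # final sample at t = 12 defines a 12 s trace; windows 0..11 hold 10
  # samples each and the boundary sample is excluded
  tr12 <- motion_trace(c(seq(0, 11.9, by = 0.1), 12), rbind(vals, 0), 10)
  expect_equal(colMeans(downsample_trace(tr12)$disp_mm), colMeans(vals),
               ignore_attr = TRUE)
})

test_that("trace CSV round-trips and rejects malformed files", {
  tr <- generate_trace(motion_params(jitter_sd_mm = c(0.5, 1, 1)), 30, 10,
                       seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  tr2 <- read_trace_csv(path)
  expect_equal(tr2$times_s, tr$times_s, tolerance = 1e-9)
  expect_true(max(abs(tr2$disp_mm - tr$disp_mm)) < 1e-6)
  expect_equal(tr2$rate_hz, 10)
  # shuffled rows break monotone time, reported with a line number
  df <- utils::read.csv(path)
  set.seed(1); df <- df[sample(nrow(df)), ]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_trace_csv(path), "non-monotone time at data line")
  # missing column is named
  utils::write.csv(df[, c("time_s", "lr_mm", "si_mm")], path,
                   row.names = FALSE)
  expect_error(read_trace_csv(path), "ap_mm")
})

test_that("cohort bookkeeping, consistency, and component estimators", {
  co <- generate_cohort(3, 4, duration_s = 60, seed = 21)
  expect_length(co$patients, 3)
  expect_length(co$patients[[1]]$traces, 4)
  # per-patient character is drawn once: same regime across fractions,
  # different realizations
  expect_length(co$patients[[1]]$character$regime, 1)
  expect_false(identical(co$patients[[1]]$traces[[1]]$disp_mm,
                         co$patients[[1]]$traces[[2]]$disp_mm))
  # regeneration with the same seed is identical
  co2 <- generate_cohort(3, 4, duration_s = 60, seed = 21)
  expect_identical(co$patients[[2]]$traces[[3]]$disp_mm,
                   co2$patients[[2]]$traces[[3]]$disp_mm)
  expect_error(generate_cohort(0, 4), "at least 1")
  # single-patient cohorts have no systematic component
  expect_error(motion_components(generate_cohort(1, 2, duration_s = 30)),
               "fewer than 2")
})

test_that("motion components match closed forms on constant cohorts", {
  mk <- function(ap) list(traces = list(const_trace(c(0, 0, ap), 50)))
  s <- motion_components(list(mk(1), mk(-1)))
  expect_equal(unname(s$systematic_mm["ap"]), sd(c(1, -1)))  # sqrt(2)
  expect_equal(unname(s$random_mm["ap"]), 0)
  expect_equal(unname(s$systematic_mm["lr"]), 0)
  # all-zero cohort: everything zero
  z <- motion_components(list(mk(0), mk(0)))
  expect_true(all(z$systematic_mm == 0) && all(z$random_mm == 0))
})

test_that("exceedance fractions are non-increasing in threshold", {
  co <- generate_cohort(5, 3, duration_s = 120, seed = 31, motion_scale = 2)
  e <- motion_components(co)$exceedance_fractions
  expect_true(all(e >= 0 & e <= 1))
  expect_true(all(e[, 1] >= e[, 2] & e[, 2] >= e[, 3]))
})
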