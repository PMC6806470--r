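#' Run configuration
#'
#' Bundles every tunable of a cohort simulation with its default. Defaults
#' reproduce the reference study conditions: a shared beam and anatomy for
#' all patients (range 30.1 g/cm^2, modulation 8.4 g/cm^2, 0.6 g/cm^2 layer
#' spacing giving 14 layers), 17 patients with 14 tracked fractions of
#' 2 Gy at 2 Gy/min (or 5 fractions of 7.25 Gy for SBRT), a 25 s pre-beam
#' delay and 0.5 s layer switching.
#'
#' @param n_patients,n_fractions cohort size.
#' @param fraction_dose_gy dose per fraction (Gy).
#' @param dose_rate_gy_per_min dose rate (Gy/min).
#' @param delay_s,switch_s pre-beam delay and layer switch time (s).
#' @param range_gcm2,modulation_gcm2,spacing_gcm2 SOBP field parameters.
#' @param peak_width_gcm2,entrance_ratio pristine peak shape parameters.
#' @param ctv_semi_axes_mm CTV ellipsoid semi-axes (LR, AP, SI) in mm.
#' @param ctv_voxel_mm CTV dose-sampling pitch (mm).
#' @param grid_spacing_mm dose grid voxel size (mm).
#' @param grid_pad_mm dose grid padding beyond the CTV (mm).
#' @param trace_duration_s,trace_rate_hz motion trace length and rate.
#' @param motion_scale cohort motion multiplier (1 = calibrated cohort).
#' @param seed cohort seed.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(n_patients = 17, n_fractions = 14,
                       fraction_dose_gy = 2, dose_rate_gy_per_min = 2,
                       delay_s = 25, switch_s = 0.5,
                       range_gcm2 = 30.1, modulation_gcm2 = 8.4,
                       spacing_gcm2 = 0.6, peak_width_gcm2 = 0.6,
                       entrance_ratio = 0.35,
                       ctv_semi_axes_mm = c(20, 16, 18), ctv_voxel_mm = 2,
                       grid_spacing_mm = 1, grid_pad_mm = 25,
                       trace_duration_s = 300, trace_rate_hz = 10,
                       motion_scale = 1, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' SBRT variant of a configuration
#'
#' @param cfg a [run_config()].
#' @return the configuration with 5 fractions of 7.25 Gy.
#' @export
sbrt_config <- function(cfg = run_config()) {
  cfg$n_fractions <- 5
  cfg$fraction_dose_gy <- 7.25
  cfg
}

# build the shared plan (beam model, weights, both lateral fields) from a
# configuration
build_plan <- function(cfg) {
  model <- bragg_peak(cfg$range_gcm2, cfg$peak_width_gcm2, cfg$entrance_ratio)
  layers <- solve_layer_weights(
    model, build_layer_set(cfg$range_gcm2, cfg$modulation_gcm2,
                           cfg$spacing_gcm2))
  ctv <- ctv_geometry(cfg$ctv_semi_axes_mm, c(0, 0, 0), cfg$ctv_voxel_mm)
  fields <- list(
    lao = build_field(model, layers, field_geometry("-x"), ctv,
                      cfg$grid_spacing_mm, cfg$grid_pad_mm),
    rao = build_field(model, layers, field_geometry("+x"), ctv,
                      cfg$grid_spacing_mm, cfg$grid_pad_mm))
  list(model = model, layers = layers, ctv = ctv, fields = fields)
}

#' Simulate a DS-versus-US cohort
#'
#' The package's main entry point. Builds one shared plan (beam and CTV
#' geometry identical for every patient, isolating the effect of motion),
#' generates the synthetic motion cohort, and delivers every (patient,
#' fraction) trace under both double scattering and uniform scanning with
#' the identical trace driving both techniques (a paired design). Fractions
#' alternate LAO and RAO fields, odd fractions LAO. DVH metrics are
#' extracted per fraction and for each patient's fraction-cumulative course
#' dose.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-generated [generate_cohort()]; by default one
#'   is generated from the configuration.
#' @return an object of class \code{"interplay_cohort"} with elements
#'   \code{records} (per patient x fraction x technique metric table),
#'   \code{course} (per patient x technique course-level metric table),
#'   \code{course_dose} (nested list of \code{course_dose} objects),
#'   \code{plan}, \code{cohort}, \code{config}.
#' @seealso [summary.interplay_cohort()], [compare_techniques()],
#'   [render_report()]
#' @export
simulate_interplay <- function(cfg = run_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  plan <- build_plan(cfg)
  if (is.null(cohort))
    cohort <- generate_cohort(cfg$n_patients, cfg$n_fractions,
                              cfg$trace_duration_s, cfg$trace_rate_hz,
                              cfg$seed, motion_scale = cfg$motion_scale)
  timelines <- list(
    ds = build_timeline("ds", cfg$fraction_dose_gy, cfg$dose_rate_gy_per_min,
                        plan$layers, cfg$delay_s, cfg$switch_s),
    us = build_timeline("us", cfg$fraction_dose_gy, cfg$dose_rate_gy_per_min,
                        plan$layers, cfg$delay_s, cfg$switch_s))

  records <- list(); course <- list(); course_dose <- list()
  for (p in seq_along(cohort$patients)) {
    traces1hz <- lapply(cohort$patients[[p]]$traces[seq_len(cfg$n_fractions)],
                        downsample_trace)
    course_dose[[p]] <- list()
    for (tech in c("ds", "us")) {
      cd <- tryCatch(
        simulate_course(plan$fields, traces1hz, timelines[[tech]],
                        cfg$n_fractions),
        error = function(e) stop(sprintf("patient %d (%s): %s",
                                         p, tech, conditionMessage(e))))
      course_dose[[p]][[tech]] <- cd
      for (f in seq_len(cfg$n_fractions)) {
        m <- dvh_metrics(cd$fractions[[f]])
        records[[length(records) + 1L]] <- data.frame(
          patient = p, fraction = f, technique = tech,
          field = cd$fields[f], t(.metric_vector(m)),
          hot = m$hot, cold = m$cold)
      }
      mc <- dvh_metrics(cd)
      course[[length(course) + 1L]] <- data.frame(
        patient = p, technique = tech, t(.metric_vector(mc)),
        hot = mc$hot, cold = mc$cold)
    }
  }
  structure(list(records = do.call(rbind, records),
                 course = do.call(rbind, course),
                 course_dose = course_dose,
                 plan = plan, cohort = cohort, config = cfg),
            class = "interplay_cohort")
}

#' @export
print.interplay_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DS vs US interplay simulation: %d patients x %d fractions, %.2f Gy/fraction\n",
              cfg$n_patients, cfg$n_fractions, cfg$fraction_dose_gy))
  cat(sprintf("  %d single-fraction dose records per technique\n",
              sum(x$records$technique == "ds")))
  cat("  use summary() for the cohort metric table\n")
  invisible(x)
}

#' Paired DS-versus-US significance test
#'
#' Two-sided Student t-test on per-record metric differences. The design is
#' intrinsically paired (the same trace drives both techniques), so the
#' paired test is the default; an unpaired (Welch) variant is available.
#' When every paired difference is zero the test statistic is undefined and
#' p = 1 is returned by convention.
#'
#' @param ds,us numeric metric vectors, equal length when paired.
#' @param paired logical, default \code{TRUE}.
#' @return p-value in [0, 1].
#' @export
compare_techniques <- function(ds, us, paired = TRUE) {
  if (paired && length(ds) != length(us))
    stop("paired comparison requires equal-length samples")
  if (length(ds) < 2 || length(us) < 2)
    stop("need at least 2 records per technique")
  if (paired) {
    d <- ds - us
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        message("zero-variance zero-mean differences: p = 1 by convention")
        return(1)
      }
      return(0)
    }
    stats::t.test(ds, us, paired = TRUE)$p.value
  } else {
    if (stats::sd(ds) == 0 && stats::sd(us) == 0 && mean(ds) == mean(us))
      return(1)
    stats::t.test(ds, us)$p.value
  }
}

#' Cohort summary table
#'
#' Mean, standard deviation, maximum and minimum of each DVH metric over
#' records, per technique, with the paired DS-versus-US p-value per metric
#' -- at the single-fraction level (one record per patient x fraction) or
#' the course level (one record per patient).
#'
#' @param object an [simulate_interplay()] result.
#' @param level \code{"single_fraction"} or \code{"course"}.
#' @param paired passed to [compare_techniques()].
#' @param ... unused.
#' @return an object of class \code{"interplay_summary"}: data frame with
#'   one row per (statistic, technique) and one column per metric, plus a
#'   \code{p_value} row pair attribute.
#' @export
summary.interplay_cohort <- function(object, level = c("single_fraction",
                                                       "course"),
                                     paired = TRUE, ...) {
  level <- match.arg(level)
  tab <- if (level == "single_fraction") object$records else object$course
  metrics <- c("V100", "V95", "V110", "D100", "D95", "D5")
  ds <- tab[tab$technique == "ds", , drop = FALSE]
  us <- tab[tab$technique == "us", , drop = FALSE]
  rows <- list()
  for (stat in c("Mean", "STD", "Max", "Min")) {
    fn <- switch(stat, Mean = mean, STD = stats::sd, Max = max, Min = min)
    for (tech in c("DS", "US")) {
      src <- if (tech == "DS") ds else us
      rows[[paste(stat, tech)]] <- vapply(metrics, function(m) fn(src[[m]]),
                                          numeric(1))
    }
  }
  p <- vapply(metrics, function(m)
    suppressMessages(compare_techniques(ds[[m]], us[[m]], paired = paired)),
    numeric(1))
  out <- do.call(rbind, rows)
  structure(list(table = out, p_value = p, level = level,
                 n_records = nrow(ds),
                 fraction_dose_gy = object$config$fraction_dose_gy),
            class = "interplay_summary")
}

#' @export
print.interplay_summary <- function(x, ...) {
  cat(sprintf("CTV DVH points, %s level (%d records per technique, %.2f Gy/fraction):\n",
              gsub("_", " ", x$level), x$n_records, x$fraction_dose_gy))
  print(round(x$table, 1))
  cat("P value:\n")
  print(signif(x$p_value, 3))
  invisible(x)
}

#' Tidy per-record metric table
#'
#' @param x an [simulate_interplay()] result.
#' @param level \code{"single_fraction"} or \code{"course"}.
#' @return long-format data frame (patient, fraction, technique, field,
#'   metric, value).
#' @export
metric_table <- function(x, level = c("single_fraction", "course")) {
  level <- match.arg(level)
  tab <- if (level == "single_fraction") x$records else x$course
  metrics <- c("V100", "V95", "V110", "D100", "D95", "D5")
  long <- do.call(rbind, lapply(metrics, function(m) {
    d <- tab[, setdiff(names(tab), c(metrics, "hot", "cold")), drop = FALSE]
    d$metric <- m
    d$value <- tab[[m]]
    d
  }))
  rownames(long) <- NULL
  long
}

#' Plot cohort DVH overlay
#'
#' Overlays the static (zero-motion) planned DVH with the per-patient course
#' DVHs of both techniques.
#'
#' @param x an [simulate_interplay()] result.
#' @param patients patient indices to draw (default all).
#' @param ... passed to the underlying plot.
#' @export
plot.interplay_cohort <- function(x, patients = NULL, ...) {
  if (is.null(patients)) patients <- seq_along(x$course_dose)
  static <- interp_dose(x$plan$fields$lao$composed, x$plan$ctv$voxels_mm)
  plot(compute_dvh(static), col = "black", lwd = 2, ...)
  for (p in patients) {
    plot(compute_dvh(x$course_dose[[p]]$ds), add = TRUE, col = "steelblue")
    plot(compute_dvh(x$course_dose[[p]]$us), add = TRUE, col = "firebrick",
         lty = 2)
  }
  graphics::legend("bottomleft", c("static plan", "DS course", "US course"),
                   col = c("black", "steelblue", "firebrick"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Write report files for a simulation
#'
#' Emits deterministic CSV tables (summary tables at both record levels,
#' long-format per-record metrics) and, optionally, DVH overlay and planar
#' dose-difference figures as PDF.
#'
#' @param x an [simulate_interplay()] result.
#' @param dir output directory (created if needed).
#' @param plots logical; also render PDF figures.
#' @return invisibly, the vector of files written.
#' @export
render_report <- function(x, dir, plots = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (lv in c("single_fraction", "course")) {
    s <- summary(x, lv)
    tab <- cbind(statistic = rownames(s$table), as.data.frame(s$table))
    tab <- rbind(tab, c(statistic = "P value", as.list(signif(s$p_value, 4))))
    f <- file.path(dir, paste0("summary_", lv, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, paste0("metrics_", lv, ".csv"))
    utils::write.csv(metric_table(x, lv), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(seed = x$config$seed,
                   n_patients = x$config$n_patients,
                   n_fractions = x$config$n_fractions,
                   fraction_dose_gy = x$config$fraction_dose_gy,
                   n_layers = x$plan$layers$n_layers)
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  if (plots) {
    f <- file.path(dir, "dvh_overlay.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    plot(x)
    grDevices::dev.off()
    files <- c(files, f)
    f <- file.path(dir, "planar_dose_difference.pdf")
    grDevices::pdf(f, width = 9, height = 4)
    .plot_planar_difference(x)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

# transverse-plane (x-y at the isocenter z) dose difference US - DS of the
# worst single fraction, sampled on the dose grid plane
.plot_planar_difference <- function(x) {
  worst <- x$records[x$records$technique == "us", ]
  worst <- worst[which.min(worst$D95), ]
  p <- worst$patient; f <- worst$fraction
  g <- x$plan$fields$lao$composed
  ax <- grid_axes(g)
  kz <- which.min(abs(ax[[3]] - x$plan$ctv$center_mm[3]))
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (tech in c("ds", "us")) {
    # re-deliver the worst fraction on the full plane
    tl <- build_timeline(tech, x$config$fraction_dose_gy,
                         x$config$dose_rate_gy_per_min, x$plan$layers,
                         x$config$delay_s, x$config$switch_s)
    tr <- downsample_trace(x$cohort$patients[[p]]$traces[[f]])
    plane_ctv <- x$plan$ctv
    pad <- 10
    keep_x <- abs(ax[[1]]) <= max(abs(plane_ctv$voxels_mm[, 1])) + pad
    keep_y <- abs(ax[[2]]) <= max(abs(plane_ctv$voxels_mm[, 2])) + pad
    pts <- as.matrix(expand.grid(ax[[1]][keep_x], ax[[2]][keep_y],
                                 ax[[3]][kz]))
    plane_ctv$voxels_mm <- pts
    fd <- accumulate_fraction(x$plan$fields[[worst$field]], tl, tr, plane_ctv)
    img <- matrix(fd$dose_pct, sum(keep_x), sum(keep_y))
    graphics::image(ax[[1]][keep_x], ax[[2]][keep_y], img,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "LR (mm)", ylab = "AP (mm)",
                    main = sprintf("%s, patient %d fraction %d",
                                   toupper(tech), p, f))
  }
  graphics::par(mfrow = c(1, 1))
}
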