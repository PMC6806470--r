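#' Accumulate one fraction of dose on a moving CTV
#'
#' Implements per-second 4D dose accumulation: for every whole second of the
#' delivery timeline the active dose source (full SOBP for DS, the current
#' energy layer for US) is rescaled to the dose delivered in that second and
#' sampled, by trilinear interpolation, at the CTV voxel positions displaced
#' by the motion-trace value for that second. Seconds that straddle segment
#' boundaries apportion dose by sub-second overlap; delay and layer-switch
#' seconds contribute nothing (the trace still advances, i.e. no
#' re-alignment at beam-on). The accumulated per-voxel sum over all seconds
#' is the fraction dose.
#'
#' @param field a [build_field()] object.
#' @param timeline a [build_timeline()] object.
#' @param trace a 1 Hz [motion_trace()] (see [downsample_trace()]) covering
#'   the timeline; sample k is the displacement held during second
#'   [k, k+1).
#' @param ctv optional [ctv_geometry()]; defaults to the field's CTV.
#' @return an object of class \code{"fraction_dose"}: per-voxel dose in
#'   percent of the fraction prescription, plus the technique label.
#' @export
accumulate_fraction <- function(field, timeline, trace, ctv = NULL) {
  stopifnot(inherits(field, "beam_field"),
            inherits(timeline, "delivery_timeline"),
            inherits(trace, "motion_trace"))
  if (is.null(ctv)) ctv <- field$ctv
  if (abs(trace$rate_hz - 1) > 1e-9)
    stop("trace must be down-sampled to 1 Hz before accumulation")
  end_s <- attr(timeline, "end_s")
  n_sec <- ceiling(end_s - 1e-9)
  if (max(trace$times_s) < n_sec - 1)
    stop(sprintf("trace (%.0f s) does not cover the timeline (%.1f s)",
                 max(trace$times_s), end_s))

  # per-second dose apportionment: for each (second, segment) overlap the
  # segment contributes dose_frac * overlap / duration of the prescription
  live <- timeline[timeline$dose_frac > 0 &
                     timeline$end_s > timeline$start_s, , drop = FALSE]
  vox <- ctv$voxels_mm
  dose <- numeric(nrow(vox))
  for (t in seq_len(n_sec) - 1L) {
    d <- trace$disp_mm[match(t, trace$times_s), ]
    if (any(is.na(d))) stop(sprintf("trace has no sample at t = %d s", t))
    ov <- pmin(live$end_s, t + 1) - pmax(live$start_s, t)
    act <- which(ov > 1e-12)
    if (length(act) == 0) next
    # displacement in (lr, si, ap); grid axes are (x=LR, y=AP, z=SI)
    pts <- cbind(vox[, 1] + d[1], vox[, 2] + d[3], vox[, 3] + d[2])
    for (a in act) {
      share <- live$dose_frac[a] * ov[a] / (live$end_s[a] - live$start_s[a])
      if (live$source[a] == "full_beam") {
        dose <- dose + share * interp_dose(field$composed, pts)
      } else {
        k <- live$layer[a]
        # layer grids are unweighted; weight and plan normalization are
        # folded into layer_scale, and share is the fraction of the layer's
        # own dose (dose_frac = weight), so divide the weight back out
        dose <- dose + share / field$layers$weights[k] *
          field$layer_scale[k] * interp_dose(field$layer_grids[[k]], pts)
      }
    }
  }
  structure(list(dose_pct = dose, technique = attr(timeline, "technique"),
                 n_voxels = nrow(vox)),
            class = "fraction_dose")
}

#' @export
print.fraction_dose <- function(x, ...) {
  cat(sprintf("Fraction dose (%s): %d CTV voxels, mean %.1f%%, range %.1f-%.1f%% of prescription\n",
              toupper(x$technique), x$n_voxels, mean(x$dose_pct),
              min(x$dose_pct), max(x$dose_pct)))
  invisible(x)
}

#' Simulate a multi-fraction treatment course
#'
#' Delivers \code{n_fractions} fractions, one motion trace and one lateral
#' field each, alternating LAO and RAO fields (odd fractions LAO by
#' default). Each fraction delivers the full fraction prescription through
#' its single field. The course dose per voxel is the mean of the
#' per-fraction percent doses (equal fraction weights), i.e. percent of the
#' total prescription.
#'
#' @param fields named list with elements \code{lao} and \code{rao}, each a
#'   [build_field()].
#' @param traces list of 1 Hz [motion_trace()] objects, one per fraction
#'   (at least \code{n_fractions}).
#' @param timeline a [build_timeline()] shared by all fractions.
#' @param n_fractions number of fractions.
#' @param first_field field of fraction 1, \code{"lao"} or \code{"rao"}.
#' @return an object of class \code{"course_dose"}: \code{dose_pct}
#'   (per-voxel percent of total prescription), \code{fractions} (list of
#'   [accumulate_fraction()] results) and \code{fields} (per-fraction field
#'   labels).
#' @export
simulate_course <- function(fields, traces, timeline, n_fractions,
                            first_field = c("lao", "rao")) {
  first_field <- match.arg(first_field)
  stopifnot(all(c("lao", "rao") %in% names(fields)))
  if (length(traces) < n_fractions)
    stop(sprintf("%d traces supplied for %d fractions",
                 length(traces), n_fractions))
  order2 <- if (first_field == "lao") c("lao", "rao") else c("rao", "lao")
  labels <- order2[(seq_len(n_fractions) - 1L) %% 2L + 1L]
  fracs <- vector("list", n_fractions)
  for (f in seq_len(n_fractions))
    fracs[[f]] <- accumulate_fraction(fields[[labels[f]]], timeline,
                                      traces[[f]])
  dose <- rowMeans(vapply(fracs, function(fr) fr$dose_pct,
                          numeric(fracs[[1]]$n_voxels)))
  structure(list(dose_pct = dose, fractions = fracs, fields = labels,
                 n_fractions = n_fractions,
                 technique = attr(timeline, "technique")),
            class = "course_dose")
}

#' @export
print.course_dose <- function(x, ...) {
  cat(sprintf("Course dose (%s, %d fractions %s...): mean %.1f%%, range %.1f-%.1f%% of total prescription\n",
              toupper(x$technique), x$n_fractions,
              paste(utils::head(toupper(x$fields), 4), collapse = "/"),
              mean(x$dose_pct), min(x$dose_pct), max(x$dose_pct)))
  invisible(x)
}
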