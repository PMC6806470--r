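#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a set of equal-volume CTV dose samples:
#' the percent of the CTV volume receiving at least each dose level. Ties at
#' a level count as receiving it (closed inequality).
#'
#' @param dose_pct numeric vector of per-voxel doses, percent of
#'   prescription, or a \code{fraction_dose} / \code{course_dose} object.
#' @param levels_pct increasing dose level grid; the default 0 to 130\% in
#'   0.1\% steps resolves one-decimal DVH metrics.
#' @return an object of class \code{"dvh_curve"}: data frame with columns
#'   \code{dose_pct} and \code{volume_pct} (non-increasing, 100 at level 0).
#' @export
compute_dvh <- function(dose_pct, levels_pct = seq(0, 130, by = 0.1)) {
  dose_pct <- .as_dose_vector(dose_pct)
  if (any(diff(levels_pct) <= 0)) stop("'levels_pct' must be increasing")
  n <- length(dose_pct)
  # volume(d) = 100 * #(dose >= d) / n via one sort; the 1e-9 guard keeps the
  # closed inequality closed under floating-point accumulation noise
  s <- sort(dose_pct)
  vol <- 100 * (n - findInterval(levels_pct - 1e-9, s, left.open = TRUE)) / n
  structure(data.frame(dose_pct = levels_pct, volume_pct = vol),
            class = c("dvh_curve", "data.frame"))
}

.as_dose_vector <- function(dose) {
  if (inherits(dose, "fraction_dose") || inherits(dose, "course_dose"))
    dose <- dose$dose_pct
  if (length(dose) == 0) stop("empty dose vector")
  as.numeric(dose)
}

#' @export
plot.dvh_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (!add)
    graphics::plot(x$dose_pct, x$volume_pct, type = "l", col = col, lty = lty,
                   xlab = "Dose (% of prescription)", ylab = "Volume (%)",
                   ylim = c(0, 100), ...)
  else
    graphics::lines(x$dose_pct, x$volume_pct, col = col, lty = lty, ...)
  invisible(x)
}

#' DVH metric panel
#'
#' Extracts the standard CTV coverage panel: V100, V95, V110 (percent of
#' volume at or above 100\%, 95\%, 110\% of prescription) and D100, D95, D5
#' (the dose received by at least 100\%, 95\%, 5\% of the volume). D-metrics
#' are exact order statistics on the voxel samples (the dose of the
#' ceiling(n*y/100)-th voxel in decreasing order), not read off a binned
#' curve. Flags: \code{hot} when V110 > 2 (overdose), \code{cold} when
#' D95 < 95 (underdose).
#'
#' @inheritParams compute_dvh
#' @param v_levels_pct dose levels (percent) for the V-metrics.
#' @param d_levels_pct volume levels (percent) for the D-metrics.
#' @return an object of class \code{"dvh_metrics"}: named list with
#'   \code{V100, V95, V110, D100, D95, D5} and logical \code{hot},
#'   \code{cold}.
#' @export
dvh_metrics <- function(dose_pct, v_levels_pct = c(100, 95, 110),
                        d_levels_pct = c(100, 95, 5)) {
  dose <- .as_dose_vector(dose_pct)
  if (any(d_levels_pct <= 0 | d_levels_pct > 100))
    stop("D-metric volume levels must be in (0, 100]")
  n <- length(dose)
  sdec <- sort(dose, decreasing = TRUE)
  # ties at the threshold count as receiving it; the 1e-9 guard keeps exact
  # ties closed under floating-point accumulation noise
  v <- vapply(v_levels_pct, function(x) 100 * sum(dose >= x - 1e-9) / n,
              numeric(1))
  d <- vapply(d_levels_pct, function(y) sdec[ceiling(n * y / 100)], numeric(1))
  out <- list(V100 = v[1], V95 = v[2], V110 = v[3],
              D100 = d[1], D95 = d[2], D5 = d[3])
  out$hot <- out$V110 > 2
  out$cold <- out$D95 < 95
  class(out) <- "dvh_metrics"
  out
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("V100 %.1f  V95 %.1f  V110 %.1f  D100 %.1f  D95 %.1f  D5 %.1f  [%s%s]\n",
              x$V100, x$V95, x$V110, x$D100, x$D95, x$D5,
              if (x$hot) "hot " else "", if (x$cold) "cold" else ""))
  invisible(x)
}

# metric panel as a plain named vector (internal convenience)
.metric_vector <- function(m) {
  c(V100 = m$V100, V95 = m$V95, V110 = m$V110,
    D100 = m$D100, D95 = m$D95, D5 = m$D5)
}
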