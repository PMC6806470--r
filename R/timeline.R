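#' Range modulator revolution period
#'
#' In double-scattering delivery the range modulator wheel rotates
#' continuously, sweeping all energies once per revolution, so the full SOBP
#' exists quasi-instantaneously on the timescale of organ motion.
#'
#' @param rpm wheel speed in revolutions per minute (default 600).
#' @return revolution period in seconds (0.1 s at 600 RPM).
#' @export
modulator_period_s <- function(rpm = 600) {
  if (rpm <= 0) stop("'rpm' must be positive")
  60 / rpm
}

#' Build a delivery timeline
#'
#' Schedules one treatment fraction. Both techniques start with a pre-beam
#' delay (patient alignment to beam-on). Double scattering (DS) then delivers
#' the full SOBP continuously for the beam-on time
#' \code{fraction_dose_gy / dose_rate_gy_per_min * 60} seconds. Uniform
#' scanning (US) delivers the energy layers sequentially from the most
#' distal to the most proximal; each layer's beam-on time is proportional to
#' its weight (constant beam current at fixed dose rate), and consecutive
#' layers are separated by a fixed beam-off switching gap. The US span from
#' beam start to the end of the last layer is therefore
#' beam-on + (n_layers - 1) * switch: 224 s for a 7.25 Gy fraction at
#' 2 Gy/min with 14 layers and 0.5 s switching.
#'
#' @param technique \code{"ds"} or \code{"us"}.
#' @param fraction_dose_gy prescription dose of the fraction (Gy).
#' @param dose_rate_gy_per_min dose rate (Gy/min), default 2.
#' @param layers a solved [build_layer_set()]; required for US.
#' @param delay_s pre-beam delay (s), default 25.
#' @param switch_s inter-layer switching time (s), default 0.5.
#' @return an object of class \code{"delivery_timeline"}: a data frame of
#'   contiguous segments with columns \code{start_s}, \code{end_s},
#'   \code{source} (\code{"beam_off"}, \code{"full_beam"} or
#'   \code{"layer"}), \code{layer} (index or \code{NA}) and
#'   \code{dose_frac} (fraction of the prescription delivered in the
#'   segment). Attributes: \code{technique}, \code{beam_on_s},
#'   \code{span_s} (beam start to last beam-on end), \code{end_s}.
#' @export
build_timeline <- function(technique = c("ds", "us"), fraction_dose_gy = 2,
                           dose_rate_gy_per_min = 2, layers = NULL,
                           delay_s = 25, switch_s = 0.5) {
  technique <- match.arg(technique)
  if (dose_rate_gy_per_min <= 0) stop("'dose_rate_gy_per_min' must be positive")
  if (fraction_dose_gy <= 0) stop("'fraction_dose_gy' must be positive")
  if (delay_s < 0 || switch_s < 0) stop("times must be nonnegative")
  beam_on <- fraction_dose_gy / dose_rate_gy_per_min * 60

  seg <- data.frame(start_s = numeric(), end_s = numeric(),
                    source = character(), layer = integer(),
                    dose_frac = numeric())
  if (delay_s > 0)
    seg[1, ] <- list(0, delay_s, "beam_off", NA_integer_, 0)

  if (technique == "ds") {
    seg[nrow(seg) + 1, ] <- list(delay_s, delay_s + beam_on, "full_beam",
                                 NA_integer_, 1)
  } else {
    if (is.null(layers) || is.null(layers$weights))
      stop("US timeline requires a layer set with solved weights")
    w <- layers$weights
    t0 <- delay_s
    for (k in seq_along(w)) {
      dur <- w[k] * beam_on
      if (dur == 0)
        message(sprintf("layer %d has zero weight: zero-duration segment", k))
      seg[nrow(seg) + 1, ] <- list(t0, t0 + dur, "layer", k, w[k])
      t0 <- t0 + dur
      if (k < length(w) && switch_s > 0) {
        seg[nrow(seg) + 1, ] <- list(t0, t0 + switch_s, "beam_off",
                                     NA_integer_, 0)
        t0 <- t0 + switch_s
      }
    }
  }
  stopifnot(isTRUE(all.equal(sum(seg$dose_frac), 1)))
  structure(seg, class = c("delivery_timeline", "data.frame"),
            technique = technique, beam_on_s = beam_on,
            delay_s = delay_s, switch_s = switch_s,
            fraction_dose_gy = fraction_dose_gy,
            span_s = max(seg$end_s[seg$dose_frac > 0]) - delay_s,
            end_s = max(seg$end_s))
}

#' @export
print.delivery_timeline <- function(x, ...) {
  cat(sprintf("%s delivery timeline: %.2f Gy, beam-on %.1f s, delay %.1f s, span %.1f s, total %.1f s\n",
              toupper(attr(x, "technique")), attr(x, "fraction_dose_gy"),
              attr(x, "beam_on_s"), attr(x, "delay_s"), attr(x, "span_s"),
              attr(x, "end_s")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
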