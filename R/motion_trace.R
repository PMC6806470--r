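#' Intrafraction motion trace
#'
#' A timestamped series of rigid 3D target displacements from the setup
#' position, in (LR, SI, AP) order, as recorded by an electromagnetic
#' transponder tracking system (nominally 10 Hz).
#'
#' @param times_s strictly increasing timestamps (s), starting at 0.
#' @param disp_mm n x 3 matrix of displacements (mm), columns
#'   \code{lr, si, ap}.
#' @param rate_hz nominal sampling rate (Hz).
#' @return an object of class \code{"motion_trace"}.
#' @export
motion_trace <- function(times_s, disp_mm, rate_hz) {
  disp_mm <- matrix(disp_mm, ncol = 3L,
                    dimnames = list(NULL, c("lr", "si", "ap")))
  if (length(times_s) != nrow(disp_mm))
    stop("'times_s' and 'disp_mm' lengths differ")
  if (any(diff(times_s) <= 0)) stop("'times_s' must be strictly increasing")
  if (!all(is.finite(disp_mm))) stop("displacements must be finite")
  structure(list(times_s = as.numeric(times_s), disp_mm = disp_mm,
                 rate_hz = rate_hz),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace: %d samples at %.1f Hz over %.1f s\n",
              length(x$times_s), x$rate_hz, max(x$times_s)))
  mag <- sqrt(rowSums(x$disp_mm^2))
  cat(sprintf("  3D displacement: mean %.2f mm, max %.2f mm\n",
              mean(mag), max(mag)))
  invisible(x)
}

#' Motion model parameters
#'
#' Parameters of the synthetic intrafraction prostate motion model. The model
#' superposes, per axis: a linear slow drift; transient excursions
#' (raised-cosine pulses that return to baseline); a persistent offset with a
#' smooth sigmoid onset at a random time, sustained to the trace end; and
#' band-limited jitter (an Ornstein-Uhlenbeck process). Superior-inferior and
#' anterior-posterior jitter innovations are correlated at
#' \code{si_ap_correlation}, reflecting the coupled SI/AP motion of the
#' prostate on the pelvic floor.
#'
#' @param regime label for the dominant character, one of
#'   \code{"stable"}, \code{"drift"}, \code{"transient"}, \code{"persistent"},
#'   \code{"mixed"} (metadata; numeric fields drive the simulation).
#' @param drift_rate_mm_per_min 3-vector (LR, SI, AP) of drift rates.
#' @param excursion_amplitude_mm peak 3D amplitude of transient excursions.
#' @param excursion_duration_s duration of one excursion pulse.
#' @param excursion_rate_per_min expected excursions per minute.
#' @param persistent_offset_mm 3-vector persistent offset reached after onset.
#' @param jitter_sd_mm 3-vector stationary SD of the jitter process.
#' @param jitter_tau_s jitter correlation time (s).
#' @param si_ap_correlation correlation of SI and AP jitter in [-1, 1].
#' @return an object of class \code{"motion_params"}.
#' @export
motion_params <- function(regime = "mixed",
                          drift_rate_mm_per_min = c(0, 0, 0),
                          excursion_amplitude_mm = 0,
                          excursion_duration_s = 20,
                          excursion_rate_per_min = 0,
                          persistent_offset_mm = c(0, 0, 0),
                          jitter_sd_mm = c(0, 0, 0),
                          jitter_tau_s = 10,
                          si_ap_correlation = 0.6) {
  regime <- match.arg(regime,
                      c("stable", "drift", "transient", "persistent", "mixed"))
  if (excursion_amplitude_mm < 0 || excursion_duration_s < 0 ||
      excursion_rate_per_min < 0 || any(jitter_sd_mm < 0) || jitter_tau_s <= 0)
    stop("amplitudes, durations, rates and jitter SDs must be nonnegative")
  if (abs(si_ap_correlation) > 1)
    stop("'si_ap_correlation' must be in [-1, 1]")
  structure(list(regime = regime,
                 drift_rate_mm_per_min = drift_rate_mm_per_min,
                 excursion_amplitude_mm = excursion_amplitude_mm,
                 excursion_duration_s = excursion_duration_s,
                 excursion_rate_per_min = excursion_rate_per_min,
                 persistent_offset_mm = persistent_offset_mm,
                 jitter_sd_mm = jitter_sd_mm,
                 jitter_tau_s = jitter_tau_s,
                 si_ap_correlation = si_ap_correlation),
            class = "motion_params")
}

#' Generate a synthetic motion trace
#'
#' Simulates one intrafraction displacement trace from a [motion_params()]
#' model. Reproducible: the same seed yields the identical trace. Samples run
#' from t = 0 to t = \code{duration_s} inclusive, so a pure drift of
#' r mm/min reaches exactly r * duration / 60 mm at the final sample.
#'
#' @param params a [motion_params()].
#' @param duration_s trace length (s); tracked sessions are typically
#'   4 to 10 minutes.
#' @param rate_hz sampling rate (Hz), default 10.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return a [motion_trace()].
#' @export
generate_trace <- function(params, duration_s = 300, rate_hz = 10,
                           seed = NULL) {
  stopifnot(inherits(params, "motion_params"))
  if (duration_s <= 0 || rate_hz <= 0)
    stop("'duration_s' and 'rate_hz' must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dt <- 1 / rate_hz
  t <- seq(0, duration_s, by = dt)
  n <- length(t)
  disp <- matrix(0, n, 3)

  # slow linear drift
  for (i in 1:3)
    disp[, i] <- disp[, i] + params$drift_rate_mm_per_min[i] * t / 60

  # transient excursions: raised-cosine pulses with random onset and a random
  # 3D direction whose SI and AP components share the jitter correlation
  n_ex <- stats::rpois(1, params$excursion_rate_per_min * duration_s / 60)
  if (n_ex > 0 && params$excursion_amplitude_mm > 0 &&
      params$excursion_duration_s > 0) {
    for (e in seq_len(n_ex)) {
      t0 <- stats::runif(1, 0, max(duration_s - params$excursion_duration_s, 0))
      dir <- .correlated_direction(params$si_ap_correlation)
      s <- (t - t0) / params$excursion_duration_s
      pulse <- ifelse(s >= 0 & s <= 1, 0.5 * (1 - cos(2 * pi * s)), 0)
      disp <- disp + params$excursion_amplitude_mm * outer(pulse, dir)
    }
  }

  # persistent offset: sigmoid onset at a uniform random time, sustained
  if (any(params$persistent_offset_mm != 0)) {
    t0 <- stats::runif(1, 0, 0.6 * duration_s)
    onset <- 1 / (1 + exp(-(t - t0) / 5))
    disp <- disp + outer(onset, params$persistent_offset_mm)
  }

  # band-limited jitter: stationary OU processes; SI and AP innovations
  # correlated at si_ap_correlation, LR independent
  if (any(params$jitter_sd_mm > 0)) {
    a <- exp(-dt / params$jitter_tau_s)
    innov_sd <- sqrt(1 - a^2)
    z <- matrix(stats::rnorm(n * 3), n, 3)
    rho <- params$si_ap_correlation
    z[, 3] <- rho * z[, 2] + sqrt(1 - rho^2) * z[, 3]
    for (i in 1:3) {
      x <- numeric(n)
      x[1] <- z[1, i]                      # stationary start (unit SD)
      x[-1] <- innov_sd * z[-1, i]
      x <- stats::filter(x, a, method = "recursive")
      disp[, i] <- disp[, i] + params$jitter_sd_mm[i] * as.numeric(x)
    }
  }
  motion_trace(t, disp, rate_hz)
}

# unit direction vector whose SI and AP components are positively coupled at
# correlation rho
.correlated_direction <- function(rho) {
  z <- stats::rnorm(3)
  z[3] <- rho * z[2] + sqrt(1 - rho^2) * z[3]
  z / sqrt(sum(z^2))
}

#' Down-sample a trace to one sample per second
#'
#' Each output sample is the arithmetic mean of the input samples falling in
#' the window [k, k+1) seconds, k = 0, 1, ...; the output has
#' \code{floor(duration)} samples. Averaging (rather than decimation)
#' suppresses jitter without biasing the window mean.
#'
#' @param trace a [motion_trace()].
#' @param window_s window length (s), default 1.
#' @return a [motion_trace()] at 1/\code{window_s} Hz; output timestamps are
#'   the window start times.
#' @export
downsample_trace <- function(trace, window_s = 1) {
  stopifnot(inherits(trace, "motion_trace"))
  if (length(trace$times_s) == 0) stop("empty trace")
  if (trace$rate_hz < 1 / window_s)
    stop("trace rate below one sample per window")
  n_win <- floor(max(trace$times_s) / window_s)
  if (n_win < 1) stop("trace shorter than one window")
  win <- floor(trace$times_s / window_s)
  keep <- win < n_win
  idx <- win[keep] + 1L
  out <- matrix(0, n_win, 3)
  for (i in 1:3)
    out[, i] <- tapply(trace$disp_mm[keep, i], idx, mean)
  motion_trace((seq_len(n_win) - 1L) * window_s, out, 1 / window_s)
}

#' Read / write motion trace CSV
#'
#' The on-disk format is a headered CSV with columns \code{time_s, lr_mm,
#' si_mm, ap_mm}. Round-trip is exact to 1e-6 mm.
#'
#' @param path CSV file path.
#' @param trace a [motion_trace()].
#' @param rate_hz nominal rate recorded on read (inferred from the median
#'   time step when omitted).
#' @return \code{read_trace_csv} returns a [motion_trace()];
#'   \code{write_trace_csv} returns \code{path} invisibly.
#' @export
read_trace_csv <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "lr_mm", "si_mm", "ap_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-monotone time at data line %d of %s", bad[1] + 1L, path))
  if (is.null(rate_hz))
    rate_hz <- 1 / stats::median(diff(df$time_s))
  motion_trace(df$time_s, as.matrix(df[, c("lr_mm", "si_mm", "ap_mm")]),
               rate_hz)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  df <- data.frame(time_s = trace$times_s,
                   lr_mm = trace$disp_mm[, 1],
                   si_mm = trace$disp_mm[, 2],
                   ap_mm = trace$disp_mm[, 3])
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
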