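#' Cohort motion calibration targets
#'
#' Default calibration of the synthetic cohort: systematic components
#' (SD across patients of the patient-mean displacement) of
#' (0.3, 0.5, 0.6) mm and random components (RMS of patient-specific
#' displacement SDs) of (0.7, 1.4, 1.9) mm in (LR, SI, AP), matching
#' transponder-tracked prostate cohorts: LR motion is smallest, AP largest.
#'
#' @return list with numeric 3-vectors \code{systematic_mm} and
#'   \code{random_mm} in (LR, SI, AP) order.
#' @export
cohort_motion_targets <- function() {
  list(systematic_mm = c(lr = 0.3, si = 0.5, ap = 0.6),
       random_mm = c(lr = 0.7, si = 1.4, ap = 1.9))
}

# deterministic sub-seed derivation so any patient/fraction is reproducible
# in isolation; kept within 32-bit integer range
.derive_seed <- function(seed, patient, fraction = 0L) {
  as.integer((as.numeric(seed) * 48271 + patient * 9973 + fraction * 101) %%
               2147483647)
}

# per-patient character sampler: regime, motion magnitude per axis, and the
# patient-level mean offset. The amplitude factor is Gamma(shape 4, mean 1)
# on the variance scale, giving a cohort with a few large movers.
.sample_patient_character <- function(targets) {
  regime <- sample(c("stable", "drift", "transient", "persistent", "mixed"),
                   1, prob = c(0.30, 0.25, 0.20, 0.15, 0.10))
  g <- stats::rgamma(1, shape = 4, rate = 4)
  list(regime = regime,
       mean_offset_mm = stats::rnorm(3, 0, targets$systematic_mm),
       axis_sd_mm = targets$random_mm * sqrt(g))
}

# raw per-fraction shape trace for a regime: realistic component mix whose
# scale is later standardized away
.regime_params <- function(regime) {
  jit <- c(0.4, 1.0, 1.0)
  switch(regime,
    stable = motion_params("stable", jitter_sd_mm = 0.6 * jit),
    drift = motion_params("drift",
      drift_rate_mm_per_min = c(0.1, 0.5, 0.6) * sample(c(-1, 1), 3, TRUE),
      jitter_sd_mm = 0.5 * jit),
    transient = motion_params("transient",
      excursion_amplitude_mm = 4, excursion_duration_s = 30,
      excursion_rate_per_min = 0.6, jitter_sd_mm = 0.5 * jit),
    persistent = motion_params("persistent",
      persistent_offset_mm = c(0.5, 2, 2.5) * sample(c(-1, 1), 3, TRUE),
      jitter_sd_mm = 0.5 * jit),
    mixed = motion_params("mixed",
      drift_rate_mm_per_min = c(0.05, 0.3, 0.4) * sample(c(-1, 1), 3, TRUE),
      excursion_amplitude_mm = 3, excursion_duration_s = 25,
      excursion_rate_per_min = 0.4, jitter_sd_mm = 0.5 * jit))
}

#' Generate a synthetic patient cohort of motion traces
#'
#' Draws per-patient motion character once (regime, per-axis magnitude,
#' patient-level mean offset) and reuses it across that patient's fractions,
#' so each patient shows a consistent motion character from fraction to
#' fraction while individual fractions differ in realization. Each fraction
#' trace is built as a shape/scale decomposition: a regime-specific raw trace
#' is standardized per axis (zero time-mean, unit time-SD) and then scaled to
#' the patient's per-axis magnitude and shifted by the patient's mean offset.
#' This makes the cohort-level systematic and random motion components
#' directly calibrated: the patient-mean displacement equals the patient
#' offset (drawn with SD = systematic target) and the per-patient
#' displacement SD equals the patient magnitude (RMS = random target).
#'
#' @param n_patients number of patients (default 17).
#' @param n_fractions tracked fractions per patient (default 14).
#' @param duration_s trace duration (s), default 300.
#' @param rate_hz sampling rate (Hz), default 10.
#' @param seed cohort seed; per-patient and per-fraction seeds are derived
#'   deterministically from it.
#' @param targets calibration targets, see [cohort_motion_targets()].
#' @param motion_scale multiplier applied to both targets (> 1 simulates a
#'   high-motion cohort).
#' @return an object of class \code{"motion_cohort"}: a list of patients,
#'   each a list with \code{character} and \code{traces} (list of
#'   [motion_trace()]).
#' @export
generate_cohort <- function(n_patients = 17, n_fractions = 14,
                            duration_s = 300, rate_hz = 10, seed = 1,
                            targets = cohort_motion_targets(),
                            motion_scale = 1) {
  if (n_patients < 1 || n_fractions < 1)
    stop("'n_patients' and 'n_fractions' must be at least 1")
  targets$systematic_mm <- targets$systematic_mm * motion_scale
  targets$random_mm <- targets$random_mm * motion_scale
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    set.seed(.derive_seed(seed, p))
    ch <- .sample_patient_character(targets)
    traces <- vector("list", n_fractions)
    for (f in seq_len(n_fractions)) {
      set.seed(.derive_seed(seed, p, f))
      par <- .regime_params(ch$regime)
      raw <- generate_trace(par, duration_s, rate_hz, seed = NULL)
      disp <- raw$disp_mm
      for (i in 1:3) {
        s <- stats::sd(disp[, i])
        disp[, i] <- if (s > 0) (disp[, i] - mean(disp[, i])) / s else 0
        disp[, i] <- ch$mean_offset_mm[i] + ch$axis_sd_mm[i] * disp[, i]
      }
      traces[[f]] <- motion_trace(raw$times_s, disp, rate_hz)
    }
    patients[[p]] <- list(character = ch, traces = traces)
  }
  structure(list(patients = patients, seed = seed, targets = targets,
                 duration_s = duration_s, rate_hz = rate_hz),
            class = "motion_cohort")
}

#' @export
print.motion_cohort <- function(x, ...) {
  nf <- length(x$patients[[1]]$traces)
  cat(sprintf("Synthetic motion cohort: %d patients x %d fractions (%d traces), %.0f s at %.0f Hz\n",
              length(x$patients), nf, length(x$patients) * nf,
              x$duration_s, x$rate_hz))
  regimes <- vapply(x$patients, function(p) p$character$regime, "")
  cat("  regimes:", paste(sprintf("%s(%d)", names(table(regimes)),
                                  table(regimes)), collapse = " "), "\n")
  invisible(x)
}

#' Cohort systematic and random motion components
#'
#' Per axis: the patient mean displacement is the mean over all samples of
#' all that patient's traces; the \emph{systematic} component is the sample
#' SD of these patient means across the cohort. The patient-specific SD is
#' the SD over all the patient's samples; the \emph{random} component is the
#' root-mean-square of these SDs. Exceedance fractions report, per patient,
#' the fraction of tracked time the 3D displacement magnitude exceeds 3, 5
#' and 7 mm.
#'
#' @param cohort a [generate_cohort()] result, or a bare list of patients
#'   each holding a list of [motion_trace()] under \code{traces}.
#' @return an object of class \code{"motion_summary"} with
#'   \code{systematic_mm}, \code{random_mm} (3-vectors, LR/SI/AP) and
#'   \code{exceedance_fractions} (patients x thresholds matrix).
#' @export
motion_components <- function(cohort) {
  patients <- if (inherits(cohort, "motion_cohort")) cohort$patients else cohort
  if (length(patients) < 2)
    stop("systematic component undefined for fewer than 2 patients")
  thr <- c(3, 5, 7)
  np <- length(patients)
  mu <- matrix(0, np, 3)
  sdv <- matrix(0, np, 3)
  exc <- matrix(0, np, 3, dimnames = list(NULL, paste0("mm", thr)))
  for (p in seq_len(np)) {
    disp <- do.call(rbind, lapply(patients[[p]]$traces, function(tr) tr$disp_mm))
    mu[p, ] <- colMeans(disp)
    sdv[p, ] <- apply(disp, 2, stats::sd)
    mag <- sqrt(rowSums(disp^2))
    exc[p, ] <- vapply(thr, function(h) mean(mag > h), numeric(1))
  }
  structure(list(
    systematic_mm = stats::setNames(apply(mu, 2, stats::sd),
                                    c("lr", "si", "ap")),
    random_mm = stats::setNames(sqrt(colMeans(sdv^2)), c("lr", "si", "ap")),
    exceedance_fractions = exc,
    n_patients = np), class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat("Cohort intrafraction motion components (mm):\n")
  m <- rbind(systematic = x$systematic_mm, random = x$random_mm)
  print(round(m, 2))
  n10 <- colSums(x$exceedance_fractions >= 0.10)
  cat(sprintf("  patients with >=10%% of time beyond 3/5/7 mm: %d/%d/%d of %d\n",
              n10[1], n10[2], n10[3], x$n_patients))
  invisible(x)
}
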