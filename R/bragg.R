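#' Analytic pristine Bragg peak model
#'
#' Constructs an analytic depth-dose model of a pristine proton Bragg peak in
#' water: a two-sided Gaussian peak (steep distal side, broad proximal
#' shoulder) on top of a slowly rising entrance plateau that is cut off at the
#' peak. The clinical \emph{range} of the peak is the nominal penetration
#' depth in g/cm^2 water-equivalent; the peak maximum sits within
#' \code{peak_width_gcm2} of it. The entrance amplitude is calibrated
#' numerically at construction so that dose at depth 0 divided by the peak
#' dose equals \code{entrance_ratio} exactly.
#'
#' @param range_gcm2 beam range in g/cm^2 water-equivalent (> 0).
#' @param peak_width_gcm2 longitudinal spread parameter of the peak (> 0).
#'   Dose beyond \code{range_gcm2 + 3 * peak_width_gcm2} is below 1\% of the
#'   peak dose.
#' @param entrance_ratio entrance-to-peak dose ratio, in [0, 1).
#' @return an object of class \code{"bragg_peak"}.
#' @seealso [bragg_depth_dose()], [build_layer_set()], [solve_layer_weights()]
#' @export
#' @examples
#' bp <- bragg_peak(30.1)
#' bragg_depth_dose(bp, c(0, 25, 30.1))
bragg_peak <- function(range_gcm2, peak_width_gcm2 = 0.6,
                       entrance_ratio = 0.35) {
  stopifnot(is.numeric(range_gcm2), length(range_gcm2) == 1L)
  if (range_gcm2 <= 0) stop("'range_gcm2' must be positive")
  if (peak_width_gcm2 <= 0) stop("'peak_width_gcm2' must be positive")
  if (entrance_ratio < 0 || entrance_ratio >= 1)
    stop("'entrance_ratio' must be in [0, 1)")

  model <- list(
    range_gcm2 = range_gcm2,
    peak_width_gcm2 = peak_width_gcm2,
    entrance_ratio = entrance_ratio,
    # shape constants: peak center offset beyond the nominal range, distal and
    # proximal sigma, entrance ramp slope (all in units of peak_width)
    mu_offset = 0.35,
    sigma_distal = 0.45,
    sigma_proximal = 1.10,
    ramp_slope = 0.40,
    entrance_amp = entrance_ratio  # provisional; calibrated below
  )
  class(model) <- "bragg_peak"

  # fixed-point calibration of the entrance amplitude: entrance/peak ratio
  # must equal entrance_ratio after the plateau term shifts the peak dose
  zg <- seq(0, range_gcm2 + 3 * peak_width_gcm2,
            by = peak_width_gcm2 / 50)
  for (i in 1:25) {
    pk <- max(.bragg_eval(model, zg))
    model$entrance_amp <- entrance_ratio * pk
  }
  model$peak_dose <- max(.bragg_eval(model, zg))
  model
}

# raw (uncalibrated-scale) depth-dose evaluation; depth vectorized
.bragg_eval <- function(model, depth) {
  pw <- model$peak_width_gcm2
  mu <- model$range_gcm2 + model$mu_offset * pw
  s_d <- model$sigma_distal * pw
  s_p <- model$sigma_proximal * pw
  s <- ifelse(depth > mu, s_d, s_p)
  peak <- exp(-(depth - mu)^2 / (2 * s^2))
  plateau <- model$entrance_amp *
    (1 + model$ramp_slope * depth / model$range_gcm2) *
    stats::pnorm((mu - depth) / s_p)
  peak + plateau
}

#' Evaluate pristine Bragg peak depth-dose
#'
#' @param model a [bragg_peak()] object.
#' @param depth_gcm2 vector of depths in g/cm^2 water-equivalent (>= 0).
#' @return relative dose (peak dose = 1), same length as \code{depth_gcm2}.
#' @export
bragg_depth_dose <- function(model, depth_gcm2) {
  stopifnot(inherits(model, "bragg_peak"))
  if (any(depth_gcm2 < 0)) stop("'depth_gcm2' must be nonnegative")
  .bragg_eval(model, depth_gcm2) / model$peak_dose
}

#' @export
print.bragg_peak <- function(x, ...) {
  cat("Pristine Bragg peak model\n")
  cat(sprintf("  range: %.2f g/cm^2, peak width: %.2f g/cm^2, entrance ratio: %.2f\n",
              x$range_gcm2, x$peak_width_gcm2, x$entrance_ratio))
  invisible(x)
}

#' Decompose an SOBP field into energy layers
#'
#' An SOBP with distal range \code{range_gcm2} and modulation width
#' \code{modulation_gcm2} is composed of \code{ceiling(modulation / spacing)}
#' energy layers whose ranges decrease from the distal layer in steps of
#' \code{spacing_gcm2}. A range of 30.1 g/cm^2 with 8.4 g/cm^2 modulation at
#' the default 0.6 g/cm^2 spacing yields 14 layers.
#'
#' @param range_gcm2 distal layer range (g/cm^2).
#' @param modulation_gcm2 modulation width (g/cm^2), 0 < modulation <= range.
#' @param spacing_gcm2 inter-layer range step (g/cm^2, > 0).
#' @return an object of class \code{"layer_set"} with fields
#'   \code{range_gcm2}, \code{modulation_gcm2}, \code{spacing_gcm2},
#'   \code{n_layers}, \code{ranges_gcm2} (distal to proximal) and
#'   \code{weights} (\code{NULL} until [solve_layer_weights()] is applied).
#' @export
build_layer_set <- function(range_gcm2, modulation_gcm2, spacing_gcm2 = 0.6) {
  if (range_gcm2 <= 0) stop("'range_gcm2' must be positive")
  if (modulation_gcm2 <= 0) stop("'modulation_gcm2' must be positive")
  if (modulation_gcm2 > range_gcm2)
    stop("modulation width exceeds beam range (target deeper than beam reach)")
  if (spacing_gcm2 <= 0) stop("'spacing_gcm2' must be positive")
  # tolerance guard: 8.4 / 0.6 is 14 + 2e-16 in floating point
  n <- as.integer(ceiling(modulation_gcm2 / spacing_gcm2 - 1e-9))
  structure(list(
    range_gcm2 = range_gcm2,
    modulation_gcm2 = modulation_gcm2,
    spacing_gcm2 = spacing_gcm2,
    n_layers = n,
    ranges_gcm2 = range_gcm2 - (seq_len(n) - 1L) * spacing_gcm2,
    weights = NULL
  ), class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  cat(sprintf("Energy layer set: %d layers, range %.2f g/cm^2, modulation %.2f g/cm^2, spacing %.2f g/cm^2\n",
              x$n_layers, x$range_gcm2, x$modulation_gcm2, x$spacing_gcm2))
  if (!is.null(x$weights))
    cat("  weights (distal to proximal):",
        paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Solve pristine peak weights for a flat SOBP
#'
#' Determines nonnegative per-layer weights so that the composed depth-dose
#' (the weighted sum of the pristine peaks, one per layer) is flat across the
#' modulation interval \code{[range - modulation, range]}. Weights are fit by
#' nonnegative least squares on a regular depth grid; an iteratively
#' reweighted refinement pushes the fit toward minimax flatness. The returned
#' weights are normalized to sum to one; the plateau scale needed to bring
#' the composed curve to 1 is stored as \code{sobp_scale}.
#'
#' @param model a [bragg_peak()] object (the distal layer; proximal layers
#'   share its shape at reduced range).
#' @param layers a [build_layer_set()] object.
#' @param flatness_tol maximum allowed relative deviation of the composed
#'   depth-dose from its plateau mean over the modulation interval
#'   (default 0.02, i.e. 2\%).
#' @param grid_step_gcm2 depth grid step for the fit (default 0.1 g/cm^2).
#' @return the layer set with \code{weights}, \code{sobp_scale} and
#'   \code{achieved_flatness} filled in.
#' @export
solve_layer_weights <- function(model, layers, flatness_tol = 0.02,
                                grid_step_gcm2 = 0.1) {
  stopifnot(inherits(model, "bragg_peak"), inherits(layers, "layer_set"))
  n <- layers$n_layers
  if (n == 1L) {
    layers$weights <- 1
    layers$sobp_scale <- 1 / bragg_depth_dose(model, layers$range_gcm2)
    layers$achieved_flatness <- 0
    return(layers)
  }
  zfit <- seq(layers$range_gcm2 - layers$modulation_gcm2, layers$range_gcm2,
              by = grid_step_gcm2)
  B <- vapply(layers$ranges_gcm2, function(rk) {
    mk <- model; mk$range_gcm2 <- rk
    .bragg_eval(mk, zfit) / model$peak_dose
  }, numeric(length(zfit)))

  # NNLS with iterative point reweighting toward minimax flatness; keep the
  # best iterate (deterministic)
  pt <- rep(1, length(zfit))
  best_dev <- Inf; w_best <- NULL
  for (it in 1:60) {
    sw <- sqrt(pt)
    w <- pracma::lsqnonneg(B * sw, sw)$x
    comp <- as.vector(B %*% w)
    dev <- abs(comp / mean(comp) - 1)
    if (max(dev) < best_dev) { best_dev <- max(dev); w_best <- w }
    pt <- pt * (1 + 5 * dev / max(dev))
    pt <- pt / mean(pt)
  }
  if (best_dev > flatness_tol)
    stop(sprintf(
      "flat SOBP infeasible at this spacing: achieved flatness %.3f%% > tolerance %.3f%%",
      100 * best_dev, 100 * flatness_tol))
  comp <- as.vector(B %*% w_best)
  layers$weights <- w_best / sum(w_best)
  layers$sobp_scale <- sum(w_best) / mean(comp)
  layers$achieved_flatness <- best_dev
  layers
}

#' Composed SOBP depth-dose
#'
#' Weighted sum of the pristine peaks of a solved layer set, scaled so the
#' plateau over the modulation interval is 1.
#'
#' @inheritParams solve_layer_weights
#' @param depth_gcm2 vector of depths (g/cm^2).
#' @return relative composed dose (plateau = 1).
#' @export
sobp_depth_dose <- function(model, layers, depth_gcm2) {
  stopifnot(inherits(layers, "layer_set"))
  if (is.null(layers$weights))
    stop("layer set has no weights; call solve_layer_weights() first")
  acc <- numeric(length(depth_gcm2))
  for (k in seq_len(layers$n_layers)) {
    mk <- model; mk$range_gcm2 <- layers$ranges_gcm2[k]
    acc <- acc + layers$weights[k] * (.bragg_eval(mk, depth_gcm2) / model$peak_dose)
  }
  acc * layers$sobp_scale
}
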