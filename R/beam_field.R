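#' Per-layer 3D dose grid
#'
#' Builds the unweighted 3D dose grid of one energy layer under a separable
#' beam model: the pristine depth-dose of the layer along the beam axis
#' multiplied by a lateral profile that is flat inside the aperture (the
#' beam's-eye-view CTV projection expanded by the aperture margin) and rolls
#' off through an error-function penumbra. The medium is homogeneous water
#' (1 g/cm^3), so depth in g/cm^2 is depth in mm / 10. The distal layer's
#' range is placed at the distal CTV surface plus the distal margin.
#'
#' @param k layer index, 1 = most distal.
#' @param model a [bragg_peak()] for the distal layer.
#' @param layers a solved [build_layer_set()].
#' @param geom a [field_geometry()].
#' @param ctv a [ctv_geometry()].
#' @param grid_spacing_mm isotropic grid voxel size (mm), default 1.
#' @param pad_mm grid padding beyond the CTV bounding box (mm); must exceed
#'   the largest expected motion plus interpolation slack.
#' @param bounds optional explicit grid bounds, a list with elements
#'   \code{lo} and \code{hi} (3-vectors, mm); must enclose the CTV.
#' @return a [dose_grid()] of unweighted relative layer dose (pristine peak
#'   maximum of the distal layer = 1).
#' @export
build_layer_dose_grid <- function(k, model, layers, geom, ctv,
                                  grid_spacing_mm = 1, pad_mm = 25,
                                  bounds = NULL) {
  stopifnot(inherits(layers, "layer_set"), inherits(geom, "field_geometry"),
            inherits(ctv, "ctv_geometry"))
  if (k < 1 || k > layers$n_layers) stop("layer index out of range")
  ax <- .field_grid_axes(ctv, grid_spacing_mm, pad_mm, bounds)
  depth <- .beam_depth_gcm2(ax$x, layers, geom, ctv)
  mk <- model; mk$range_gcm2 <- layers$ranges_gcm2[k]
  dprof <- .bragg_eval(mk, pmax(depth, 0)) / model$peak_dose
  lat <- .lateral_profile(ax$y, ax$z, geom, ctv)
  vals <- array(0, dim = c(length(ax$x), length(ax$y), length(ax$z)))
  for (iz in seq_along(ax$z))
    vals[, , iz] <- outer(dprof, lat[, iz])
  dose_grid(c(ax$x[1], ax$y[1], ax$z[1]), rep(grid_spacing_mm, 3), vals)
}

# grid axes enclosing the CTV bounding box plus padding; the default grid is
# symmetric about the CTV centre so mirrored fields share a mirrored grid
.field_grid_axes <- function(ctv, spacing, pad, bounds = NULL) {
  if (!is.null(bounds)) {
    if (any(bounds$lo > ctv$center_mm - ctv$semi_axes_mm) ||
        any(bounds$hi < ctv$center_mm + ctv$semi_axes_mm))
      stop("grid bounds do not enclose the CTV")
    return(list(x = seq(bounds$lo[1], bounds$hi[1], by = spacing),
                y = seq(bounds$lo[2], bounds$hi[2], by = spacing),
                z = seq(bounds$lo[3], bounds$hi[3], by = spacing)))
  }
  ax <- lapply(1:3, function(i) {
    half <- ceiling((ctv$semi_axes_mm[i] + pad) / spacing)
    ctv$center_mm[i] + (-half:half) * spacing
  })
  names(ax) <- c("x", "y", "z")
  ax
}

# water-equivalent depth (g/cm^2) of grid x-coordinates for a lateral beam:
# the distal layer's range sits at the distal CTV surface + distal margin
.beam_depth_gcm2 <- function(x_mm, layers, geom, ctv) {
  if (geom$beam_axis == "+x") {
    x_distal <- ctv$center_mm[1] + ctv$semi_axes_mm[1] + geom$distal_margin_mm
    layers$range_gcm2 - (x_distal - x_mm) / 10
  } else {
    x_distal <- ctv$center_mm[1] - ctv$semi_axes_mm[1] - geom$distal_margin_mm
    layers$range_gcm2 - (x_mm - x_distal) / 10
  }
}

# lateral profile on the (y, z) axes: flat inside the aperture ellipse,
# error-function penumbra outside; returns length(y) x length(z) matrix
.lateral_profile <- function(y_mm, z_mm, geom, ctv) {
  b <- ctv$semi_axes_mm[2] + geom$aperture_margin_mm
  cc <- ctv$semi_axes_mm[3] + geom$aperture_margin_mm
  # 80-20% width of a Gaussian-blurred edge is 2 * qnorm(0.8) sigma
  sigma <- geom$penumbra_80_20_mm / (2 * stats::qnorm(0.8))
  u <- (y_mm - ctv$center_mm[2]) / b
  v <- (z_mm - ctv$center_mm[3]) / cc
  U <- matrix(u, length(u), length(v))
  V <- matrix(v, length(u), length(v), byrow = TRUE)
  rho <- sqrt(U^2 + V^2)
  # first-order signed distance to the ellipse: (rho - 1) / |grad rho|,
  # grad rho = (u/b, v/c) / rho
  gradn <- sqrt((U / b)^2 + (V / cc)^2)
  dist <- ifelse(gradn > 1e-12, (rho - 1) * rho / gradn, -min(b, cc))
  stats::pnorm(-dist / sigma)
}

#' Compose weighted layer grids into a beam dose grid
#'
#' Voxelwise weighted sum of the per-layer dose grids. If a normalization
#' point is supplied (typically the CTV center), the composed grid is
#' rescaled so the dose there equals 100 (percent of prescription); the
#' applied scale is attached as attribute \code{"norm_scale"} so per-layer
#' doses can be expressed on the same scale.
#'
#' @param layer_grids list of [dose_grid()] objects sharing geometry.
#' @param weights nonnegative per-layer weights.
#' @param norm_point_mm optional 3-vector: point where composed dose is
#'   normalized to 100.
#' @return a [dose_grid()] of composed dose.
#' @export
compose_beam_dose <- function(layer_grids, weights, norm_point_mm = NULL) {
  stopifnot(length(layer_grids) == length(weights), all(weights >= 0))
  g1 <- layer_grids[[1]]
  for (g in layer_grids[-1]) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        !isTRUE(all.equal(g$origin_mm, g1$origin_mm)) ||
        !isTRUE(all.equal(g$spacing_mm, g1$spacing_mm)))
      stop("layer grids do not share origin/spacing/shape")
  }
  acc <- array(0, dim = dim(g1$values))
  for (k in seq_along(layer_grids))
    acc <- acc + weights[k] * layer_grids[[k]]$values
  out <- dose_grid(g1$origin_mm, g1$spacing_mm, acc)
  scale <- 1
  if (!is.null(norm_point_mm)) {
    ref <- interp_dose(out, matrix(norm_point_mm, 1))
    if (ref <= 0) stop("composed dose is zero at the normalization point")
    scale <- 100 / ref
    out$values <- out$values * scale
  }
  attr(out, "norm_scale") <- scale
  out
}

#' Build a complete treatment field
#'
#' Assembles one lateral field: all unweighted per-layer dose grids, the
#' composed SOBP grid normalized to 100\% of prescription at the CTV center,
#' and the effective per-layer scales (weight times normalization) that put
#' individual layers on the composed percent scale. The composed grid is
#' exactly the scale-weighted sum of the layer grids, so a layer-by-layer
#' delivery that completes all layers reproduces the composed dose to
#' machine precision.
#'
#' @inheritParams build_layer_dose_grid
#' @param normalize plan normalization: \code{"ctv_min"} (default) scales the
#'   composed dose so the minimum static CTV dose is 100\%, i.e. the
#'   prescription isodose just covers the CTV, as a clinical plan would be
#'   normalized; \code{"center"} sets the dose at the CTV center to 100\%.
#' @return an object of class \code{"beam_field"} with elements
#'   \code{layer_grids}, \code{composed}, \code{layer_scale}, \code{layers},
#'   \code{geom}, \code{ctv}.
#' @export
build_field <- function(model, layers, geom, ctv, grid_spacing_mm = 1,
                        pad_mm = 25, bounds = NULL,
                        normalize = c("ctv_min", "center")) {
  normalize <- match.arg(normalize)
  if (is.null(layers$weights))
    stop("layer set has no weights; call solve_layer_weights() first")
  lg <- lapply(seq_len(layers$n_layers), function(k)
    build_layer_dose_grid(k, model, layers, geom, ctv, grid_spacing_mm,
                          pad_mm, bounds))
  composed <- compose_beam_dose(lg, layers$weights, ctv$center_mm)
  scale <- attr(composed, "norm_scale")
  if (normalize == "ctv_min") {
    # prescription isodose covers the CTV: static CTV minimum = 100%
    extra <- 100 / min(interp_dose(composed, ctv$voxels_mm))
    composed$values <- composed$values * extra
    attr(composed, "norm_scale") <- scale * extra
    scale <- scale * extra
  }
  structure(list(layer_grids = lg,
                 composed = composed,
                 layer_scale = layers$weights * scale,
                 layers = layers, geom = geom, ctv = ctv),
            class = "beam_field")
}

#' @export
print.beam_field <- function(x, ...) {
  cat(sprintf("Proton field (%s): %d energy layers\n",
              x$geom$beam_axis, x$layers$n_layers))
  print(x$composed)
  invisible(x)
}
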