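#' Clinical target volume geometry
#'
#' The CTV is modeled as an ellipsoid, rigidly translated during delivery.
#' Dose is accumulated at a regular lattice of sample points (voxel centers)
#' inside the ellipsoid at its nominal (setup) position; equal voxel volumes
#' make DVH volume fractions simple point counts.
#'
#' @param semi_axes_mm numeric 3-vector of ellipsoid semi-axes (mm) in
#'   (LR, AP, SI) order.
#' @param center_mm ellipsoid center (mm), default the isocenter at origin.
#' @param voxel_mm sampling lattice pitch (mm); 2 mm resolves a prostate-size
#'   target with a few thousand points.
#' @return an object of class \code{"ctv_geometry"} with the n x 3 matrix of
#'   voxel centers (columns x = LR, y = AP, z = SI).
#' @export
ctv_geometry <- function(semi_axes_mm = c(20, 16, 18), center_mm = c(0, 0, 0),
                         voxel_mm = 2) {
  stopifnot(length(semi_axes_mm) == 3L, all(semi_axes_mm > 0), voxel_mm > 0)
  # lattice symmetric about the centre, so mirrored fields sample the same
  # dose multiset on a symmetric CTV
  ax <- lapply(1:3, function(i) {
    half <- floor(semi_axes_mm[i] / voxel_mm) * voxel_mm
    center_mm[i] + seq(-half, half, by = voxel_mm)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  u <- sweep(pts, 2, center_mm)
  inside <- (u[, 1] / semi_axes_mm[1])^2 + (u[, 2] / semi_axes_mm[2])^2 +
    (u[, 3] / semi_axes_mm[3])^2 <= 1
  if (!any(inside)) stop("CTV sampling produced no voxels; reduce 'voxel_mm'")
  structure(list(voxels_mm = pts[inside, , drop = FALSE],
                 semi_axes_mm = semi_axes_mm,
                 center_mm = as.numeric(center_mm),
                 voxel_mm = voxel_mm),
            class = "ctv_geometry")
}

#' @export
print.ctv_geometry <- function(x, ...) {
  cat(sprintf("Ellipsoidal CTV: semi-axes %s mm (LR/AP/SI), %d sample voxels at %.1f mm pitch\n",
              paste(format(x$semi_axes_mm), collapse = "/"),
              nrow(x$voxels_mm), x$voxel_mm))
  invisible(x)
}

#' Lateral proton field geometry
#'
#' Geometry of one lateral treatment field. Beams are modeled as purely
#' lateral (along the patient x = LR axis): \code{"+x"} means the beam
#' travels in the +x direction (enters from the patient's right),
#' \code{"-x"} the reverse. The aperture is the beam's-eye-view projection
#' of the CTV expanded by \code{aperture_margin_mm}, with an error-function
#' lateral penumbra of 80--20\% width \code{penumbra_80_20_mm}. Range margins
#' extend SOBP coverage beyond the CTV along the beam axis.
#'
#' @param beam_axis \code{"+x"} or \code{"-x"}.
#' @param iso_mm isocenter (mm).
#' @param aperture_margin_mm lateral margin beyond the CTV projection (mm).
#' @param penumbra_80_20_mm lateral 80--20\% penumbra width (mm).
#' @param distal_margin_mm,proximal_margin_mm range margins (mm).
#' @return an object of class \code{"field_geometry"}.
#' @export
field_geometry <- function(beam_axis = c("+x", "-x"), iso_mm = c(0, 0, 0),
                           aperture_margin_mm = 8, penumbra_80_20_mm = 6,
                           distal_margin_mm = 5, proximal_margin_mm = 10) {
  beam_axis <- match.arg(beam_axis)
  if (aperture_margin_mm < 0 || distal_margin_mm < 0 || proximal_margin_mm < 0)
    stop("margins must be nonnegative")
  if (penumbra_80_20_mm <= 0) stop("'penumbra_80_20_mm' must be positive")
  structure(list(beam_axis = beam_axis, iso_mm = as.numeric(iso_mm),
                 aperture_margin_mm = aperture_margin_mm,
                 penumbra_80_20_mm = penumbra_80_20_mm,
                 distal_margin_mm = distal_margin_mm,
                 proximal_margin_mm = proximal_margin_mm),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("Lateral field (%s): aperture margin %.1f mm, penumbra %.1f mm, distal/proximal margins %.1f/%.1f mm\n",
              x$beam_axis, x$aperture_margin_mm, x$penumbra_80_20_mm,
              x$distal_margin_mm, x$proximal_margin_mm))
  invisible(x)
}
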