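#' Regular 3D dose grid
#'
#' Container for a dose distribution sampled on a regular axis-aligned grid in
#' fixed patient axes: x = left-right (LR), y = anterior-posterior (AP),
#' z = superior-inferior (SI). Dose values are expressed as percent of the
#' fraction prescription.
#'
#' @param origin_mm numeric 3-vector, coordinates (mm) of the center of the
#'   first voxel.
#' @param spacing_mm numeric 3-vector of positive voxel spacings (mm).
#' @param values 3D numeric array of nonnegative dose values, dimension
#'   ordered (x, y, z).
#' @return an object of class \code{"dose_grid"}.
#' @export
dose_grid <- function(origin_mm, spacing_mm, values) {
  stopifnot(length(origin_mm) == 3L, length(spacing_mm) == 3L,
            is.array(values), length(dim(values)) == 3L)
  if (any(spacing_mm <= 0)) stop("'spacing_mm' components must be positive")
  if (any(values < 0)) stop("dose values must be nonnegative")
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 values = values),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dose grid %d x %d x %d (x=LR, y=AP, z=SI), spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = "/"),
              paste(format(x$origin_mm), collapse = "/")))
  cat(sprintf("  dose range: %.2f to %.2f %% of prescription\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# coordinate vectors of the grid axes
grid_axes <- function(g) {
  d <- dim(g$values)
  lapply(1:3, function(i) g$origin_mm[i] + (seq_len(d[i]) - 1) * g$spacing_mm[i])
}

#' Trilinear interpolation on a dose grid
#'
#' Samples the grid at arbitrary points by trilinear interpolation. Points
#' outside the grid bounding box are an error: the grid must be padded to
#' cover the largest expected target motion.
#'
#' @param g a [dose_grid()].
#' @param pts n x 3 matrix of query points (mm), columns (x, y, z).
#' @return numeric vector of interpolated dose values, length n.
#' @export
interp_dose <- function(g, pts) {
  stopifnot(inherits(g, "dose_grid"))
  pts <- matrix(pts, ncol = 3L)
  d <- dim(g$values)
  # fractional voxel index per axis
  fx <- (pts[, 1] - g$origin_mm[1]) / g$spacing_mm[1]
  fy <- (pts[, 2] - g$origin_mm[2]) / g$spacing_mm[2]
  fz <- (pts[, 3] - g$origin_mm[3]) / g$spacing_mm[3]
  eps <- 1e-9
  if (any(fx < -eps | fx > d[1] - 1 + eps |
          fy < -eps | fy > d[2] - 1 + eps |
          fz < -eps | fz > d[3] - 1 + eps))
    stop("query point outside dose grid; pad the grid for the expected motion range")
  i0 <- pmin(pmax(floor(fx), 0), d[1] - 2); tx <- fx - i0
  j0 <- pmin(pmax(floor(fy), 0), d[2] - 2); ty <- fy - j0
  k0 <- pmin(pmax(floor(fz), 0), d[3] - 2); tz <- fz - k0
  v <- g$values
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  c000 <- v[idx(i0,     j0,     k0)]
  c100 <- v[idx(i0 + 1, j0,     k0)]
  c010 <- v[idx(i0,     j0 + 1, k0)]
  c110 <- v[idx(i0 + 1, j0 + 1, k0)]
  c001 <- v[idx(i0,     j0,     k0 + 1)]
  c101 <- v[idx(i0 + 1, j0,     k0 + 1)]
  c011 <- v[idx(i0,     j0 + 1, k0 + 1)]
  c111 <- v[idx(i0 + 1, j0 + 1, k0 + 1)]
  (((c000 * (1 - tx) + c100 * tx) * (1 - ty) +
    (c010 * (1 - tx) + c110 * tx) * ty) * (1 - tz) +
   ((c001 * (1 - tx) + c101 * tx) * (1 - ty) +
    (c011 * (1 - tx) + c111 * tx) * ty) * tz)
}

#' Write / read a dose grid as ASCII NRRD
#'
#' Plain-text NRRD serialization (\code{encoding: ascii}) preserving origin
#' and spacing metadata, so grids survive as human-readable text. Values are
#' written in C order (x fastest), matching the NRRD axis convention used
#' here (sizes listed x, y, z).
#'
#' @param g a [dose_grid()].
#' @param path output file path.
#' @return \code{write_nrrd} returns \code{path} invisibly; \code{read_nrrd}
#'   returns a [dose_grid()].
#' @export
write_nrrd <- function(g, path) {
  stopifnot(inherits(g, "dose_grid"))
  d <- dim(g$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "# dose grid, percent of prescription; axes x=LR y=AP z=SI",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: ascii",
    "space: right-anterior-superior",
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            g$origin_mm[1], g$origin_mm[2], g$origin_mm[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            g$spacing_mm[1], g$spacing_mm[2], g$spacing_mm[3]),
    ""
  ), con)
  writeLines(format(as.vector(g$values), digits = 12, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD"))
    stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no blank line before data")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0(name, ":"))]
    if (length(ln) == 0) stop("NRRD header missing field: ", name)
    trimws(sub(paste0("^", name, ":"), "", ln[1]))
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (tolower(field("encoding")) != "ascii")
    stop("only ascii-encoded NRRD is supported")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  origin <- parse_vec(field("space origin"))
  dirs <- regmatches(field("space directions"),
                     gregexpr("\\(([^)]*)\\)", field("space directions")))[[1]]
  spacing <- vapply(seq_along(dirs), function(i) parse_vec(dirs[i])[i],
                    numeric(1))
  vals <- as.numeric(unlist(strsplit(lines[(blank + 1):length(lines)], "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes))
    stop("NRRD data length does not match sizes")
  dose_grid(origin, spacing, array(vals, dim = sizes))
}
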