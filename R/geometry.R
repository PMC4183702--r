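#' Uniform full-circle view angles
#'
#' The sparse-view acquisitions here use `count` view angles uniformly spaced
#' over the full circle, starting at 0 and ascending, i.e.
#' `2 * pi * (0:(count-1)) / count`.
#'
#' @param count number of views (>= 1).
#' @return numeric vector of angles in radians, in `[0, 2*pi)`.
#' @examples
#' view_angles(4) * 180 / pi  # 0 90 180 270
#' @export
view_angles <- function(count) {
  if (!is.numeric(count) || length(count) != 1L || count < 1 ||
      count != round(count))
    stop("`count` must be a single integer >= 1", call. = FALSE)
  2 * pi * (seq_len(count) - 1) / count
}

#' Fan-beam acquisition geometry
#'
#' Circular fan-beam scan: the source moves on a circle of radius
#' `source_to_axis` around the rotation axis, and measurements are modeled on
#' a virtual equi-distance detector — a uniformly sampled line through the
#' rotation axis, perpendicular to the source direction. With 1025 bins of
#' 0.05 cm the detector spans 51.25 cm at the axis, covering a 51.2 cm field
#' of view (the `fov_radius` field records the nominal scan-field radius
#' descriptor).
#'
#' @param views number of view angles (ignored if `angles` given).
#' @param bins number of detector elements (>= 1).
#' @param bin_aperture detector element aperture in cm at the axis.
#' @param source_to_axis source-to-rotation-axis distance in cm.
#' @param angles optional explicit view angles in radians, each in
#'   `[0, 2*pi)`.
#' @param fov_radius nominal field-of-view radius descriptor in cm.
#' @return an object of class `fan_beam_geometry`.
#' @export
fan_beam_geometry <- function(views = 40L, bins = 1025L, bin_aperture = 0.05,
                              source_to_axis = 293.1, angles = NULL,
                              fov_radius = 51.1) {
  if (is.null(angles)) angles <- view_angles(views)
  if (any(angles < 0 | angles >= 2 * pi))
    stop("all `angles` must lie in [0, 2*pi)", call. = FALSE)
  if (bins < 1) stop("`bins` must be >= 1", call. = FALSE)
  if (bin_aperture <= 0 || source_to_axis <= 0)
    stop("`bin_aperture` and `source_to_axis` must be positive", call. = FALSE)
  structure(list(angles = as.numeric(angles), views = length(angles),
                 bins = as.integer(bins), bin_aperture = as.numeric(bin_aperture),
                 source_to_axis = as.numeric(source_to_axis),
                 fov_radius = as.numeric(fov_radius),
                 detector_kind = "equi-distance-virtual"),
            class = "fan_beam_geometry")
}

#' @export
print.fan_beam_geometry <- function(x, ...) {
  cat(sprintf(paste0("<fan_beam_geometry> %d views, %d bins x %.3g cm ",
                     "(virtual detector through axis), source-to-axis %.4g cm\n"),
              x$views, x$bins, x$bin_aperture, x$source_to_axis))
  invisible(x)
}

# source position and detector-bin center for 0-based view/bin indices
ray_points <- function(geom, view0, bin0) {
  th <- geom$angles[view0 + 1]
  src <- geom$source_to_axis * c(cos(th), sin(th))
  t <- (bin0 - (geom$bins - 1) / 2) * geom$bin_aperture
  det <- t * c(-sin(th), cos(th))
  list(src = src, det = det)
}

#' Physical ray segment for one (view, bin) pair
#'
#' Returns the line segment from the source position at the requested view,
#' through the center of the requested detector bin on the virtual detector
#' line through the rotation axis, extended to exit the image bounding box.
#'
#' @param geom a [fan_beam_geometry()].
#' @param view view index (1-based).
#' @param bin detector bin index (1-based).
#' @param grid an [image_grid()] defining the bounding box to exit.
#' @return 2 x 2 matrix; rows are the start (source) and end points, columns
#'   x and y in cm.
#' @export
ray_segment <- function(geom, view, bin, grid) {
  stopifnot(inherits(geom, "fan_beam_geometry"), inherits(grid, "image_grid"))
  if (view < 1 || view > geom$views) stop("`view` out of range", call. = FALSE)
  if (bin < 1 || bin > geom$bins) stop("`bin` out of range", call. = FALSE)
  pt <- ray_points(geom, view - 1, bin - 1)
  d <- pt$det - pt$src
  dl <- sqrt(sum(d^2))
  if (dl <= 0) stop("degenerate ray: source coincides with detector bin",
                    call. = FALSE)
  reach <- geom$source_to_axis + grid$n * grid$pixel_size
  ends <- pt$src + d / dl * (dl + reach)
  matrix(c(pt$src, ends), 2, 2, byrow = TRUE,
         dimnames = list(c("start", "end"), c("x", "y")))
}

#' Siddon ray trace through a pixel grid
#'
#' Exact intersection lengths of a line segment with every pixel it crosses,
#' computed by parametric traversal of the grid lines.
#'
#' @param grid an [image_grid()].
#' @param segment 2 x 2 matrix of endpoints (rows start/end, columns x, y in
#'   cm); the endpoints must bracket the grid bounding box.
#' @return data frame with `index` (row-major pixel index, 1-based) and
#'   `length` (cm), in traversal order; zero rows if the segment misses the
#'   grid.
#' @export
siddon_trace <- function(grid, segment) {
  stopifnot(inherits(grid, "image_grid"))
  segment <- as.matrix(segment)
  if (!all(dim(segment) == c(2, 2)))
    stop("`segment` must be a 2 x 2 matrix of endpoints", call. = FALSE)
  if (all(segment[1, ] == segment[2, ]))
    stop("degenerate zero-length segment", call. = FALSE)
  tr <- cpp_siddon_trace(segment[1, 1], segment[1, 2],
                         segment[2, 1], segment[2, 2],
                         grid$n, grid$pixel_size)
  data.frame(index = tr$index + 1L, length = tr$length)
}

#' Build the sparse fan-beam system matrix
#'
#' Computes the `M x N` matrix of ray-pixel intersection lengths (Siddon
#' tracing, one ray per detector-bin center), with `M = views x bins` rows in
#' view-major, bin-minor order and `N = n^2` row-major pixel columns. Rays
#' that miss the grid keep empty rows. Per-ray sums, per-pixel sums and
#' per-view pixel sums are cached for the SART update.
#'
#' @param geom a [fan_beam_geometry()].
#' @param grid an [image_grid()] (only `n` and `pixel_size` are used).
#' @param max_nnz memory guard: abort if the estimated number of stored
#'   intersection lengths exceeds this cap.
#' @return an object of class `system_matrix` holding the CSR arrays
#'   (`row_ptr`, `col_ind`, `val`, all 0-based), the cached sums, and the
#'   geometry/grid descriptors.
#' @export
system_matrix <- function(geom, grid, max_nnz = 3e8) {
  stopifnot(inherits(geom, "fan_beam_geometry"), inherits(grid, "image_grid"))
  M <- geom$views * geom$bins
  est <- M * 2 * grid$n
  if (est > max_nnz)
    stop("estimated nonzeros (", format(est, big.mark = ","),
         ") exceed max_nnz; reduce the grid side n or raise `max_nnz`",
         call. = FALSE)
  raw <- cpp_build_system_matrix(geom$angles, geom$bins, geom$bin_aperture,
                                 geom$source_to_axis, grid$n, grid$pixel_size)
  structure(list(row_ptr = raw$row_ptr, col_ind = raw$col_ind, val = raw$val,
                 row_sums = raw$row_sums, col_sums = raw$col_sums,
                 view_col_sums = raw$view_col_sums,
                 M = M, N = grid$n^2, geom = geom,
                 n = grid$n, pixel_size = grid$pixel_size),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d x %d, %s stored lengths (%d views x %d bins)\n",
              x$M, x$N, format(length(x$val), big.mark = ","),
              x$geom$views, x$geom$bins))
  invisible(x)
}

#' Dense copy of a system matrix (small problems only)
#' @param A a [system_matrix()].
#' @return dense `M x N` matrix.
#' @export
as_dense_matrix <- function(A) {
  stopifnot(inherits(A, "system_matrix"))
  if (A$M * A$N > 5e7) stop("matrix too large to densify", call. = FALSE)
  D <- matrix(0, A$M, A$N)
  rp <- A$row_ptr
  for (i in seq_len(A$M)) {
    k <- rp[i] + seq_len(rp[i + 1] - rp[i])
    D[i, A$col_ind[k] + 1L] <- A$val[k]
  }
  D
}

#' Forward projection p = A f
#' @param A a [system_matrix()].
#' @param image an [image_grid()] with `n^2 == A$N` pixels.
#' @return a `sinogram` object (values arranged views x bins).
#' @export
forward_project <- function(A, image) {
  stopifnot(inherits(A, "system_matrix"), inherits(image, "image_grid"))
  if (image$n^2 != A$N)
    stop("image has ", image$n^2, " pixels but the system matrix expects ",
         A$N, call. = FALSE)
  p <- cpp_forward(A$row_ptr, A$col_ind, A$val, as_pixel_vector(image))
  sinogram(matrix(p, nrow = A$geom$views, ncol = A$geom$bins, byrow = TRUE),
           A$geom)
}

#' Back projection A' p
#' @param A a [system_matrix()].
#' @param sino a [sinogram()] with `M` values.
#' @return an [image_grid()] holding the transposed-matrix image.
#' @export
back_project <- function(A, sino) {
  stopifnot(inherits(A, "system_matrix"), inherits(sino, "sinogram"))
  p <- as_ray_vector(sino)
  if (length(p) != A$M)
    stop("sinogram has ", length(p), " rays but the system matrix expects ",
         A$M, call. = FALSE)
  f <- cpp_back(A$row_ptr, A$col_ind, A$val, p, A$N)
  image_grid(f, pixel_size = A$pixel_size, n = A$n)
}

#' Sinogram container
#'
#' Ray-sum measurements arranged views x bins with a reference to the
#' acquisition geometry.
#'
#' @param values numeric `views x bins` matrix of ray sums.
#' @param geom the [fan_beam_geometry()] that produced them.
#' @param meta optional provenance list (noise spec, seed, ...).
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geom, meta = list()) {
  stopifnot(inherits(geom, "fan_beam_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geom$views || ncol(values) != geom$bins)
    stop("sinogram shape ", nrow(values), " x ", ncol(values),
         " does not match geometry (", geom$views, " views x ", geom$bins,
         " bins)", call. = FALSE)
  if (!all(is.finite(values)))
    stop("sinogram values must be finite", call. = FALSE)
  structure(list(values = values, geom = geom, meta = meta),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d bins, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# ray-major (view-major, bin-minor) vector matching system-matrix row order
#' Flatten a sinogram to the projector's ray-ordered vector
#' @param sino a [sinogram()].
#' @return numeric vector of length `views * bins`, view-major.
#' @export
as_ray_vector <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  as.vector(t(sino$values))
}

# analytic chord length of a segment inside the grid bounding box
# (Liang-Barsky clip); used by tests and the chord-conservation property
chord_length <- function(grid, segment) {
  half <- grid$n * grid$pixel_size / 2
  x0 <- segment[1, 1]; y0 <- segment[1, 2]
  dx <- segment[2, 1] - x0; dy <- segment[2, 2] - y0
  t0 <- 0; t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 + half, half - x0, y0 + half, half - y0)
  for (k in 1:4) {
    if (p[k] == 0) { if (q[k] < 0) return(0) }
    else {
      r <- q[k] / p[k]
      if (p[k] < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  max(t1 - t0, 0) * sqrt(dx^2 + dy^2)
}
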