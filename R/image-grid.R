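#' Square pixel image with physical spacing
#'
#' The common container for ground-truth phantoms and reconstructions: an
#' `n x n` matrix of densities (linear-attenuation-like units, water = 1.0)
#' on square pixels of side `pixel_size` cm. The physical origin sits at the
#' grid center, x increases rightward (columns), y increases upward, and
#' row 1 is the top of the image.
#'
#' @param values numeric `n x n` matrix of pixel densities (row = image row,
#'   top first), or a length-`n^2` vector in row-major order.
#' @param pixel_size side length of a pixel in cm; must be positive.
#' @param n side length in pixels; required only when `values` is a vector.
#' @return An object of class `image_grid` with elements `values` (matrix),
#'   `n` and `pixel_size`.
#' @examples
#' img <- image_grid(matrix(0, 8, 8), pixel_size = 0.1)
#' @export
image_grid <- function(values, pixel_size, n = NULL) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (cm)", call. = FALSE)
  if (is.matrix(values)) {
    if (nrow(values) != ncol(values))
      stop("`values` must be a square matrix", call. = FALSE)
    n <- nrow(values)
  } else {
    if (is.null(n)) stop("`n` is required when `values` is a vector", call. = FALSE)
    if (length(values) != n * n)
      stop("`values` has length ", length(values), ", expected n^2 = ", n * n,
           call. = FALSE)
    values <- matrix(values, n, n, byrow = TRUE)
  }
  if (n < 2) stop("grid side `n` must be at least 2 pixels", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all pixel values must be finite", call. = FALSE)
  structure(list(values = values, n = as.integer(n),
                 pixel_size = as.numeric(pixel_size)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, %.4g cm/pixel, range [%.4g, %.4g]\n",
              x$n, x$n, x$pixel_size, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.image_grid <- function(x, window = NULL, ...) {
  v <- x$values
  if (!is.null(window)) v <- pmin(pmax(v, window[1]), window[2])
  # image() draws column-major bottom-up; flip rows so row 1 is on top
  graphics::image(t(v[x$n:1, , drop = FALSE]), col = grDevices::gray.colors(256),
                  asp = 1, axes = FALSE, ...)
  invisible(x)
}

# Row-major pixel vector (matches the system-matrix pixel index j = r*n + c,
# 0-based) and its inverse.
#' Flatten an image to the projector's row-major pixel vector
#' @param img an `image_grid`.
#' @return numeric vector of length `n^2`, row-major.
#' @export
as_pixel_vector <- function(img) {
  stopifnot(inherits(img, "image_grid"))
  as.vector(t(img$values))
}

#' Rebuild an image from a row-major pixel vector
#' @param values numeric vector of length `n^2`, row-major.
#' @param like an `image_grid` supplying `n` and `pixel_size`.
#' @return an `image_grid`.
#' @export
as_image_grid <- function(values, like) {
  image_grid(values, pixel_size = like$pixel_size, n = like$n)
}

# physical center coordinates of pixel (r, c), 1-based
pixel_centers <- function(n, pixel_size) {
  half <- n * pixel_size / 2
  xc <- -half + (seq_len(n) - 0.5) * pixel_size   # by column
  yc <- half - (seq_len(n) - 0.5) * pixel_size    # by row (top first)
  list(x = xc, y = yc)
}
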