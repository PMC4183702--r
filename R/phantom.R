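#' Analytic phantom specification
#'
#' An analytic phantom is an ordered list of ellipse primitives, each adding
#' a signed density on top of whatever lies beneath it, so the phantom value
#' at a point is the sum of the densities of all ellipses containing it.
#'
#' @param shapes data frame with columns `x`, `y` (center, cm), `a`, `b`
#'   (semi-axes, cm, strictly positive), `angle` (rotation, degrees,
#'   counter-clockwise) and `density` (additive density).
#' @param name label for the phantom.
#' @return An object of class `phantom_spec`.
#' @seealso [rasterize_phantom()], [forbild_head_phantom()]
#' @export
phantom_spec <- function(shapes, name = "phantom") {
  need <- c("x", "y", "a", "b", "angle", "density")
  if (nrow(shapes) > 0) {
    miss <- setdiff(need, names(shapes))
    if (length(miss))
      stop("`shapes` is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(shapes$a <= 0) || any(shapes$b <= 0))
      stop("ellipse semi-axes must be strictly positive", call. = FALSE)
  } else {
    shapes <- data.frame(x = numeric(), y = numeric(), a = numeric(),
                         b = numeric(), angle = numeric(), density = numeric())
  }
  structure(list(shapes = shapes[, need, drop = FALSE], name = name),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': %d ellipse(s)\n", x$name, nrow(x$shapes)))
  invisible(x)
}

#' Combine two phantom specifications additively
#' @param e1,e2 `phantom_spec` objects.
#' @return a `phantom_spec` whose shape list is the concatenation.
#' @export
"+.phantom_spec" <- function(e1, e2) {
  phantom_spec(rbind(e1$shapes, e2$shapes),
               name = paste(e1$name, e2$name, sep = "+"))
}

#' Rasterize an analytic phantom onto a pixel grid
#'
#' Each pixel receives the mean additive density over `supersample^2`
#' uniformly placed sub-sample points, which anti-aliases ellipse boundaries
#' while leaving interior pixels exact. Deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param n grid side in pixels (>= 2).
#' @param pixel_size pixel side in cm (> 0).
#' @param supersample sub-samples per pixel side (>= 1); default 4.
#' @return an [image_grid()].
#' @export
rasterize_phantom <- function(spec, n, pixel_size, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (cm)", call. = FALSE)
  s <- as.integer(supersample)
  if (s < 1) stop("`supersample` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  ns <- n * s
  half <- n * pixel_size / 2
  hs <- pixel_size / s
  xs <- -half + (seq_len(ns) - 0.5) * hs      # sub-sample x by column
  ys <- half - (seq_len(ns) - 0.5) * hs       # sub-sample y by row, top first
  X <- matrix(xs, ns, ns, byrow = TRUE)
  Y <- matrix(ys, ns, ns)
  acc <- matrix(0, ns, ns)
  sh <- spec$shapes
  for (k in seq_len(nrow(sh))) {
    th <- sh$angle[k] * pi / 180
    dx <- X - sh$x[k]; dy <- Y - sh$y[k]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / sh$a[k])^2 + (v / sh$b[k])^2 <= 1
    acc <- acc + sh$density[k] * inside
  }
  if (s > 1) {
    # average s x s blocks
    acc <- rowsum(acc, rep(seq_len(n), each = s))
    acc <- t(rowsum(t(acc), rep(seq_len(n), each = s))) / (s * s)
  }
  dimnames(acc) <- NULL
  image_grid(acc, pixel_size = pixel_size)
}

# FORBILD-style 2D head slice, transcribed from the public FORBILD head
# design: outer cranium ellipse (bone, 1.80), brain interior (1.05),
# frontal-sinus air cavity, two CSF lateral ventricles (1.045), left and
# right petrous bones (1.80) with small air drill holes standing in for the
# fine high-contrast inner-ear structures, and a group of low-contrast
# lesions (1.040-1.060) that fall inside the conventional [1.03, 1.08]
# display window. Coordinates in cm, densities relative to water = 1.0.
forbild_head_shapes <- function() {
  sh <- rbind(
    # x,      y,     a,    b,    angle, density
    c( 0.0,   0.0,  9.60, 12.00,   0,  1.800),   # cranium (bone)
    c( 0.0,   0.0,  9.00, 11.40,   0, -0.750),   # brain interior -> 1.050
    c( 0.0,   9.30, 2.00,  1.30,   0, -1.050),   # frontal sinus (air)
    c(-1.10,  1.00, 0.70,  2.30,   8, -0.005),   # left ventricle -> 1.045
    c( 1.10,  1.00, 0.70,  2.30,  -8, -0.005),   # right ventricle -> 1.045
    c(-5.60, -4.20, 2.20,  1.10,  35,  0.750),   # left petrous bone -> 1.800
    c( 5.60, -4.20, 2.20,  1.10, -35,  0.750),   # right petrous bone -> 1.800
    c(-6.60, -4.90, 0.12,  0.12,   0, -1.800),   # inner-ear drill holes (air)
    c(-6.10, -4.55, 0.10,  0.10,   0, -1.800),
    c(-5.60, -4.20, 0.12,  0.12,   0, -1.800),
    c(-5.10, -3.85, 0.10,  0.10,   0, -1.800),
    c(-4.60, -3.50, 0.12,  0.12,   0, -1.800),
    c(-2.50,  5.00, 0.80,  0.80,   0,  0.005),   # low-contrast lesions
    c( 2.50,  5.00, 0.80,  0.80,   0,  0.010),
    c( 0.00,  6.80, 0.50,  0.50,   0, -0.010),
    c( 0.00, -3.00, 1.00,  0.60,   0,  0.005),
    c(-2.20, -6.50, 0.40,  0.40,   0,  0.010),
    c( 2.20, -6.50, 0.30,  0.30,   0,  0.010)
  )
  colnames(sh) <- c("x", "y", "a", "b", "angle", "density")
  as.data.frame(sh)
}

#' FORBILD-style head phantom slice
#'
#' Ground-truth slice for the few-view reconstruction experiments: a
#' low-contrast head phantom in the FORBILD style, with soft tissue around
#' 1.05, bone at 1.80, air cavities at 0, and fine high-contrast inner-ear
#' structure. At the default 512 x 512 grid with 0.1 cm pixels the head
#' (19.2 x 24 cm) fits the 51.2 cm field of view.
#'
#' @param n grid side in pixels (>= 64 for meaningful structure).
#' @param pixel_size pixel side in cm.
#' @param supersample sub-samples per pixel side passed to
#'   [rasterize_phantom()].
#' @return an [image_grid()].
#' @examples
#' ph <- forbild_head_phantom(n = 128)
#' range(ph$values)
#' @export
forbild_head_phantom <- function(n = 512L, pixel_size = 0.1, supersample = 4L) {
  if (n < 64) stop("`n` must be >= 64 for meaningful head structure",
                   call. = FALSE)
  rasterize_phantom(phantom_spec(forbild_head_shapes(), "forbild-head"),
                    n = n, pixel_size = pixel_size, supersample = supersample)
}

#' Small piecewise-constant test phantoms
#'
#' Fixtures with known analytic properties for unit tests: a centered
#' uniform disc of density 1 (radius 0.4 of the grid width), two unit-density
#' rectangles on a zero background, or a one-pixel checkerboard.
#'
#' @param kind one of `"uniform-disc"`, `"two-rect"`, `"checker"`.
#' @param n grid side in pixels.
#' @param pixel_size pixel side in cm.
#' @return an [image_grid()].
#' @export
make_test_phantom <- function(kind = c("uniform-disc", "two-rect", "checker"),
                              n = 32L, pixel_size = 0.1) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (kind == "uniform-disc") {
    ctr <- pixel_centers(n, pixel_size)
    r2 <- outer(ctr$y^2, ctr$x^2, "+")
    vals <- (r2 <= (0.4 * n * pixel_size)^2) * 1.0
    return(image_grid(vals, pixel_size))
  }
  if (kind == "two-rect") {
    vals <- matrix(0, n, n)
    q <- max(1L, n %/% 4L)
    vals[q:(2 * q), q:(2 * q)] <- 1
    vals[(n - 2 * q):(n - q), (n - 2 * q):(n - q)] <- 1
    return(image_grid(vals, pixel_size))
  }
  vals <- outer(seq_len(n), seq_len(n), function(r, c) (r + c) %% 2)
  image_grid(vals * 1.0, pixel_size)
}
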