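# File formats: raw little-endian float payload (32- or 64-bit) plus a JSON
# metadata sidecar at "<path>.json" describing shape, dtype and provenance.

write_raw_payload <- function(values, path, dtype) {
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = size, endian = "little")
}

read_raw_payload <- function(path, count, dtype) {
  size <- if (dtype == "float32") 4L else 8L
  expected <- count * size
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop("raw payload '", path, "': expected ", expected, " bytes (",
         count, " x ", dtype, "), found ", actual, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = count, size = size, endian = "little")
}

check_fields <- function(meta, fields, what) {
  miss <- setdiff(fields, names(meta))
  if (length(miss))
    stop(what, " sidecar is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Save / load a sinogram as raw floats with a JSON sidecar
#'
#' The payload is a little-endian float array in view-major (row-major)
#' order; the sidecar at `<path>.json` records views, bins, geometry, dtype
#' and any noise provenance. `float64` round-trips exactly; `float32`
#' quantizes once on the first save.
#'
#' @param sino a [sinogram()].
#' @param path payload file path.
#' @param dtype `"float32"` or `"float64"`.
#' @return `save_sinogram` returns `path` invisibly; `load_sinogram` returns
#'   a [sinogram()].
#' @export
save_sinogram <- function(sino, path, dtype = c("float32", "float64")) {
  stopifnot(inherits(sino, "sinogram"))
  dtype <- match.arg(dtype)
  write_raw_payload(as_ray_vector(sino), path, dtype)
  meta <- list(kind = "sinogram", dtype = dtype, byte_order = "little",
               views = sino$geom$views, bins = sino$geom$bins,
               bin_aperture = sino$geom$bin_aperture,
               source_to_axis = sino$geom$source_to_axis,
               fov_radius = sino$geom$fov_radius,
               angles = sino$geom$angles, units = "cm",
               meta = sino$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_sinogram
#' @export
load_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_fields(meta, c("kind", "dtype", "views", "bins", "bin_aperture",
                       "source_to_axis", "angles"), "sinogram")
  if (!identical(meta$kind, "sinogram"))
    stop("sidecar field 'kind' is '", meta$kind, "', expected 'sinogram'",
         call. = FALSE)
  geom <- fan_beam_geometry(bins = meta$bins, bin_aperture = meta$bin_aperture,
                            source_to_axis = meta$source_to_axis,
                            angles = meta$angles,
                            fov_radius = meta$fov_radius %||% 51.1)
  vals <- read_raw_payload(path, geom$views * geom$bins, meta$dtype)
  sinogram(matrix(vals, geom$views, geom$bins, byrow = TRUE), geom,
           meta = as.list(meta$meta))
}

#' Save / load an image as raw floats with a JSON sidecar
#'
#' Row-major little-endian float payload plus a `<path>.json` sidecar with
#' the grid descriptor.
#'
#' @param img an [image_grid()].
#' @param path payload file path.
#' @param dtype `"float32"` or `"float64"`.
#' @return `save_image` returns `path` invisibly; `load_image` returns an
#'   [image_grid()].
#' @export
save_image <- function(img, path, dtype = c("float32", "float64")) {
  stopifnot(inherits(img, "image_grid"))
  dtype <- match.arg(dtype)
  write_raw_payload(as_pixel_vector(img), path, dtype)
  meta <- list(kind = "image", dtype = dtype, byte_order = "little",
               n = img$n, pixel_size = img$pixel_size, units = "cm",
               order = "row-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_fields(meta, c("kind", "dtype", "n", "pixel_size"), "image")
  if (!identical(meta$kind, "image"))
    stop("sidecar field 'kind' is '", meta$kind, "', expected 'image'",
         call. = FALSE)
  vals <- read_raw_payload(path, meta$n^2, meta$dtype)
  image_grid(vals, pixel_size = meta$pixel_size, n = meta$n)
}

#' Write a window/level 16-bit PNG for visual inspection
#'
#' Presentation-only export: densities are clipped to `window` and mapped
#' linearly to gray. Metrics are always computed on the raw floats, never on
#' this rendering.
#'
#' @param img an [image_grid()].
#' @param path output PNG path.
#' @param window display window `c(low, high)` in density units; the
#'   conventional soft-tissue window for the head slice is `c(1.03, 1.08)`.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path, window = c(1.03, 1.08)) {
  stopifnot(inherits(img, "image_grid"))
  v <- (img$values - window[1]) / (window[2] - window[1])
  v <- pmin(pmax(v, 0), 1)
  png::writePNG(v, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate an experiment configuration file
#'
#' Reads a YAML (or JSON) configuration and validates it into an
#' [experiment_spec()]. Validation errors name the offending field.
#'
#' @param path configuration file.
#' @return an `experiment_spec`.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  algs <- lapply(cfg$algorithms, function(a) {
    do.call(recon_config, a)
  })
  experiment_spec(
    n = cfg$n %||% 512L,
    pixel_size = cfg$pixel_size %||% 0.1,
    views = cfg$views %||% 40L,
    bins = cfg$bins %||% 1025L,
    bin_aperture = cfg$bin_aperture %||% 0.05,
    source_to_axis = cfg$source_to_axis %||% 293.1,
    noise_percent = cfg$noise_percent %||% 0,
    noise_seed = cfg$noise_seed %||% NULL,
    algorithms = algs,
    iterations = cfg$iterations %||% 400L,
    checkpoints = cfg$checkpoints %||% NULL
  )
}

#' Save an experiment configuration as YAML
#' @param spec an [experiment_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(spec, path) {
  stopifnot(inherits(spec, "experiment_spec"))
  out <- unclass(spec)
  out$algorithms <- lapply(spec$algorithms, function(a) {
    a <- unclass(a)
    a[!vapply(a, is.null, logical(1))]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
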