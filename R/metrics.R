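# shared coercion/validation for the image-quality metrics
metric_values <- function(f, truth, roi = NULL) {
  fv <- if (inherits(f, "image_grid")) f$values else as.matrix(f)
  tv <- if (inherits(truth, "image_grid")) truth$values else as.matrix(truth)
  if (!all(dim(fv) == dim(tv)))
    stop("reconstruction and truth have different shapes", call. = FALSE)
  if (is.null(roi)) roi <- rep(TRUE, length(tv))
  list(f = fv[roi], t = tv[roi], peak = max(tv))
}

#' Root-mean-square error
#'
#' `sqrt(mean((f - truth)^2))` over the region of interest (default: whole
#' image).
#'
#' @param f reconstructed [image_grid()] or matrix.
#' @param truth ground-truth image, same shape.
#' @param roi optional logical mask or index vector selecting the region of
#'   interest.
#' @return scalar RMSE in density units.
#' @export
rmse <- function(f, truth, roi = NULL) {
  v <- metric_values(f, truth, roi)
  sqrt(mean((v$f - v$t)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max(truth) / rmse(f, truth))` in dB, using the maximum
#' density of the ground-truth phantom as the peak.
#'
#' @inheritParams rmse
#' @return scalar PSNR in dB; `Inf` (with a message) for a perfect match.
#' @export
psnr <- function(f, truth, roi = NULL) {
  v <- metric_values(f, truth, roi)
  r <- sqrt(mean((v$f - v$t)^2))
  if (r == 0) {
    message("perfect match: RMSE is 0, PSNR is infinite")
    return(Inf)
  }
  20 * log10(v$peak / r)
}

#' Normalized root-mean-square distance
#'
#' `sqrt(sum((f - truth)^2) / sum((truth - mean(truth))^2))` over the ROI;
#' equals 1 for a uniform image with the correct average density, and is
#' dominated by a few large errors.
#'
#' @inheritParams rmse
#' @return scalar NRMSD (dimensionless).
#' @export
nrmsd <- function(f, truth, roi = NULL) {
  v <- metric_values(f, truth, roi)
  den <- sum((v$t - mean(v$t))^2)
  if (den == 0)
    stop("truth is constant over the ROI; NRMSD undefined", call. = FALSE)
  sqrt(sum((v$f - v$t)^2) / den)
}

#' Normalized mean absolute distance
#'
#' `sum(|f - truth|) / sum(|truth|)` over the ROI; equals 1 for an all-zero
#' reconstruction, and emphasizes many small errors over a few large ones.
#'
#' @inheritParams rmse
#' @return scalar NMAD (dimensionless).
#' @export
nmad <- function(f, truth, roi = NULL) {
  v <- metric_values(f, truth, roi)
  den <- sum(abs(v$t))
  if (den == 0)
    stop("truth is zero over the ROI; NMAD undefined", call. = FALSE)
  sum(abs(v$f - v$t)) / den
}

#' All four image-quality metrics at once
#'
#' @inheritParams rmse
#' @return data frame with one row: `rmse`, `psnr`, `nrmsd`, `nmad`.
#' @export
quality_metrics <- function(f, truth, roi = NULL) {
  data.frame(rmse = rmse(f, truth, roi),
             psnr = suppressMessages(psnr(f, truth, roi)),
             nrmsd = nrmsd(f, truth, roi),
             nmad = nmad(f, truth, roi))
}

#' Extract a 1D profile from an image
#'
#' Ordered pixel values along one row or column, with 1-based indices (so
#' "row 240, columns 200 to 300" returns 101 values).
#'
#' @param image an [image_grid()] or matrix.
#' @param axis `"row"` for a horizontal profile or `"column"` for a
#'   vertical one.
#' @param index 1-based row (or column) number.
#' @param from,to 1-based inclusive span along the profile.
#' @return numeric vector of length `to - from + 1`.
#' @export
extract_profile <- function(image, axis = c("row", "column"), index, from, to) {
  axis <- match.arg(axis)
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  n_along <- if (axis == "row") ncol(v) else nrow(v)
  n_across <- if (axis == "row") nrow(v) else ncol(v)
  if (index < 1 || index > n_across)
    stop("`index` out of range 1..", n_across, call. = FALSE)
  if (from < 1 || to > n_along || from > to)
    stop("profile span must satisfy 1 <= from <= to <= ", n_along,
         call. = FALSE)
  if (axis == "row") v[index, from:to] else v[from:to, index]
}
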