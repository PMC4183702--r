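#' Partial gradient fields of an image
#'
#' The four first-order difference fields used by the total-difference
#' regularizers: horizontal `d1(i,j) = f(i,j) - f(i,j-1)`, vertical
#' `d2(i,j) = f(i,j) - f(i-1,j)`, and the two diagonals
#' `d3(i,j) = f(i,j) - f(i-1,j-1)` and `d4(i,j) = f(i,j) - f(i-1,j+1)`.
#' Differences that would reference a pixel outside the grid are 0.
#'
#' @param image an [image_grid()] (or plain matrix), side >= 2.
#' @return list with matrices `d1`, `d2`, `d3`, `d4`, same shape as the
#'   image.
#' @export
partial_gradients <- function(image) {
  f <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  nr <- nrow(f); nc <- ncol(f)
  if (nr < 2 || nc < 2) stop("image side must be >= 2", call. = FALSE)
  d1 <- d2 <- d3 <- d4 <- matrix(0, nr, nc)
  d1[, 2:nc] <- f[, 2:nc] - f[, 1:(nc - 1)]
  d2[2:nr, ] <- f[2:nr, ] - f[1:(nr - 1), ]
  d3[2:nr, 2:nc] <- f[2:nr, 2:nc] - f[1:(nr - 1), 1:(nc - 1)]
  d4[2:nr, 1:(nc - 1)] <- f[2:nr, 1:(nc - 1)] - f[1:(nr - 1), 2:nc]
  list(d1 = d1, d2 = d2, d3 = d3, d4 = d4)
}

#' Total difference (TD) of an image
#'
#' Anisotropic L1 measure of the horizontal and vertical differences,
#' `sum(|d1| + |d2|)` — the computationally convenient surrogate for total
#' variation used by the TD-regularized reconstruction.
#'
#' @param image an [image_grid()] or matrix.
#' @return scalar TD value.
#' @export
td_measure <- function(image) {
  g <- partial_gradients(image)
  sum(abs(g$d1)) + sum(abs(g$d2))
}

#' Weighted total difference (WTD) of an image
#'
#' `sum(|d1| + |d2|) + alpha * sum(|d3| + |d4|)`: the horizontal/vertical
#' terms measure gradient sparsity, the alpha-weighted diagonal terms measure
#' directional gradient continuity. `alpha = 0` recovers the plain TD.
#'
#' @param image an [image_grid()] or matrix.
#' @param alpha nonnegative diagonal weight (default 1, penalizing sparsity
#'   and continuity equally).
#' @return scalar WTD value.
#' @export
wtd_measure <- function(image, alpha = 1) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  g <- partial_gradients(image)
  sum(abs(g$d1)) + sum(abs(g$d2)) + alpha * (sum(abs(g$d3)) + sum(abs(g$d4)))
}

#' Soft-threshold (shrinkage) function
#'
#' `S_w(x) = sign(x) * max(|x| - w, 0)`, applied elementwise.
#'
#' @param x numeric vector or matrix.
#' @param w nonnegative threshold.
#' @return shrunk values, same shape as `x`.
#' @examples
#' soft_threshold(c(-5, 1, 5), 2)  # -3 0 3
#' @export
soft_threshold <- function(x, w) {
  if (length(w) != 1L || w < 0) stop("`w` must be a single value >= 0",
                                     call. = FALSE)
  sign(x) * pmax(abs(x) - w, 0)
}

#' Soft-threshold filtering step (pseudo-inverse of the WTD)
#'
#' One filtering pass that reduces the weighted total difference of an
#' image. For every pixel, each in-grid neighbor n (4 axial with weight 1,
#' 4 diagonal with weight `alpha`) proposes the candidate
#' `g_n = f_n + S_w(f_ij - f_n)` — the center value with its difference to
#' that neighbor shrunk by `w` — and the output pixel is the weighted mean
#' `[sum_axial g_n + alpha * sum_diag g_n] / (4 + 4 alpha)`, with the
#' normalizer reduced to the weights of the neighbors actually present at
#' the borders. `w = 0` is the identity; `alpha = 0` is the 4-neighbor TD
#' filtering; `w -> Inf` tends to the alpha-weighted 8-neighborhood mean.
#'
#' @param image an [image_grid()] (side >= 3) or matrix.
#' @param w nonnegative soft threshold (density units).
#' @param alpha nonnegative diagonal-neighbor weight.
#' @return filtered image, same class as the input.
#' @export
stf_filter_step <- function(image, w, alpha = 1) {
  if (w < 0) stop("`w` must be >= 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  f <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  if (nrow(f) < 3 || ncol(f) < 3)
    stop("image side must be >= 3 for the filtering step", call. = FALSE)
  out <- cpp_stf_filter(f, w, alpha)
  if (inherits(image, "image_grid"))
    image_grid(out, pixel_size = image$pixel_size)
  else out
}

#' Geometric soft-threshold schedule
#'
#' The decreasing threshold sequence `w_k = w0 * decay^k` used by the
#' filtering step across iterations (k starting at 0).
#'
#' @param w0 initial threshold; default 0.02, on the scale of the phantom's
#'   soft-tissue contrast.
#' @param decay per-iteration geometric factor in (0, 1].
#' @param k iteration indices (0-based).
#' @return thresholds `w_k`.
#' @export
threshold_schedule <- function(w0 = 0.02, decay = 0.995, k = 0) {
  if (w0 < 0 || decay <= 0 || decay > 1)
    stop("need w0 >= 0 and decay in (0, 1]", call. = FALSE)
  w0 * decay^k
}
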