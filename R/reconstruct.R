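#' Reconstruction configuration
#'
#' Algorithm choice and tuning parameters for [reconstruct()].
#' `"sart"` runs plain SART sweeps; `"tdm-stf"` interleaves SART with the
#' total-difference soft-threshold filtering (equivalent to `"wtdm-stf"` with
#' `alpha = 0`); `"wtdm-stf"` adds the alpha-weighted diagonal terms and is
#' the weighted-total-difference algorithm.
#'
#' @param algorithm one of `"sart"`, `"tdm-stf"`, `"wtdm-stf"`.
#' @param lambda SART relaxation parameter, in (0, 2); default 1.
#' @param alpha diagonal weight of the WTD; default 1 (ignored for
#'   `"sart"`; forced to 0 for `"tdm-stf"`).
#' @param w0 initial soft threshold of the geometric schedule; default 0.02.
#' @param decay geometric threshold decay per iteration; default 0.995.
#' @param max_iterations stopping rule: number of outer iterations; default
#'   400.
#' @param nonnegativity clamp the image to be nonnegative after each
#'   iteration (off by default).
#' @param sart_mode `"sequential"` view-by-view sweeps in angle order, or
#'   `"simultaneous"` one normalized correction from all views.
#' @param fista_restart reset the momentum when the sweep residual
#'   increases (off by default; plain acceleration).
#' @param stf_factor multiplier applied to the schedule threshold inside the
#'   shrinkage (default 1).
#' @param seed recorded for provenance of any stochastic input.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(algorithm = c("wtdm-stf", "tdm-stf", "sart"),
                         lambda = 1.0, alpha = 1.0, w0 = 0.02, decay = 0.995,
                         max_iterations = 400L, nonnegativity = FALSE,
                         sart_mode = c("sequential", "simultaneous"),
                         fista_restart = FALSE, stf_factor = 1.0,
                         seed = NULL) {
  algorithm <- match.arg(algorithm)
  sart_mode <- match.arg(sart_mode)
  if (lambda <= 0 || lambda >= 2)
    stop("`lambda` must lie in (0, 2)", call. = FALSE)
  if (max_iterations < 0) stop("`max_iterations` must be >= 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (algorithm == "tdm-stf") alpha <- 0
  structure(list(algorithm = algorithm, lambda = lambda, alpha = alpha,
                 w0 = w0, decay = decay,
                 max_iterations = as.integer(max_iterations),
                 nonnegativity = nonnegativity, sart_mode = sart_mode,
                 fista_restart = fista_restart, stf_factor = stf_factor,
                 seed = seed),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon_config> %s: lambda=%.3g alpha=%.3g w0=%.3g decay=%.4g iters=%d\n",
              x$algorithm, x$lambda, x$alpha, x$w0, x$decay, x$max_iterations))
  invisible(x)
}

#' One SART pass over all views
#'
#' Relaxed algebraic update: for each view in angle order, every pixel j
#' receives `lambda * [sum_{i in view} a_ij (p_i - <a_i, f>) / row_sum_i] /
#' col_sum_j` where the column sum runs over the rays of that view; rays and
#' pixels with zero weight sums are skipped.
#'
#' @param A a [system_matrix()].
#' @param p a [sinogram()] (or ray-ordered numeric vector).
#' @param f current image as an [image_grid()] (or row-major vector).
#' @param lambda relaxation parameter; values outside (0, 2) trigger a
#'   warning.
#' @param mode `"sequential"` or `"simultaneous"` (see [recon_config()]).
#' @return list with `image` (same class as `f`) and `residual`, the root
#'   sum of squared ray discrepancies accumulated as the sweep visited each
#'   ray.
#' @export
sart_sweep <- function(A, p, f, lambda = 1.0,
                       mode = c("sequential", "simultaneous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "system_matrix"))
  pv <- if (inherits(p, "sinogram")) as_ray_vector(p) else as.numeric(p)
  if (anyNA(pv)) stop("projection data contain NA/NaN", call. = FALSE)
  if (length(pv) != A$M)
    stop("projection vector length ", length(pv), " != M = ", A$M,
         call. = FALSE)
  was_grid <- inherits(f, "image_grid")
  fv <- if (was_grid) as_pixel_vector(f) else as.numeric(f)
  if (length(fv) != A$N)
    stop("image length ", length(fv), " != N = ", A$N, call. = FALSE)
  if (lambda <= 0 || lambda >= 2)
    warning("relaxation parameter lambda = ", lambda,
            " lies outside the usual (0, 2) range")
  out <- cpp_sart_sweep(A$row_ptr, A$col_ind, A$val, pv, fv, lambda,
                        A$geom$bins, A$geom$views, A$row_sums,
                        A$view_col_sums, A$col_sums,
                        if (mode == "simultaneous") 1L else 0L)
  img <- if (was_grid) image_grid(out$f, pixel_size = A$pixel_size, n = A$n)
         else out$f
  list(image = img, residual = out$residual)
}

#' FISTA momentum step
#'
#' The acceleration recurrence `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2` and
#' the extrapolated iterate `x_k + ((t_k - 1)/t_{k+1}) (x_k - x_km1)`.
#'
#' @param t_k current momentum scalar (>= 1).
#' @param x_k current iterate (numeric vector/matrix or [image_grid()]).
#' @param x_km1 previous iterate, same shape.
#' @return list with `t_next` and `image` (the extrapolated iterate, same
#'   class as `x_k`).
#' @export
fista_step <- function(t_k, x_k, x_km1) {
  if (t_k < 1) stop("`t_k` must be >= 1", call. = FALSE)
  t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
  beta <- (t_k - 1) / t_next
  if (inherits(x_k, "image_grid")) {
    v <- x_k$values + beta * (x_k$values - x_km1$values)
    return(list(t_next = t_next, image = image_grid(v, x_k$pixel_size)))
  }
  list(t_next = t_next, image = x_k + beta * (x_k - x_km1))
}

#' Iterative few-view reconstruction
#'
#' Runs the three-stage alternating loop from a zero initial image: (1) the
#' SART data-constraint sweep; (2) for the STF algorithms, the
#' soft-threshold filtering step that reduces the (weighted) total
#' difference, with threshold `w_k = w0 * decay^k`; (3) the FISTA momentum
#' extrapolation. Plain `"sart"` skips stages (2)-(3). The loop stops after
#' `max_iterations` outer iterations.
#'
#' @param A a [system_matrix()].
#' @param p a [sinogram()] of measured ray sums.
#' @param config a [recon_config()].
#' @param truth optional ground-truth [image_grid()]; when supplied the
#'   per-iteration trace carries RMSE/PSNR/NRMSD/NMAD against it.
#' @param checkpoints optional ascending iteration numbers at which to
#'   snapshot the image.
#' @return an object of class `ct_reconstruction`: `image` (final
#'   [image_grid()]), `trace` (data frame, one row per iteration: sweep
#'   residual and any truth metrics), `iterations`, `config`, and
#'   `checkpoints` (named list of snapshot images).
#' @export
reconstruct <- function(A, p, config = recon_config(), truth = NULL,
                        checkpoints = NULL) {
  stopifnot(inherits(A, "system_matrix"), inherits(config, "recon_config"))
  pv <- if (inherits(p, "sinogram")) as_ray_vector(p) else as.numeric(p)
  if (length(pv) != A$M)
    stop("projection vector length ", length(pv), " != M = ", A$M,
         call. = FALSE)
  if (!is.null(checkpoints)) {
    checkpoints <- as.integer(checkpoints)
    if (is.unsorted(checkpoints) || any(checkpoints > config$max_iterations) ||
        any(checkpoints < 1))
      stop("`checkpoints` must be ascending and within 1..max_iterations",
           call. = FALSE)
  }
  truth_v <- if (!is.null(truth)) as_pixel_vector(truth) else NULL
  n <- A$n
  use_stf <- config$algorithm != "sart"
  alpha <- config$alpha

  f <- rep(0, A$N)          # initial image is zero
  x_prev <- f
  t_k <- 1
  prev_res <- Inf
  iters <- config$max_iterations
  trace <- list(iteration = integer(iters), residual = numeric(iters))
  if (!is.null(truth_v))
    trace <- c(trace, list(rmse = numeric(iters), psnr = numeric(iters),
                           nrmsd = numeric(iters), nmad = numeric(iters)))
  snaps <- list()

  for (k in seq_len(iters)) {
    sw <- sart_sweep(A, pv, f, lambda = config$lambda, mode = config$sart_mode)
    x_k <- sw$image
    if (use_stf) {
      w_k <- config$stf_factor * threshold_schedule(config$w0, config$decay,
                                                    k - 1)
      fm <- cpp_stf_filter(matrix(x_k, n, n, byrow = TRUE), w_k, alpha)
      x_k <- as.vector(t(fm))
    }
    if (config$nonnegativity) x_k <- pmax(x_k, 0)
    if (use_stf) {
      if (config$fista_restart && sw$residual > prev_res) t_k <- 1
      fs <- fista_step(t_k, x_k, x_prev)
      f <- fs$image
      t_k <- fs$t_next
    } else {
      f <- x_k
    }
    x_prev <- x_k
    prev_res <- sw$residual

    trace$iteration[k] <- k
    trace$residual[k] <- sw$residual
    if (!is.null(truth_v)) {
      e <- x_k - truth_v
      trace$rmse[k] <- sqrt(mean(e^2))
      trace$psnr[k] <- if (trace$rmse[k] > 0)
        20 * log10(max(truth_v) / trace$rmse[k]) else Inf
      mu <- mean(truth_v)
      trace$nrmsd[k] <- sqrt(sum(e^2) / sum((truth_v - mu)^2))
      trace$nmad[k] <- sum(abs(e)) / sum(abs(truth_v))
    }
    if (!is.null(checkpoints) && k %in% checkpoints)
      snaps[[as.character(k)]] <- image_grid(x_prev, pixel_size = A$pixel_size,
                                             n = n)
  }
  # report the last proximal iterate, not the extrapolated one
  final <- image_grid(if (iters > 0) x_prev else f,
                      pixel_size = A$pixel_size, n = n)
  structure(list(image = final, trace = as.data.frame(trace),
                 iterations = iters, config = config, checkpoints = snaps),
            class = "ct_reconstruction")
}

#' @export
print.ct_reconstruction <- function(x, ...) {
  cat(sprintf("<ct_reconstruction> %s, %d iterations\n",
              x$config$algorithm, x$iterations))
  if (x$iterations > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final sweep residual %.6g", last$residual))
    if (!is.null(x$trace$rmse))
      cat(sprintf("; RMSE %.6g, PSNR %.4f dB", last$rmse, last$psnr))
    cat("\n")
  }
  invisible(x)
}
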