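#' Simulate noise-free projection data
#'
#' The noise-free sinogram is the system matrix applied to the discrete
#' phantom, `p = A f*` — the same forward model used inside the
#' reconstruction loop, so the simulated data are exactly consistent with
#' the imaging model (the usual inverse-crime protocol for algorithm
#' comparisons).
#'
#' @param phantom ground-truth [image_grid()].
#' @param A a [system_matrix()].
#' @return a [sinogram()] with provenance metadata.
#' @export
simulate_projections <- function(phantom, A) {
  sino <- forward_project(A, phantom)
  sino$meta$source <- "simulate_projections"
  sino$meta$noise <- list(percent_of_max = 0)
  sino
}

#' Add zero-mean Gaussian measurement noise
#'
#' Adds i.i.d. Gaussian noise with mean 0 and standard deviation
#' `percent_of_max` times the global maximum of the sinogram (e.g. 5e-4 for
#' a standard deviation of 0.05% of the maximum ray sum). Reproducible for a
#' fixed seed; the RNG algorithm is recorded in the metadata. Values are not
#' clipped to be nonnegative unless `clip_negative = TRUE`.
#'
#' @param sino a [sinogram()].
#' @param percent_of_max noise level as a fraction of the sinogram maximum
#'   (>= 0).
#' @param seed optional integer RNG seed; the global RNG state is restored
#'   afterwards.
#' @param clip_negative clamp negative noisy ray sums to zero.
#' @return a [sinogram()] with the noise spec recorded in `meta`.
#' @export
add_gaussian_noise <- function(sino, percent_of_max = 5e-4, seed = NULL,
                               clip_negative = FALSE) {
  stopifnot(inherits(sino, "sinogram"))
  if (percent_of_max < 0)
    stop("`percent_of_max` must be >= 0", call. = FALSE)
  if (length(sino$values) == 0) stop("empty sinogram", call. = FALSE)
  sigma <- percent_of_max * max(sino$values)
  if (percent_of_max > 0 && sigma == 0) {
    warning("sinogram maximum is 0; no noise added")
    return(sino)
  }
  out <- sino
  if (sigma > 0) {
    eps <- with_seed(seed, stats::rnorm(length(sino$values), mean = 0,
                                        sd = sigma))
    out$values <- sino$values + matrix(eps, nrow(sino$values))
    if (clip_negative) out$values <- pmax(out$values, 0)
  }
  out$meta$noise <- list(percent_of_max = percent_of_max, sigma = sigma,
                         mean = 0, seed = seed,
                         rng = RNGkind()[1], clipped = clip_negative)
  out
}

# evaluate `expr` under a temporary RNG seed, restoring the global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
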