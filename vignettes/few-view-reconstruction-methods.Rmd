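---
title: "Few-view fan-beam CT reconstruction with weighted total difference regularization"
author: "fewviewct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-view fan-beam CT reconstruction with weighted total difference regularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sparse angular sampling reduces X-ray dose, but with only a few dozen view
angles the linear system `p = A f` relating the image `f` (N pixels) to the
measured ray sums `p` (M = views x bins) is badly underdetermined, and
analytic reconstruction produces severe streak artifacts. The remedy studied
here is compressed-sensing-style iterative reconstruction: alternate a data
constraint (an algebraic update that pulls `A f` toward `p`) with a proximal
filtering step that reduces a sparsity-promoting regularizer of the image.

`fewviewct` implements this pipeline end to end — analytic phantom,
ray-driven system matrix, sinogram simulation with Gaussian measurement
noise, three reconstruction algorithms, and the standard image-quality
metrics — with no external data.

## Regularizers: TD and WTD

With the four first-order difference fields (horizontal `d1`, vertical `d2`,
diagonals `d3`, `d4`; out-of-grid references give 0):

* **Total difference (TD)**: `sum(|d1| + |d2|)`, the anisotropic L1
  surrogate of total variation. It promotes sparse horizontal/vertical
  gradients, and is therefore biased toward axis-aligned edges.
* **Weighted total difference (WTD)**:
  `sum(|d1| + |d2|) + alpha * sum(|d3| + |d4|)`. The diagonal terms reward
  directional continuity of the gradient field, so oblique and curved edges
  are preserved, not staircased. `alpha = 1` (the default) penalizes
  gradient sparsity and gradient continuity equally; `alpha = 0` recovers
  TD exactly.

## The three-stage loop

`reconstruct()` runs, from a zero initial image:

1. **SART sweep** (`sart_sweep()`): for each view in angle order, every
   pixel j receives
   `lambda * [sum_{i in view} a_ij (p_i - <a_i, f>) / row_sum_i] / col_sum_j`,
   with the column sum taken over that view's rays. Rays or pixels with zero
   weight sums are skipped. `lambda = 1` by default (values in (0, 2) are
   accepted); a simultaneous all-views variant is available behind
   `sart_mode = "simultaneous"`.
2. **Soft-threshold filtering** (`stf_filter_step()`), skipped for plain
   SART: each in-grid neighbor n of a pixel (4 axial with weight 1, 4
   diagonal with weight `alpha`) proposes `g_n = f_n + S_w(f_ij - f_n)`
   with `S_w(x) = sign(x) max(|x| - w, 0)`, and the pixel becomes the
   weighted mean of the candidates, `[sum_ax g + alpha sum_diag g] /
   (4 + 4 alpha)` (the normalizer shrinks at borders to the neighbors
   actually present). This is the pseudo-inverse filtering form of the TD
   literature generalized by the diagonal weight: one pass provably leaves
   constants fixed, is the identity at `w = 0`, and empirically reduces the
   WTD on piecewise-constant images (a property the test suite asserts for
   the first 10 applications).
3. **FISTA acceleration** (`fista_step()`): the standard momentum
   recurrence `t_{k+1} = (1 + sqrt(1 + 4 t_k^2))/2` with extrapolation
   `x_k + ((t_k - 1)/t_{k+1})(x_k - x_{k-1})`; the extrapolated iterate
   enters the next sweep, and the reported image is always the last
   filtered (proximal) iterate. Momentum restart on residual increase is
   available but off by default, matching the plain acceleration scheme.

The stopping rule is a fixed iteration budget (400 by default). TDM-STF is
implemented *as* WTDM-STF with `alpha = 0` — the two are bit-identical by
construction, which the tests check.

### The threshold schedule

The filtering threshold decays geometrically, `w_k = w0 * decay^k`, with
`w0 = 0.02` (the scale of the phantom's soft-tissue contrast: the brain
structures span about 0.005–0.02 density units) and `decay = 0.995`, so
that filtering is strong while streaks dominate and fades as data
consistency takes over. Both constants are exposed in `recon_config()`.
Geometric decay is the standard realization of the decreasing-threshold
schemes in the shrinkage literature; the relative algorithm comparisons are
stable across nearby schedules, although absolute error levels move
substantially with `decay` (slower decay leaves a residual filtering bias,
faster decay converges both STF algorithms closer to the exact solution and
narrows the gap between them).

## Geometry and projector

The scan is a circular fan-beam acquisition: source at distance 293.1 cm
from the rotation axis, view angles uniform over the full circle starting
at 0 (`view_angles()`), and a *virtual equi-distance detector* — a
uniformly sampled line through the rotation axis perpendicular to the
source direction, 1025 bins of 0.05 cm in the reference setup (span
51.25 cm, covering the 51.2 cm field of view; the nominal 51.1 cm
scan-field radius is kept as a config descriptor). One ray is traced per
bin center, and the system-matrix weight `a_ij` is the exact intersection
length of ray i with pixel j, computed by Siddon-style parametric
traversal. Design points:

* Rays that miss the grid keep empty rows, so M is always views x bins.
* Chord conservation (`sum_j a_ij` equals the analytic chord of the ray in
  the grid box) and entrywise agreement with an independent
  per-pixel clipping oracle on small grids are asserted in the tests at
  1e-9.
* Coordinates: physical origin at the grid center, x rightward, y upward,
  row 1 on top; pixel indices row-major. Angles are radians internally.
* A ray lying exactly on a shared pixel edge is attributed to one of the
  two adjacent pixel rows (a measure-zero event; the convention is stable
  and deterministic).

## Phantom

`forbild_head_phantom()` rasterizes a FORBILD-style low-contrast head
slice: cranium ellipse (9.6 x 12 cm, bone density 1.80), brain interior at
1.05, a frontal-sinus air cavity, CSF ventricles at 1.045, petrous bones at
1.80 carrying a row of small air drill holes (the high-contrast fine
inner-ear structure that generates the dominant streaks), and several
low-contrast lesions between 1.040 and 1.060 — all inside the conventional
[1.03, 1.08] display window. The geometric parameters are embedded
constants transcribed from the public FORBILD head design; the fine
inner-ear detail is a simplified stand-in, which shifts absolute error
levels slightly but not the relative algorithm comparisons. Rasterization
anti-aliases ellipse boundaries with 4 x 4 supersampling per pixel;
interior pixels are exact, and the same rasterization serves as ground
truth and as input to data simulation (the deliberate inverse-crime
protocol of simulation studies: `p = A f*` uses the same discrete model the
reconstruction inverts, so noise-free data are exactly consistent).

## Noise model

`add_gaussian_noise()` adds i.i.d. zero-mean Gaussian noise with standard
deviation equal to 0.05% of the global sinogram maximum (`percent_of_max =
5e-4`). The maximum is global, not per view; values are not clipped to
nonnegative (a flag exists); the RNG seed and algorithm are recorded in the
sinogram metadata so noisy runs replay exactly. What this emulates is
small additive electronic/quantum noise on line integrals; it does not
model Poisson photon statistics, detector blur, scatter, beam hardening or
motion — so passing tests demonstrate algorithmic behavior under the
stated simulation protocol, not clinical performance.

## Metrics

`rmse()`, `psnr()` (peak = maximum truth density, so the skull's 1.8),
`nrmsd()` (unit value for a uniform image at the correct mean; sensitive to
few large errors) and `nmad()` (unit value for an all-zero image; sensitive
to many small errors), all over a configurable ROI defaulting to the whole
image. Profile extraction (`extract_profile()`) uses 1-based inclusive
indices, so "row 240, columns 200–300" returns 101 values.

## Problem sizes and numerical choices

The reference study runs at full scale: 512 x 512 phantom, 40 views x
1025 bins (M = 41 000, about 25 million stored intersection lengths), 400
iterations per algorithm; a single reconstruction takes on the order of two
minutes on one CPU and the system matrix builds in a few seconds. The test
suite exercises the same pipeline at 128 x 128 / 257 bins (pixel size
0.4 cm keeps the physical field of view), where 150 iterations complete in
a few seconds, and validates kernels against dense oracles on grids of at
most 16 x 16. Degenerate inputs are rejected with explicit messages
(zero-length rays, shape mismatches, constant-truth NRMSD, all-zero-truth
NMAD); ties in ray/pixel incidence are resolved deterministically; the
memory guard in `system_matrix()` aborts on an estimated nonzero count
beyond a configurable cap rather than exhausting memory.

## Known limitations

* Equi-angular detectors, cone-beam and limited-angle geometries are out of
  scope; the projector is 2D fan-beam only.
* The filtering step is the pseudo-inverse construction described above;
  other readings of the diagonal-weighted proximal step exist, and the
  operator is isolated behind `stf_filter_step()` so an alternative can be
  swapped in.
* Absolute error levels depend on the exact phantom slice, the relaxation
  parameter and the threshold schedule; the robust quantities are the
  relative WTD-over-TD gains and the SART/TDM/WTDM quality ordering.
* The nonnegativity clamp is off by default (densities are physically
  nonnegative, but the reference loop does not clamp).
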