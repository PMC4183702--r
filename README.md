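# fewviewct

Iterative image reconstruction for **few-view fan-beam computed
tomography** in R. When a CT scan uses only a few dozen view angles (to cut
radiation dose), the reconstruction problem `p = A f` is severely
underdetermined and classical algebraic methods leave strong streak
artifacts. `fewviewct` implements and compares three reconstruction
algorithms on a self-contained simulation study — no external data:

* **SART** — the simultaneous algebraic reconstruction technique: relaxed
  view-by-view updates
  `f_j <- f_j + λ Σ_{i∈view} a_ij (p_i − ⟨a_i, f⟩)/Σ_k a_ik / Σ_{i∈view} a_ij`.
* **TDM-STF** — SART alternated with soft-threshold filtering that reduces
  the *total difference* `TD(f) = Σ(|D1 f| + |D2 f|)`, the anisotropic L1
  surrogate of total variation over horizontal/vertical differences.
* **WTDM-STF** — the same loop driven by the *weighted total difference*
  `WTD(f) = Σ(|D1 f| + |D2 f|) + α Σ(|D3 f| + |D4 f|)`, whose α-weighted
  diagonal terms (α = 1 by default) also enforce directional continuity of
  the gradient field, preserving oblique edges and suppressing streaks.

The filtering step shrinks pixel-neighbor differences with
`S_w(x) = sign(x)·max(|x| − w, 0)` and recombines them through the
pseudo-inverse of the difference operator; a FISTA momentum step
(`t_{k+1} = (1 + √(1+4t_k²))/2`) accelerates the loop. The package also
provides the FORBILD-style low-contrast head phantom, an exact Siddon
ray-driven sparse system matrix for the fan-beam geometry (virtual
equi-distance detector through the rotation axis), Gaussian sinogram noise,
the RMSE / PSNR / NRMSD / NMAD quality metrics, 1D profile extraction,
raw+JSON file round-tripping, an experiment runner and a small CLI
(`inst/cli/fewviewct.R`).

See `vignettes/few-view-reconstruction-methods.Rmd` for the model,
parameter and design discussion.

## Worked example

A scaled version of the head-slice study (128 × 128 phantom on 0.4 cm
pixels — same 51.2 cm field of view — 40 views, 257 detector bins, 150
iterations):

```r
library(fewviewct)

phantom <- forbild_head_phantom(n = 128, pixel_size = 0.4)
geom <- fan_beam_geometry(views = 40, bins = 257, bin_aperture = 0.2)
A <- system_matrix(geom, phantom)
#> <system_matrix> 10280 x 16384, 1,570,352 stored lengths (40 views x 257 bins)

sino <- simulate_projections(phantom, A)
#> <sinogram> 40 views x 257 bins, range [0, 26.56]

recons <- lapply(c(sart = "sart", `tdm-stf` = "tdm-stf",
                   `wtdm-stf` = "wtdm-stf"), function(alg)
  reconstruct(A, sino, recon_config(alg, max_iterations = 150),
              truth = phantom))

summary <- do.call(rbind, lapply(names(recons), function(a)
  cbind(algorithm = a, quality_metrics(recons[[a]]$image, phantom))))
print(summary, row.names = FALSE, digits = 4)
#>  algorithm     rmse  psnr   nrmsd    nmad
#>       sart 0.067971 28.46 0.16904 0.30696
#>    tdm-stf 0.008766 46.25 0.02180 0.03083
#>   wtdm-stf 0.005221 50.75 0.01299 0.01601
print(gain_table(summary), row.names = FALSE, digits = 4)
#>  metric gain_percent
#>    rmse        40.43
#>    psnr         9.73
#>   nrmsd        40.43
#>    nmad        48.06
```

Reading the numbers: SART alone leaves streak artifacts (RMSE 0.068 in
density units, where soft-tissue contrasts are 0.005–0.02); both filtered
algorithms remove most of the error, and the weighted (diagonal-aware)
regularizer improves on the plain TD version by ~40% in RMSE/NRMSD and
~48% in NMAD at equal iteration count, with a higher PSNR (peak = the
skull's density 1.8). `reconstruct()` also returns a per-iteration trace
(`$trace`) of the sweep residual and, when ground truth is supplied, all
four metrics — the curves separate clearly beyond roughly 100 iterations.

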