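---
title: "Slice-specific z-shim selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-specific z-shim selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zshimtools)
```

## The problem

T2\*-weighted gradient-echo EPI of the cervical spinal cord suffers from
periodic signal dropouts along the rostro-caudal axis: the susceptibility
difference between vertebral bodies and intervertebral disks imposes a B0
gradient along the slice direction that dephases spins across the slice and
attenuates the echo. Because the pattern repeats with the vertebral spacing
(roughly 15 mm), a single global shim cannot remove it — but a brief
slice-specific gradient pulse (a "z-shim") applied before readout can cancel
the local through-slice gradient slice by slice.

The scanner can only apply a discrete set of compensation moments. This
package implements the two automated ways of picking the best moment per
slice, the metrics used to evaluate them, and a physics-based simulator that
makes the whole pipeline testable without scanner data.

## The dephasing model

For an ideal rectangular slice profile of thickness $\Delta z$, a residual
through-slice gradient $G_z$ at echo time $TE$ attenuates the signal by

$$A(G_z) = \left|\,\mathrm{sinc}\!\left(\bar\gamma\, G_z\, TE\, \Delta z\right)\right|,
\qquad \bar\gamma = 42.577\ \mathrm{kHz/mT},$$

with $\mathrm{sinc}(u) = \sin(\pi u)/(\pi u)$. $A(0)=1$, $A$ is even, and the
first null is at $G_z = 1/(\bar\gamma\, TE\, \Delta z)$ — about 0.117 mT/m at
$TE = 40$ ms and $\Delta z = 5$ mm, i.e. comfortably inside the range of
gradients observed near intervertebral junctions. The slice profile of a real
excitation is not perfectly rectangular; a Gaussian-profile variant
($A = \exp(-(\pi u)^2 k)$) is available through
`through_slice_attenuation(profile = "gaussian")` for robustness checks, but
all defaults use the rect model.

```{r attenuation}
p <- acq_params(te = 40, slice_thickness = 5, n_slices = 24)
g <- seq(-0.25, 0.25, length.out = 201)
plot(g, through_slice_attenuation(g, p), type = "l",
     xlab = "residual through-slice gradient (mT/m)", ylab = "attenuation")
abline(v = c(-1, 1) / (42.577 * 0.04 * 5), lty = 2)
```

## The compensation grid

The z-shim sequence offers `n_steps` equidistant compensation values,
symmetric about zero; `n_steps` is required to be odd so an exact "no z-shim"
neutral value exists. The standard protocol grid is 21 steps spanning
$\pm$0.21 mT/m (0.021 mT/m per step, neutral index 11); a coarser 15-step
grid spanning $\pm$4.9 mT/m·ms in moment units (0.7 per step, neutral
index 8) is also used in practice. Since the applied moment is $G_z \cdot TE$
and the sequence scales it with $TE$, a selected index is valid across echo
times; `moment_for_index()` makes the scaling explicit.

Two behaviours of `nearest_index()` are deliberately ours, because the
procedure they implement is under-specified in practice:

* **Ties**: an estimate exactly midway between two grid values rounds toward
  the smaller compensation magnitude. When the estimate is that uncertain,
  the smaller perturbation is the safer setting.
* **Out-of-range estimates** clamp to the end of the grid with a warning
  rather than erroring: the scanner can only apply grid values, and a
  clamped extreme compensation is still the best available one.

## EPI-reference-based selection

A reference scan acquires one EPI volume per grid value. For each slice, the
mean intensity over the cord mask is extracted per volume
(`intensity_matrix()`, a `n_slices × n_steps` matrix — 24 × 21 under the
standard protocol), and the step with the maximum intensity wins
(`select_zshim_epi()`). Exact intensity ties (possible in noiseless
simulation, vanishingly rare in data) reuse the grid's tie rule: smaller
compensation first, then the lower index. Slices whose mask is empty fall
back to the neutral index with a warning instead of failing the run —
fail-safe behaviour matters more than completeness in an online scanner
workflow, and a neutral setting reproduces the uncompensated acquisition.

Cord segmentation itself is out of scope: the mask is an input.
`mean_reference_volume()` exposes the across-step mean image that
segmentation tools are usually run on.

## Field-map-based selection

A field map gives the per-voxel frequency offset $\Delta\nu_0$ (Hz). Two
estimators are implemented:

* `frequency_from_two_echoes()`: the phase difference of two echoes, wrapped
  to $(-\pi, \pi]$, divided by $2\pi\,\Delta TE$ — unambiguous for
  $|\Delta\nu| < 1/(2\Delta TE)$.
* `frequency_from_multiecho()`: per-voxel least-squares slope of the phase
  across many echoes after temporal unwrapping (`unwrap_echo_train()`).
  Unwrapping is per voxel along the echo axis only; with short inter-echo
  spacing (1.3 ms in the motivating acquisition) the per-echo phase advance
  stays below $\pi$ for offsets up to ~385 Hz, so no spatial unwrapping is
  needed. Beyond that limit the echo train aliases, and the estimate is
  wrong by construction — a documented failure mode, not an error.

For selection, the map is smoothed with an isotropic 1 mm Gaussian kernel
(`smooth_fieldmap()`; the kernel is specified in millimetres and divided by
the voxel size per axis, so anisotropic voxels still get an isotropic
physical kernel), then each EPI slice gets an ordinary least-squares fit of
$\Delta\nu$ on $[x, y, z, 1]$ over cord-mask voxels in a slab centred on the
slice (`fit_slicewise_basis()`). The slab is the slice thickness plus a 2 mm
margin per side — 9 mm, i.e. nine 1 mm field-map planes, for a 5 mm slice —
because the extra planes stabilise the through-slice slope estimate.
Coordinates are centred on the slab's mask centroid before fitting; the
choice decorrelates the offset term from the slopes and improves
conditioning, and it does not change the slopes. The fitted $G_z$
(slope$_z$/\(\bar\gamma\): 42.577 Hz/mm per mT/m) is rounded onto the grid
with `nearest_index()`. Slices with fewer than 4 usable voxels or a
rank-deficient design are flagged and fall back to neutral, mirroring the
EPI method's policy. The fit is unweighted: whether voxels should be
weighted (e.g. by magnitude signal) is an open question we resolve by the
simplest defensible choice.

### The histogram variant

Compensating the slab's *mean* through-slice gradient is not always optimal:
a few extreme-gradient voxels near tissue interfaces can pull the mean away
from the value that suits the majority of voxels, losing more signal overall
than they recover. `histogram_gradient()` therefore computes per-voxel
through-slice gradients by finite differences along z (central in the slab
interior, one-sided at the slab edges), histograms them (21 bins over the
observed range by default), and returns the mean of the gradients in the
modal bin and its two neighbours. The bin count and the modal$\pm$1 trimmed
mean are our concrete reading of a method described only loosely in the
field; both are exposed as arguments so users can tighten or relax the
trimming.

## The synthetic-data generator

`simulate_scenario()` builds matched inputs for both methods from one field
specification:

* **Phantom**: a homogeneous cylinder (default radius 4 mm, intensity 100,
  background 10) standing in for the cord cross-section, at 1 mm in-plane
  resolution on a 32 × 32 matrix. Only mask voxels matter downstream, so the
  small matrix sacrifices nothing.
* **Field**: either a sinusoidal through-slice gradient
  $g_z(z) = A \sin(2\pi (z - \phi)/P)$ with period $P = 15$ mm (the
  vertebral periodicity) and default amplitude 0.15 mT/m (between the first
  sinc null and the grid edge, i.e. strong but compensable dropout), or a
  per-slice table mode in which the field is exactly constant-plus-linear
  within each EPI slice. The frequency map is
  $\Delta\nu = \bar\gamma (g_x x + g_y y + \int g_z\,dz) + \nu_0$.
* **Reference stack**: volume $k$ is the phantom times
  $A(g_{\mathrm{true}}(s) - g_k)$ plus i.i.d. Gaussian noise, where
  $g_{\mathrm{true}}$ is the analytic mean of $g_z$ over the slice extent —
  so the EPI-stack ground truth and the field-map fit target coincide by
  construction. Default noise SD 5 at cord intensity 100, i.e. voxel SNR 20,
  a realistic figure for cord EPI. The per-slice optimal indices are
  returned alongside as ground truth.
* **Time series / phases**: volumes under a given selection with optional
  drift and spike volumes; wrapped phase images at arbitrary echo times with
  optional phase noise.

Noise is Gaussian rather than Rician: at the simulated SNRs the two are
nearly indistinguishable, and Gaussianity keeps the estimator tests
analytic. In-plane gradients $g_x, g_y$ enter the field map but not the
simulated EPI intensity — echo-shift physics is out of scope — so
cross-method comparisons on simulated data stay valid by construction.

What the phantom does *not* emulate: respiration-driven dynamic fields,
motion, geometric distortion, partial-volume and CSF effects, and the
gray/white matter structure of a real cord. Passing tests therefore
demonstrate the correctness of the selection arithmetic and estimation
chain under the stated physics, not in-vivo performance.

### Why the sinusoidal and table modes behave differently

In table mode, slice-wise fits recover the per-slice gradients exactly
(up to the 2 mm slab overhang into neighbouring slices, which cancels when
the per-slice gradients vary by at most ~1 step per slice). In sinusoidal
mode with a 15 mm period, the 9 mm slab straddles a substantial fraction of
the period, so the least-squares slope *underestimates* rapid gradient
variation and the field-map method lands within a step or two of the
EPI-based choice rather than exactly on it. This is a faithful reproduction
of the physics that makes field-map-based selection slightly inferior to
reference-scan selection in practice, not an implementation artefact.
Exact-recovery tests accordingly use table-mode fields with on-grid
gradients; sinusoidal fields exercise the realistic regime.

## Evaluation metrics

* `slicewise_mean()` / `profile_summary()`: per-slice cord means; mean,
  sample variance ($n-1$) and coefficient of variation across slices. The
  CV is the scale-free dropout-variability measure; variance is reported
  too for comparability with older work.
* `tsnr_map()` / `censored_tsnr()`: voxelwise temporal mean over sample SD.
  Censoring removes volumes flagged by `detect_outlier_volumes()` — dVARS
  (RMS difference to the previous volume, undefined for the first volume)
  and refRMS (RMS difference to the temporal mean volume), each thresholded
  at its run mean + 2 SD, flags combined by union. Both metrics are
  computed within the cord mask by default (configurable to whole-volume);
  the region choice is a config decision, not a fixed fact of the
  procedure. Exclusion is equivalent to per-volume delta regressors of no
  interest up to degrees-of-freedom bookkeeping, which we accept for
  simplicity.
* `reconstruct_from_reference()`: the "artificial volume" built by taking,
  per slice, the reference volume a selection chose — the standard way to
  compare selections without reacquiring data.
* `step_difference_profile()`: per-slice |index − neutral| and the fractions
  of slices at step differences 0, 1, 2, 3, >3.
* `percent_difference_ci()`: paired percentage difference with a percentile
  bootstrap CI over units. Percentile (not BCa) because nothing stronger is
  warranted by the use case; with ~24 paired units, empirical coverage of
  the 95% interval sits slightly below nominal — near 93–95% — which the acceptance
  checks account for.

## Worked example

```{r example}
grid <- zshim_grid(21, 0.21)
params <- acq_params(te = 40, slice_thickness = 5, n_slices = 24)
field <- field_spec(gz_amplitude = 0.15, period_mm = 15)
sc <- simulate_scenario(grid, params, field,
                        noise = noise_spec(sigma_image = 5),
                        sigma_dnu_hz = 5, seed = 42)
sel_epi <- select_zshim_epi(sc$stack, mask = sc$epi_mask)
sel_fm  <- zshim_from_fieldmap(sc$fm, sc$fm_mask, grid, params)
rbind(truth = sc$optimal_indices,
      epi   = sel_epi$indices,
      fm    = sel_fm$indices)
summary(sel_epi)
```

## Numerical and scale choices

Default problem sizes — 32 × 32 × 24 phantoms, 100-replicate noise studies,
1000-replicate bootstrap coverage checks with 1000 resamples each — were
chosen so that every property of interest is measured with comfortable
Monte-Carlo margin while a full run of the suite stays in the tens of
seconds; all sizes are arguments, so heavier studies are one call away.
Seeds are explicit everywhere randomness exists, and all generators are
bit-reproducible given (spec, seed).

## Known limitations

* Field maps must already be resampled onto a grid whose third axis is the
  EPI slice axis; registration and resampling are upstream concerns, and a
  mismatch is a documented precondition, not a detected error.
* Odd/even echo phase corrections for bipolar multi-echo acquisitions are
  assumed done upstream (vendor reconstruction); simulated phases carry no
  odd/even offset.
* The histogram estimator's knobs are defensible defaults, not validated
  optima.
* tSNR gains on the phantom quantify the dephasing model, not BOLD
  sensitivity in vivo.
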