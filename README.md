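# zshimtools

Automated slice-specific z-shim selection for gradient-echo EPI of the human
spinal cord, with evaluation metrics and a physics-based simulator.

## The problem

T2\*-weighted EPI of the cervical cord shows periodic signal dropouts along
the rostro-caudal axis: susceptibility differences at the vertebra/disk
interfaces impose a local B0 gradient along the slice direction, which
dephases spins across the slice. With an ideal rectangular slice profile of
thickness Δz, a residual through-slice gradient G_z at echo time TE
attenuates the signal as

    A(G_z) = | sinc( γ̄ · G_z · TE · Δz ) |,   γ̄ = 42.577 kHz/mT,

so at TE = 40 ms and Δz = 5 mm the signal vanishes entirely at
G_z ≈ 0.117 mT/m — a gradient strength that routinely occurs near
intervertebral junctions. A slice-specific compensation gradient pulse (a
"z-shim"), chosen from a discrete grid of moments (typically 21 equidistant
values spanning ±0.21 mT/m), can cancel the local gradient slice by slice.

The package is for researchers running or simulating spinal-cord fMRI
protocols. It implements:

* **grid arithmetic** — the discrete compensation grid, index/gradient/moment
  conversions, rounding with clamping and documented tie-breaking
  (`zshim_grid()`, `nearest_index()`, `moment_for_index()`);
* **EPI-reference-based selection** — per-slice argmax of mean cord intensity
  across a z-shim reference scan (`select_zshim_epi()`);
* **field-map-based selection** — per-voxel frequency offsets from two-echo
  or multi-echo phase data, slice-wise least-squares fits of
  constant-plus-linear field terms over a 9 mm slab, rounding of the fitted
  G_z onto the grid, and a histogram-based robust variant
  (`frequency_from_multiecho()`, `fit_slicewise_basis()`,
  `zshim_from_fieldmap()`);
* **evaluation metrics** — slice profiles, coefficient of variation,
  temporal SNR, dVARS/refRMS outlier censoring, artificial volume
  reconstruction, step-difference characterisation, bootstrap CIs
  (`tsnr_map()`, `detect_outlier_volumes()`,
  `reconstruct_from_reference()`, `percent_difference_ci()`);
* **a synthetic-data generator** — cylindrical cord phantom, rostro-caudally
  periodic through-slice gradient field (~15 mm period), sinc-type
  dephasing, reference stacks, time series and wrapped multi-echo phase
  images with ground truth (`simulate_scenario()`).

## Worked example

```r
library(zshimtools)

grid   <- zshim_grid(21, 0.21)                    # ±0.21 mT/m in 0.021 steps
params <- acq_params(te = 40, slice_thickness = 5, n_slices = 24)
field  <- field_spec(gz_amplitude = 0.15, period_mm = 15)
sc <- simulate_scenario(grid, params, field,
                        noise = noise_spec(sigma_image = 5),  # SNR 20
                        sigma_dnu_hz = 5, seed = 42)

sel_epi <- select_zshim_epi(sc$stack, mask = sc$epi_mask)
sel_fm  <- zshim_from_fieldmap(sc$fm, sc$fm_mask, grid, params)
rbind(truth = sc$optimal_indices, epi = sel_epi$indices, fm = sel_fm$indices)
#>       [,1] [,2] [,3] [,4] [,5] [,6] ...
#> truth    6   11   16    6   11   16 ...
#> epi      6   11   16    6   11   16 ...
#> fm       6   11   15    7   11   15 ...
```

The EPI-based method recovers the ground-truth indices exactly at SNR 20;
the field-map method lands within one step — its 9 mm fitting slab averages
over a substantial fraction of the 15 mm field period, slightly shrinking
rapidly varying gradients (the same physics that makes field-map-based
selection a touch weaker than reference-scan selection on real data).
Indices 6/11/16 correspond to compensations of +0.105/0/−0.105 mT/m
(`gradient_for_index()`), i.e. moments of ±4.2 mT/m·ms at TE 40 ms.

Comparing the reconstructed volume under the selected shims against the
no-z-shim (all index 11) condition:

```r
rec_sel <- reconstruct_from_reference(sc$stack, sel_epi)
rec_neu <- reconstruct_from_reference(sc$stack, neutral_selection(grid, params))
profile_summary(slicewise_mean(rec_sel, sc$epi_mask))
#> mean cord intensity: 99.8 (selected) vs 39.6 (no z-shim)  [+151.8%]
#> slice CV: 0.008 vs 1.101  [-99.3%]
```

On this phantom, two of every three slices sit in a dropout zone, so shim
selection roughly recovers the phantom's full intensity and flattens the
slice profile. (Real cords show smaller but still substantial gains; the
phantom numbers quantify the dephasing model, not in-vivo effect sizes.)

## Command line

A thin CLI over the same functions lives at `inst/cli/zshim.R`
(after installation: `system.file("cli", "zshim.R", package = "zshimtools")`):

```sh
Rscript zshim.R simulate   --out-dir sim --seed 4 --sigma-image 5
Rscript zshim.R select-epi --stack sim/reference_stack.nii.gz \
                           --mask sim/epi_mask.nii.gz --out-dir out
Rscript zshim.R select-fm  --fieldmap sim/fieldmap_hz.nii.gz \
                           --mask sim/fm_mask.nii.gz --out-dir outfm
```

`select-*` writes the scanner text file (one 1-based index per line), a JSON
selection record, and a CSV diagnostic table (intensity matrix or per-slice
fit coefficients).

## Scope

Cord segmentation, motion correction, template registration and group
statistics are upstream/downstream of this package: masks are inputs,
selections and metrics are outputs.
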