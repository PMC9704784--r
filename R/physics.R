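#' Cylindrical cord phantom specification
#'
#' Geometry of the synthetic phantom standing in for a cervical-cord
#' cross-section: a homogeneous cylinder of raised intensity along the slice
#' axis, embedded in low-intensity background tissue. Defaults mimic a
#' cervical cord (radius 4 mm) at 1 mm in-plane resolution; the in-plane
#' matrix is kept small because only cord-mask voxels matter downstream.
#'
#' @param matrix `(nx, ny, nz)` voxel counts.
#' @param voxel_size `(dx, dy, dz)` mm.
#' @param cord_radius cylinder radius, mm.
#' @param cord_center in-plane centre `(x, y)` in mm relative to the
#'   field-of-view centre.
#' @param s0 baseline intensity inside the cord.
#' @param background intensity outside.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = c(32L, 32L, 24L), voxel_size = c(1, 1, 5),
                         cord_radius = 4, cord_center = c(0, 0),
                         s0 = 100, background = 10) {
  stopifnot(length(matrix) == 3L, all(matrix >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            cord_radius >= 0, s0 > background, background >= 0)
  # a radius larger than the FOV is allowed (mask covers everything);
  # a zero radius gives an empty mask that downstream pre-checks reject
  structure(list(matrix = as.integer(matrix), voxel_size = voxel_size,
                 cord_radius = cord_radius, cord_center = cord_center,
                 s0 = s0, background = background),
            class = "phantom_spec")
}

#' Build the cord phantom
#'
#' Binary cylinder mask (voxel centre within `cord_radius` of the cord axis)
#' and the corresponding intensity volume (`s0` inside, `background`
#' outside). Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return List with `intensity` (3D array) and `mask` (a [cord_mask()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$matrix
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * spec$voxel_size[1]
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * spec$voxel_size[2]
  r2 <- outer((xs - spec$cord_center[1])^2, (ys - spec$cord_center[2])^2, "+")
  inplane <- (r2 <= spec$cord_radius^2) * 1L
  mask <- array(rep(inplane, d[3]), d)
  intensity <- array(spec$background, d)
  intensity[mask == 1L] <- spec$s0
  list(intensity = intensity, mask = cord_mask(mask))
}

#' Structured B0 field specification
#'
#' The through-slice field gradient of the cervical cord is modulated
#' rostro-caudally with the periodicity of the vertebral column (period
#' about 15 mm, strongest near the intervertebral junctions). Two modes:
#' `"sinusoidal"` uses `gz(z) = gz_amplitude * sin(2*pi*(z - phase_mm) /
#' period_mm)`; `"per_slice_table"` makes the field exactly
#' constant-plus-linear within each EPI slice with the given per-slice
#' through-slice gradient (continuous across slice boundaries), so
#' slice-wise fits recover the table exactly.
#'
#' @param gz_amplitude peak through-slice gradient, mT/m.
#' @param period_mm rostro-caudal modulation period, mm (default 15).
#' @param phase_mm spatial phase offset, mm.
#' @param gx,gy in-plane linear field terms, mT/m.
#' @param offset_hz global frequency offset, Hz.
#' @param mode `"sinusoidal"` or `"per_slice_table"`.
#' @param per_slice_gz explicit per-EPI-slice gradients, mT/m (table mode).
#' @param gz_cap sanity cap on `|gz|`, mT/m.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(gz_amplitude = 0.15, period_mm = 15, phase_mm = 0,
                       gx = 0, gy = 0, offset_hz = 0,
                       mode = c("sinusoidal", "per_slice_table"),
                       per_slice_gz = NULL, gz_cap = 1) {
  mode <- match.arg(mode)
  stopifnot(period_mm > 0, gz_cap > 0)
  if (mode == "per_slice_table") {
    if (is.null(per_slice_gz)) stop("table mode requires 'per_slice_gz'")
    if (any(abs(per_slice_gz) > gz_cap)) stop("per_slice_gz exceeds gz_cap")
  } else if (abs(gz_amplitude) > gz_cap) {
    stop("gz_amplitude exceeds gz_cap")
  }
  structure(list(gz_amplitude = gz_amplitude, period_mm = period_mm,
                 phase_mm = phase_mm, gx = gx, gy = gy,
                 offset_hz = offset_hz, mode = mode,
                 per_slice_gz = per_slice_gz, gz_cap = gz_cap),
            class = "field_spec")
}

# integral of gz(z) dz in mT/m * mm, as a function of z (mm):
# the frequency offset contribution is gamma_bar * integral.
.field_z_integral <- function(spec, z, params = NULL) {
  if (spec$mode == "sinusoidal") {
    A <- spec$gz_amplitude; P <- spec$period_mm
    -A * P / (2 * pi) * cos(2 * pi * (z - spec$phase_mm) / P)
  } else {
    stopifnot(!is.null(params))
    t <- params$slice_thickness
    centers <- epi_slice_centers(params)
    g <- spec$per_slice_gz
    n <- length(g)
    # piecewise linear-in-z integral, continuous at slice boundaries
    C <- numeric(n)
    if (n > 1L)
      for (s in 2:n) C[s] <- C[s - 1L] + (g[s - 1L] + g[s]) * t / 2
    s_of_z <- pmin(pmax(ceiling(z / t), 1L), n)
    C[s_of_z] + g[s_of_z] * (z - centers[s_of_z])
  }
}

#' Through-slice gradient of the specified field
#'
#' `gz(z)` in mT/m at coordinates `z` (mm) for a [field_spec()].
#' @param spec a [field_spec()].
#' @param z coordinates along the slice axis, mm.
#' @param params [acq_params()] (table mode only).
#' @export
field_gz_at <- function(spec, z, params = NULL) {
  if (spec$mode == "sinusoidal") {
    spec$gz_amplitude * sin(2 * pi * (z - spec$phase_mm) / spec$period_mm)
  } else {
    stopifnot(!is.null(params))
    n <- length(spec$per_slice_gz)
    s_of_z <- pmin(pmax(ceiling(z / params$slice_thickness), 1L), n)
    spec$per_slice_gz[s_of_z]
  }
}

#' Per-slice mean through-slice gradient (ground truth)
#'
#' The analytic mean of `gz(z)` over each EPI slice's extent,
#' `[Iz(c + t/2) - Iz(c - t/2)] / t` with `Iz` the integral of `gz`. This is
#' the gradient a z-shim can cancel for that slice, and (by construction)
#' what both the reference-scan ground truth and the slice-wise field fit
#' should recover.
#'
#' @param spec a [field_spec()].
#' @param params [acq_params()].
#' @return Numeric vector of per-slice gradients, mT/m.
#' @export
slice_mean_gz <- function(spec, params) {
  if (spec$mode == "per_slice_table") return(spec$per_slice_gz)
  t <- params$slice_thickness
  centers <- epi_slice_centers(params)
  (.field_z_integral(spec, centers + t / 2) -
   .field_z_integral(spec, centers - t / 2)) / t
}

#' Evaluate the field specification on a voxel grid
#'
#' Builds the frequency-offset map
#' `dnu(x, y, z) = gamma_bar * (gx*x + gy*y + integral(gz) ) + offset_hz`
#' (Hz) on a grid with the given dimensions and voxel size, z starting at 0
#' (plane centres at `(k - 1/2) * dz`). In table mode the through-slice slope
#' inside EPI slice `s` is exactly `per_slice_gz[s]`.
#'
#' @param spec a [field_spec()].
#' @param dim `(nx, ny, nz)` voxels.
#' @param voxel_size `(dx, dy, dz)` mm.
#' @param params [acq_params()] (required in table mode).
#' @return A [field_map()] with `slice_centers` filled in when `params` is
#'   given.
#' @export
make_field <- function(spec, dim, voxel_size = c(1, 1, 1), params = NULL) {
  stopifnot(inherits(spec, "field_spec"), length(dim) == 3L)
  xs <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * voxel_size[1]
  ys <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * voxel_size[2]
  zs <- (seq_len(dim[3]) - 0.5) * voxel_size[3]
  gb <- .GAMMA_BAR_HZ_PER_MT / 1000   # Hz per (mT/m * mm)
  plane <- gb * (outer(spec$gx * xs, spec$gy * ys, "+")) + spec$offset_hz
  zint <- gb * .field_z_integral(spec, zs, params)
  dnu <- array(0, dim)
  for (k in seq_len(dim[3])) dnu[, , k] <- plane + zint[k]
  field_map(dnu, voxel_size = voxel_size, z_origin = zs[1],
            slice_centers = if (!is.null(params)) epi_slice_centers(params))
}

#' Through-slice dephasing attenuation
#'
#' Signal attenuation of a gradient-echo slice with an ideal rectangular
#' slice profile under a residual through-slice gradient `g`:
#' `A = |sin(pi*u) / (pi*u)|` with `u = gamma_bar * g * TE * dz`
#' (dimensionless; TE in s, slice thickness in m). `A(0) = 1`, `A` is even in
#' `g`, and the first null sits at `g = 1/(gamma_bar * TE * dz)` — about
#' 0.1174 mT/m at TE 40 ms and 5 mm slices. A Gaussian slice-profile variant
#' `A = exp(-(pi*u)^2 * k)` is available for robustness checks; the rect
#' profile is the default model.
#'
#' @param g_residual residual through-slice gradient(s), mT/m.
#' @param params [acq_params()] (TE, slice thickness).
#' @param profile `"rect"` (default) or `"gaussian"`.
#' @param gaussian_k shape factor of the Gaussian profile.
#' @return Attenuation factor(s) in `[0, 1]`.
#' @export
through_slice_attenuation <- function(g_residual, params,
                                      profile = c("rect", "gaussian"),
                                      gaussian_k = 0.05) {
  profile <- match.arg(profile)
  stopifnot(inherits(params, "acq_params"))
  u <- .GAMMA_BAR_HZ_PER_MT * g_residual * (params$te / 1000) *
    (params$slice_thickness / 1000)
  if (profile == "rect") {
    a <- ifelse(u == 0, 1, abs(sin(pi * u) / (pi * u)))
  } else {
    a <- exp(-(pi * u)^2 * gaussian_k)
  }
  a
}

#' Noise specification
#'
#' @param sigma_image Gaussian intensity noise SD (image units).
#' @param sigma_phase_rad Gaussian phase noise SD (radians).
#' @param drift_per_volume fractional linear intensity drift per volume.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_image = 0, sigma_phase_rad = 0,
                       drift_per_volume = 0, seed = NULL) {
  stopifnot(sigma_image >= 0, sigma_phase_rad >= 0)
  structure(list(sigma_image = sigma_image, sigma_phase_rad = sigma_phase_rad,
                 drift_per_volume = drift_per_volume, seed = seed),
            class = "noise_spec")
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Simulate a z-shim reference scan
#'
#' One EPI volume per grid step: volume `k` is the phantom intensity scaled
#' by the dephasing attenuation of the residual gradient
#' `g_true(slice) - gradient_for_index(grid, k)`, plus Gaussian noise.
#' `g_true` is the per-slice mean through-slice gradient of the field
#' ([slice_mean_gz()]), so the brightest volume per slice marks the
#' compensation nearest the truth.
#'
#' @param phantom output of [make_phantom()] (on the EPI grid:
#'   `nz == params$n_slices`).
#' @param field a [field_spec()], or a numeric vector of per-slice
#'   through-slice gradients (mT/m).
#' @param grid [zshim_grid()].
#' @param params [acq_params()].
#' @param noise [noise_spec()].
#' @param profile slice profile passed to [through_slice_attenuation()].
#' @return A [reference_stack()] with attribute `"ground_truth"`: list of
#'   `g_true` (per-slice mT/m) and `optimal_indices` (per-slice argmax of
#'   the noiseless attenuation, ties toward the smaller compensation).
#' @export
simulate_reference_scan <- function(phantom, field, grid, params,
                                    noise = noise_spec(), profile = "rect") {
  g_true <- if (inherits(field, "field_spec")) slice_mean_gz(field, params)
            else as.numeric(field)
  stopifnot(length(g_true) == params$n_slices)
  d <- c(dim(phantom$intensity), grid$n_steps)
  stopifnot(d[3] == params$n_slices)
  att <- outer(g_true, grid$values,
               function(g, gc) through_slice_attenuation(g - gc, params,
                                                         profile = profile))
  data <- array(0, d)
  for (k in seq_len(grid$n_steps))
    for (s in seq_len(params$n_slices))
      data[, , s, k] <- phantom$intensity[, , s] * att[s, k]
  if (noise$sigma_image > 0)
    data <- data + .with_seed(noise$seed,
                              array(rnorm(prod(d), 0, noise$sigma_image), d))
  data[data < 0] <- 0
  stack <- reference_stack(data, grid, params)
  absg <- abs(grid$values)
  opt <- apply(att, 1L, function(a) {
    cand <- which(a == max(a))
    cand[order(absg[cand], cand)][1L]
  })
  attr(stack, "ground_truth") <- list(g_true = g_true,
                                      optimal_indices = as.integer(opt))
  stack
}

#' Simulate an EPI time series under a z-shim selection
#'
#' Each volume is the phantom attenuated by the residual gradient left after
#' the selected compensation, with optional linear drift, Gaussian noise and
#' injected global spike volumes (for outlier-censoring tests).
#'
#' @inheritParams simulate_reference_scan
#' @param selection a [zshim_selection()] (e.g. ground truth or neutral).
#' @param n_volumes number of volumes (the evaluation protocol uses 250).
#' @param spike_volumes integer indices of volumes receiving a spike.
#' @param spike_amplitude intensity added to every voxel of a spike volume.
#' @return 4D array `[x, y, slice, volume]`.
#' @export
simulate_timeseries <- function(phantom, field, selection, n_volumes, params,
                                noise = noise_spec(), profile = "rect",
                                spike_volumes = integer(0),
                                spike_amplitude = 0) {
  stopifnot(inherits(selection, "zshim_selection"))
  g_true <- if (inherits(field, "field_spec")) slice_mean_gz(field, params)
            else as.numeric(field)
  att <- through_slice_attenuation(g_true - selection$gradients, params,
                                   profile = profile)
  base <- phantom$intensity * rep(att, each = prod(dim(phantom$intensity)[1:2]))
  d <- c(dim(phantom$intensity), n_volumes)
  data <- array(0, d)
  drift <- 1 + noise$drift_per_volume * (seq_len(n_volumes) - 1)
  for (t in seq_len(n_volumes)) data[, , , t] <- base * drift[t]
  if (noise$sigma_image > 0)
    data <- data + .with_seed(noise$seed,
                              array(rnorm(prod(d), 0, noise$sigma_image), d))
  for (t in spike_volumes) data[, , , t] <- data[, , , t] + spike_amplitude
  data
}

#' Simulate multi-echo field-map phases
#'
#' Wrapped phase volumes `phi(TE) = wrap(2*pi*dnu*TE + phi0 + noise)` at the
#' given echo times, from a frequency-offset map. (Noise is added before the
#' final wrap so outputs always satisfy the (-pi, pi] convention.)
#'
#' @param fm a [field_map()] (Hz).
#' @param echo_times_ms echo times, ms.
#' @param noise [noise_spec()] (`sigma_phase_rad`).
#' @param phi0 receiver phase offset, radians.
#' @return A [phase_series()] with the field map's geometry.
#' @export
simulate_fieldmap_phases <- function(fm, echo_times_ms, noise = noise_spec(),
                                     phi0 = 0) {
  stopifnot(inherits(fm, "field_map"), length(echo_times_ms) >= 2L)
  d <- c(dim(fm$dnu), length(echo_times_ms))
  ph <- array(0, d)
  for (e in seq_along(echo_times_ms))
    ph[, , , e] <- 2 * pi * fm$dnu * (echo_times_ms[e] / 1000) + phi0
  if (noise$sigma_phase_rad > 0)
    ph <- ph + .with_seed(noise$seed,
                          array(rnorm(prod(d), 0, noise$sigma_phase_rad), d))
  phase_series(wrap_phase(ph), echo_times_ms,
               voxel_size = fm$voxel_size, z_origin = fm$z_origin)
}

#' Simulate a complete evaluation scenario
#'
#' Convenience wrapper building everything the two selection methods need
#' from one field specification: the EPI-grid phantom and mask, the z-shim
#' reference stack (with ground truth), the field-map-grid phantom mask and
#' frequency-offset map (optionally with added Gaussian frequency noise),
#' sampled at `params$slice_spacing_fm` along the slice axis.
#'
#' @param grid [zshim_grid()].
#' @param params [acq_params()].
#' @param field a [field_spec()].
#' @param phantom a [phantom_spec()] for the EPI grid; its z dimension and
#'   spacing are forced to `params`.
#' @param noise [noise_spec()]; `sigma_image` applies to the reference stack,
#'   `sigma_dnu_hz` below to the field map.
#' @param sigma_dnu_hz Gaussian noise SD added to the frequency map, Hz.
#' @param seed RNG seed for all noise draws.
#' @return List: `stack`, `epi_mask`, `fm`, `fm_mask`, `g_true`,
#'   `optimal_indices`, `params`, `grid`.
#' @export
simulate_scenario <- function(grid = zshim_grid(), params = acq_params(),
                              field = field_spec(),
                              phantom = NULL, noise = noise_spec(),
                              sigma_dnu_hz = 0, seed = NULL) {
  if (!is.null(seed)) noise$seed <- seed
  if (is.null(phantom))
    phantom <- phantom_spec(matrix = c(32L, 32L, params$n_slices),
                            voxel_size = c(1, 1, params$slice_thickness))
  ph_epi <- make_phantom(phantom)
  stack <- simulate_reference_scan(ph_epi, field, grid, params, noise)
  gt <- attr(stack, "ground_truth")
  nz_fm <- round(params$n_slices * params$slice_thickness /
                 params$slice_spacing_fm)
  fm_spec <- phantom_spec(matrix = c(phantom$matrix[1:2], nz_fm),
                          voxel_size = c(phantom$voxel_size[1:2],
                                         params$slice_spacing_fm),
                          cord_radius = phantom$cord_radius,
                          cord_center = phantom$cord_center,
                          s0 = phantom$s0, background = phantom$background)
  ph_fm <- make_phantom(fm_spec)
  fm <- make_field(field, dim = fm_spec$matrix,
                   voxel_size = fm_spec$voxel_size, params = params)
  if (sigma_dnu_hz > 0)
    fm$dnu <- fm$dnu + .with_seed(if (is.null(seed)) NULL else seed + 1L,
                                  array(rnorm(length(fm$dnu), 0, sigma_dnu_hz),
                                        dim(fm$dnu)))
  list(stack = stack, epi_mask = ph_epi$mask, phantom = ph_epi,
       fm = fm, fm_mask = ph_fm$mask,
       g_true = gt$g_true, optimal_indices = gt$optimal_indices,
       params = params, grid = grid)
}
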