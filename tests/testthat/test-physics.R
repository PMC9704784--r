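test_that("cylinder phantom mask matches the point-in-circle oracle", {
  spec <- phantom_spec(matrix = c(16L, 16L, 4L), voxel_size = c(1, 1, 5),
                       cord_radius = 4)
  ph <- make_phantom(spec)
  xs <- (seq_len(16) - 8.5)
  count <- 0L
  for (i in 1:16) for (j in 1:16)
    if (xs[i]^2 + xs[j]^2 <= 16) count <- count + 1L
  expect_identical(sum(ph$mask$data[, , 1]), count)
  expect_true(all(apply(ph$mask$data, 3, sum) == count))
  expect_true(all(ph$intensity[ph$mask$data == 1] == spec$s0))
  expect_true(all(ph$intensity[ph$mask$data == 0] == spec$background))

  # radius covering the whole FOV -> all-ones mask
  big <- make_phantom(phantom_spec(matrix = c(8L, 8L, 2L),
                                   cord_radius = 100))
  expect_true(all(big$mask$data == 1))

  # radius 0 -> empty mask, rejected by downstream pre-checks
  tiny <- make_phantom(phantom_spec(matrix = c(8L, 8L, 2L), cord_radius = 0))
  expect_true(all(tiny$mask$data == 0))
  g <- zshim_grid(); p <- acq_params(n_slices = 2L)
  stack <- simulate_reference_scan(tiny, rep(0, 2), g, p)
  expect_error(intensity_matrix(stack, tiny$mask), "empty")
})

test_that("make_field realises constant, table and sinusoidal fields", {
  p <- acq_params(n_slices = 4L)
  fm0 <- make_field(field_spec(gz_amplitude = 0, offset_hz = 10),
                    c(4, 4, 20), params = p)
  expect_true(all(fm0$dnu == 10))

  # table mode: the slice-wise fit recovers the per-slice gradients exactly
  gz_tab <- c(0.05, -0.03, 0, 0.08)
  fs <- field_spec(mode = "per_slice_table", per_slice_gz = gz_tab)
  fm <- make_field(fs, c(8, 8, 20), params = p)
  mask <- cord_mask(array(1L, c(8, 8, 20)))
  for (s in 1:4) {
    fit <- fit_slicewise_basis(fm, mask, s, p, slab_margin_mm = 0)
    expect_equal(fit$gz, gz_tab[s], tolerance = 1e-10)
  }

  # sinusoidal mode: finite-difference slope tracks gamma_bar * gz(z)
  fss <- field_spec(gz_amplitude = 0.1, period_mm = 15)
  fms <- make_field(fss, c(2, 2, 120), params = acq_params())
  zc <- (seq_len(120) - 0.5)
  fd <- (fms$dnu[1, 1, 3:120] - fms$dnu[1, 1, 1:118]) / 2    # Hz/mm at zc[2:119]
  # central differences at 1 mm on a 15 mm period carry a sinc(2*pi*h/P)
  # discretisation factor (~3%), so compare at that order
  expect_equal(fieldgrad_from_slope(fd),
               field_gz_at(fss, zc[2:119]), tolerance = 0.05)
})

test_that("through-slice attenuation is a unit-peak even sinc with nulls at
           integer dephasing cycles", {
  p <- acq_params(te = 40, slice_thickness = 5)
  expect_identical(through_slice_attenuation(0, p), 1)
  g_null <- 1 / (42.577 * 0.04 * 5)       # first sinc null, ~0.1174 mT/m
  expect_equal(through_slice_attenuation(g_null, p), 0, tolerance = 1e-12)
  expect_equal(through_slice_attenuation(2 * g_null, p), 0, tolerance = 1e-12)
  g <- seq(-0.3, 0.3, by = 0.013)
  a <- through_slice_attenuation(g, p)
  expect_equal(a, through_slice_attenuation(-g, p))
  expect_true(all(a >= 0 & a <= 1))
  # Gaussian-profile variant: also unit peak, even, monotone in |g|
  ag <- through_slice_attenuation(g, p, profile = "gaussian")
  expect_equal(ag, through_slice_attenuation(-g, p, profile = "gaussian"))
  expect_identical(through_slice_attenuation(0, p, profile = "gaussian"), 1)
})

test_that("reference-scan simulation places the brightest volume at the
           ground-truth index", {
  sc <- ramp_scenario()
  m <- intensity_matrix(sc$stack, sc$epi_mask)
  expect_identical(apply(m, 1, which.max), sc$optimal_indices)

  # zero gradient: neutral volume brightest, +/-g volumes pairwise identical
  g <- zshim_grid(); p <- acq_params(n_slices = 2L)
  ph <- make_phantom(phantom_spec(matrix = c(12L, 12L, 2L)))
  st <- simulate_reference_scan(ph, rep(0, 2), g, p)
  m0 <- intensity_matrix(st, ph$mask)
  expect_true(all(apply(m0, 1, which.max) == 11L))
  for (k in 1:10)
    expect_equal(st$data[, , , k], st$data[, , , 22 - k], tolerance = 1e-12)

  # at the sinc null the uncompensated slice is wiped out
  null_g <- 1 / (42.577 * 0.04 * 5)
  stn <- simulate_reference_scan(ph, rep(null_g, 2), g, acq_params(n_slices = 2L))
  mn <- intensity_matrix(stn, ph$mask)
  expect_lt(mn[1, 11], 1e-9)
})

test_that("time-series simulation reproduces tSNR = mu/sigma and rewards
           correct shim selection", {
  g <- zshim_grid(); p <- acq_params(n_slices = 4L)
  ph <- make_phantom(phantom_spec(matrix = c(12L, 12L, 4L)))
  idx <- c(6L, 11L, 16L, 9L)
  gt <- gradient_for_index(g, idx)
  sel <- zshim_selection(idx, g, p, method = "manual")

  ts0 <- simulate_timeseries(ph, gt, sel, 5, p)
  expect_true(all(ts0[, , , 1] == ts0[, , , 5]))   # noiseless: identical
  expect_identical(attr(tsnr_map(ts0), "n_zero_sd"), length(ts0[, , , 1]))

  ts <- simulate_timeseries(ph, gt, sel, 250, p,
                            noise = noise_spec(sigma_image = 5, seed = 9))
  tm <- tsnr_map(ts)
  cordvox <- ph$mask$data == 1
  expect_equal(mean(tm[cordvox]), 100 / 5, tolerance = 0.03)

  # ground-truth selection beats neutral on dropout slices
  neu <- neutral_selection(g, p)
  tsn <- simulate_timeseries(ph, gt, neu, 250, p,
                             noise = noise_spec(sigma_image = 5, seed = 9))
  expect_gt(mean(tsnr_map(ts)[cordvox]), mean(tsnr_map(tsn)[cordvox]))
})

test_that("phase simulation respects the wrap convention and round-trips", {
  fm <- field_map(array(0, c(2, 2, 2)))
  ser <- simulate_fieldmap_phases(fm, c(4, 6.46))
  expect_true(all(ser$phases == 0))
  te <- (seq_len(12) - 1) * 1.3 + 4
  fm2 <- field_map(array(runif(8, -300, 300), c(2, 2, 2)))
  ser2 <- simulate_fieldmap_phases(fm2, te, phi0 = 0.3)
  expect_true(all(ser2$phases > -pi & ser2$phases <= pi))
})

test_that("generators are bit-reproducible given a seed", {
  a <- ramp_scenario(seed = 123, sigma_image = 5, sigma_dnu_hz = 5)
  b <- ramp_scenario(seed = 123, sigma_image = 5, sigma_dnu_hz = 5)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$fm$dnu, b$fm$dnu)
  c <- ramp_scenario(seed = 124, sigma_image = 5)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("field_spec validates its inputs", {
  expect_error(field_spec(mode = "per_slice_table"), "per_slice_gz")
  expect_error(field_spec(gz_amplitude = 2, gz_cap = 1), "cap")
  expect_error(field_spec(period_mm = 0), "period_mm")
})
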