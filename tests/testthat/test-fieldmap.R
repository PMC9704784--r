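test_that("two-echo frequency estimation follows the wrapped closed form", {
  ph <- array(0, c(2, 2, 2, 2))
  ph[, , , 2] <- pi / 2                       # quarter cycle over dTE
  ser <- phase_series(ph, c(4.00, 6.46))
  fm <- frequency_from_two_echoes(ser)
  expect_equal(fm$dnu[1, 1, 1], 0.25 / 0.00246, tolerance = 1e-12)

  ser0 <- phase_series(array(1.2, c(2, 2, 2, 2)), c(4.00, 6.46))
  expect_true(all(frequency_from_two_echoes(ser0)$dnu == 0))
})

test_that("two-echo estimation inverts simulated phases below the
           ambiguity limit", {
  set.seed(21)
  dnu_true <- array(runif(4 * 4 * 6, -200, 200), c(4, 4, 6))  # |dnu| < 203 Hz
  fm0 <- field_map(dnu_true)
  ser <- simulate_fieldmap_phases(fm0, c(4.00, 6.46))
  fm <- frequency_from_two_echoes(ser)
  expect_equal(fm$dnu, dnu_true, tolerance = 1e-9)
})

test_that("echo-train unwrapping recovers wrapped ramps exactly", {
  nech <- 12L
  wrap_arr <- function(slope) {
    true <- array(rep(slope * (seq_len(nech) - 1), each = 8), c(2, 2, 2, nech))
    list(true = true,
         ser = phase_series(wrap_phase(true), seq_len(nech) * 1.3))
  }
  w <- wrap_arr(2.0)                       # wraps every other echo
  un <- unwrap_echo_train(w$ser)
  expect_equal(un$phases, w$true, tolerance = 1e-12)

  w <- wrap_arr(0.25)                      # stays inside (-pi, pi]: identity
  expect_equal(unwrap_echo_train(w$ser)$phases, w$ser$phases)

  w <- wrap_arr(-2.5)                      # monotone decreasing after unwrap
  un <- unwrap_echo_train(w$ser)
  expect_equal(un$phases, w$true, tolerance = 1e-12)
  expect_true(all(apply(un$phases, 1:3, diff) < 0))

  expect_error(unwrap_echo_train(phase_series(array(0, c(2, 2, 2, 2)),
                                              c(1, 2))), "3 echoes")
})

test_that("multi-echo frequency estimation is exact on noiseless data and
           matches the two-point slope on wrap-free data", {
  te <- (seq_len(12) - 1) * 1.3 + 4
  dnu_true <- array(seq(-300, 300, length.out = 27), c(3, 3, 3))
  ser <- simulate_fieldmap_phases(field_map(dnu_true), te)
  fm <- frequency_from_multiecho(ser)
  expect_equal(fm$dnu, dnu_true, tolerance = 1e-9)

  expect_true(all(frequency_from_multiecho(
    simulate_fieldmap_phases(field_map(array(0, c(2, 2, 2))), te))$dnu == 0))

  # wrap-free data: OLS slope equals the first/last two-point slope
  dnu_small <- array(runif(8, -20, 20), c(2, 2, 2))
  ser2 <- simulate_fieldmap_phases(field_map(dnu_small), te)
  un <- unwrap_echo_train(ser2)
  two_point <- (un$phases[, , , 12] - un$phases[, , , 1]) /
    (2 * pi * (te[12] - te[1]) / 1000)
  expect_equal(frequency_from_multiecho(ser2)$dnu, two_point,
               tolerance = 1e-9)
})

test_that("multi-echo estimator beats the matched two-echo estimator under
           phase noise", {
  te <- (seq_len(12) - 1) * 1.3 + 4
  truth <- 50
  nrep <- 400L
  set.seed(33)
  est_me <- est_2e <- numeric(nrep)
  for (r in seq_len(nrep)) {
    ns <- noise_spec(sigma_phase_rad = 0.05)
    ser <- simulate_fieldmap_phases(field_map(array(truth, c(1, 1, 1))), te,
                                    noise = ns)
    est_me[r] <- frequency_from_multiecho(ser)$dnu[1]
    ser2 <- phase_series(ser$phases[, , , c(1, 12), drop = FALSE],
                         te[c(1, 12)])
    est_2e[r] <- frequency_from_two_echoes(ser2)$dnu[1]
  }
  expect_lt(sd(est_me), sd(est_2e))
  expect_equal(mean(est_me), truth, tolerance = 0.01)
})

test_that("frequencies beyond the per-echo Nyquist limit alias", {
  te <- (seq_len(12) - 1) * 1.3 + 4       # dTE 1.3 ms -> limit ~385 Hz
  ser <- simulate_fieldmap_phases(field_map(array(500, c(1, 1, 1))), te)
  rec <- frequency_from_multiecho(ser)$dnu[1]
  expect_gt(abs(rec - 500), 100)          # documented failure mode
  # the alias is the true frequency minus one cycle per inter-echo interval
  expect_equal(rec, 500 - 1000 / 1.3, tolerance = 1e-6)
})

test_that("Gaussian smoothing keeps constants fixed, linear fields unchanged
           in the interior, and conserves impulse mass", {
  fmc <- field_map(array(7.7, c(8, 8, 10)))
  expect_equal(smooth_fieldmap(fmc, 1)$dnu, fmc$dnu, tolerance = 1e-12)

  zs <- (seq_len(20) - 0.5) * 1
  lin <- field_map(array(rep(3 * zs, each = 64), c(8, 8, 20)))
  sm <- smooth_fieldmap(lin, 1)
  inner <- 6:15
  expect_equal(sm$dnu[4, 4, inner], lin$dnu[4, 4, inner], tolerance = 1e-9)

  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  smi <- smooth_fieldmap(field_map(imp), 1)
  expect_equal(sum(smi$dnu), 1, tolerance = 1e-6)
  expect_lt(max(smi$dnu), 1)
})

test_that("the default slab spans nine 1 mm field-map planes for a 5 mm
           slice", {
  p <- acq_params()
  fm <- make_field(field_spec(gz_amplitude = 0), c(4, 4, 120),
                   voxel_size = c(1, 1, 1), params = p)
  zi <- slab_fm_slices(fm, epi_slice_centers(p)[12], p)
  expect_length(zi, 9L)
  expect_equal(diff(range(zi)), 8L)
})

test_that("slice-wise basis fit recovers exact linear fields and matches
           the normal-equations oracle", {
  p <- acq_params(n_slices = 4L)
  dimv <- c(10, 10, 20)
  xs <- (seq_len(10) - 5.5); ys <- xs; zs <- (seq_len(20) - 0.5)
  a <- 1.3; b <- -0.7; cc <- 2.1; d0 <- 40
  dnu <- outer(outer(a * xs, b * ys, "+"), cc * zs, "+") + d0
  fm <- field_map(dnu, voxel_size = c(1, 1, 1))
  mask <- cord_mask(array(1L, dimv))
  fit <- fit_slicewise_basis(fm, mask, 2, p)
  expect_true(fit$ok)
  expect_equal(fit$gx, fieldgrad_from_slope(a), tolerance = 1e-10)
  expect_equal(fit$gy, fieldgrad_from_slope(b), tolerance = 1e-10)
  expect_equal(fit$gz, fieldgrad_from_slope(cc), tolerance = 1e-10)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-9)

  # constant field: zero slopes, offset recovered
  fmc <- field_map(array(5.5, dimv))
  fitc <- fit_slicewise_basis(fmc, mask, 2, p)
  expect_equal(c(fitc$gx, fitc$gy, fitc$gz), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fitc$offset, 5.5, tolerance = 1e-12)

  # oracle equivalence on random slabs with random masks
  set.seed(44)
  for (r in 1:10) {
    mk <- array(rbinom(prod(dimv), 1, 0.4), dimv)
    if (sum(mk) < 10) next
    fmr <- field_map(array(rnorm(prod(dimv), 0, 30), dimv))
    fit <- fit_slicewise_basis(fmr, cord_mask(mk), 3, p)
    zi <- slab_fm_slices(fmr, epi_slice_centers(p)[3], p)
    sel <- which(mk[, , zi] != 0, arr.ind = TRUE)
    beta <- oracle_fit_slab((sel[, 1] - 1), (sel[, 2] - 1),
                            zs[zi][sel[, 3]], fmr$dnu[, , zi][sel])
    expect_equal(fit$gz, fieldgrad_from_slope(beta[3]), tolerance = 1e-9)
    expect_equal(fit$gx, fieldgrad_from_slope(beta[1]), tolerance = 1e-9)
    expect_equal(fit$offset, beta[4], tolerance = 1e-9)
  }
})

test_that("a through-slice slope of 42.577 Hz/mm is exactly 1 mT/m", {
  expect_equal(fieldgrad_from_slope(42.577), 1.0, tolerance = 1e-12)
  expect_equal(slope_from_fieldgrad(1.0), 42.577, tolerance = 1e-12)
})

test_that("degenerate slabs are flagged, not fitted", {
  p <- acq_params(n_slices = 2L)
  fm <- field_map(array(1, c(4, 4, 10)))
  mk <- array(0L, c(4, 4, 10)); mk[2, 2, 3] <- 1L   # 1 voxel < 4
  fit <- fit_slicewise_basis(fm, cord_mask(mk), 1, p)
  expect_false(fit$ok)
  expect_true(is.na(fit$gz))
  # coplanar voxels (all same z): rank-deficient design
  mk2 <- array(0L, c(4, 4, 10)); mk2[, , 3] <- 1L
  fit2 <- fit_slicewise_basis(fm, cord_mask(mk2), 1, p)
  expect_false(fit2$ok)
})

test_that("select_zshim_fm rounds gradients onto the grid with neutral
           fallback and clamping", {
  g <- zshim_grid(21, 0.21)
  p <- acq_params(n_slices = 4L)
  fits <- data.frame(gz = c(0, 0.063, 0.30, NA),
                     ok = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(sel <- select_zshim_fm(fits, g, p), "clamped")
  expect_identical(sel$indices, c(11L, 8L, 1L, 11L))
  expect_match(sel$flags[3], "clamped")
  expect_match(sel$flags[4], "fit_failed")
  expect_identical(sel$method, "fm_fit")

  sel0 <- select_zshim_fm(data.frame(gz = rep(0, 4), ok = TRUE), g, p)
  expect_identical(sel0$indices, rep(11L, 4))
})

test_that("histogram gradient estimator is exact on linear fields and
           resists outlier contamination", {
  p <- acq_params(n_slices = 4L)
  dimv <- c(8, 8, 20)
  zs <- seq_len(20) - 0.5
  slope <- slope_from_fieldgrad(0.05)
  fm <- field_map(array(rep(slope * zs, each = 64), dimv))
  mask <- cord_mask(array(1L, dimv))
  h <- histogram_gradient(fm, mask, 2, p)
  expect_true(h$ok)
  expect_equal(h$gz, 0.05, tolerance = 1e-10)

  hc <- histogram_gradient(field_map(array(4, dimv)), mask, 2, p)
  expect_equal(hc$gz, 0, tolerance = 1e-12)

  # 90% of columns at gz = 0.05, 10% at 0.20: histogram tracks the mode,
  # the plain mean is pulled to ~0.065
  set.seed(55)
  dnu <- array(rep(slope * zs, each = 64), dimv)
  out_cols <- sample(64, 6)     # ~10% of the 8x8 columns
  ij <- arrayInd(out_cols, c(8, 8))
  for (k in seq_len(nrow(ij)))
    dnu[ij[k, 1], ij[k, 2], ] <- slope_from_fieldgrad(0.20) * zs
  fmo <- field_map(dnu)
  ho <- histogram_gradient(fmo, mask, 2, p)
  fito <- fit_slicewise_basis(fmo, mask, 2, p)
  expect_lt(abs(ho$gz - 0.05), 0.015)             # within one bin width
  expect_gt(fito$gz, 0.060)                        # LS mean pulled upward
  expect_lt(abs(ho$gz - 0.05), abs(fito$gz - 0.05))

  mk3 <- array(0L, dimv); mk3[1, 1, 3] <- 1L
  expect_false(histogram_gradient(field_map(dnu), cord_mask(mk3), 1, p)$ok)
})

test_that("histogram estimator beats plain least squares across seeds on the
           contaminated-mixture family", {
  p <- acq_params(n_slices = 4L)
  dimv <- c(8, 8, 20)
  zs <- seq_len(20) - 0.5
  mask <- cord_mask(array(1L, dimv))
  for (seed in 1:5) {
    set.seed(seed)
    dnu <- array(rep(slope_from_fieldgrad(0.05) * zs, each = 64), dimv)
    out_cols <- sample(64, 6)
    ij <- arrayInd(out_cols, c(8, 8))
    for (k in seq_len(nrow(ij)))
      dnu[ij[k, 1], ij[k, 2], ] <- slope_from_fieldgrad(0.20) * zs
    fmo <- field_map(dnu)
    err_h <- abs(histogram_gradient(fmo, mask, 2, p)$gz - 0.05)
    err_ls <- abs(fit_slicewise_basis(fmo, mask, 2, p)$gz - 0.05)
    expect_lte(err_h, err_ls)
  }
})
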