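# Shared fixtures: all synthetic, generated in code at test time.

# Triangular on-grid index pattern around neutral (+/- 1 step per slice).
# Gentle enough that the 9 mm slab fit recovers each slice's gradient to
# within half a grid step even where the slope changes sign.
tri_indices <- function(n_slices = 24L, amplitude = 4L, neutral = 11L) {
  period <- c(0:amplitude, (amplitude - 1):(-amplitude), (-amplitude + 1):(-1))
  neutral + rep_len(period, n_slices)
}

# Ramp field scenario: table-mode field whose per-slice gradients sit
# exactly on the grid, plus matched reference stack and field map.
ramp_scenario <- function(seed = NULL, sigma_image = 0, sigma_dnu_hz = 0,
                          matrix_xy = 32L, grid = zshim_grid(),
                          params = acq_params()) {
  idx <- tri_indices(params$n_slices)
  fs <- field_spec(mode = "per_slice_table",
                   per_slice_gz = gradient_for_index(grid, idx))
  simulate_scenario(grid = grid, params = params, field = fs,
                    phantom = phantom_spec(
                      matrix = c(matrix_xy, matrix_xy, params$n_slices),
                      voxel_size = c(1, 1, params$slice_thickness)),
                    noise = noise_spec(sigma_image = sigma_image),
                    sigma_dnu_hz = sigma_dnu_hz, seed = seed)
}

# Brute-force argmax oracle for the EPI selection: explicit double loop,
# ties toward smaller |gradient| then lower index.
oracle_select_epi <- function(mat, grid) {
  out <- integer(nrow(mat))
  for (s in seq_len(nrow(mat))) {
    best <- 1L
    for (k in seq_len(ncol(mat))) {
      if (mat[s, k] > mat[s, best]) {
        best <- k
      } else if (mat[s, k] == mat[s, best]) {
        gk <- abs(grid$values[k]); gb <- abs(grid$values[best])
        if (gk < gb || (gk == gb && k < best)) best <- k
      }
    }
    out[s] <- best
  }
  out
}

# Normal-equations oracle for the slice-wise field fit.
oracle_fit_slab <- function(xs, ys, zs, y) {
  X <- cbind(xs - mean(xs), ys - mean(ys), zs - mean(zs), 1)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
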