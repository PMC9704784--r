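#' Z-shim reference stack
#'
#' A 4D EPI acquisition with one volume per z-shim compensation step
#' (`[x, y, slice, step]`). Volume `k` was acquired with compensation
#' `gradient_for_index(grid, k)`; the per-slice brightest volume therefore
#' identifies the best compensation for that slice.
#'
#' @param data 4D numeric array `[x, y, slice, step]`, non-negative.
#' @param grid [zshim_grid()]; `grid$n_steps` must equal `dim(data)[4]`.
#' @param params [acq_params()]; `params$n_slices` must equal `dim(data)[3]`.
#' @return An object of class `reference_stack`.
#' @export
reference_stack <- function(data, grid, params) {
  stopifnot(inherits(grid, "zshim_grid"), inherits(params, "acq_params"))
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array [x, y, slice, step]")
  if (dim(data)[4] != grid$n_steps)
    stop(sprintf("stack has %d volumes but grid has %d steps",
                 dim(data)[4], grid$n_steps))
  if (dim(data)[3] != params$n_slices)
    stop(sprintf("stack has %d slices but params declare %d",
                 dim(data)[3], params$n_slices))
  if (any(data < 0, na.rm = TRUE))
    stop("reference intensities must be non-negative")
  structure(list(data = data, grid = grid, params = params),
            class = "reference_stack")
}

#' @export
print.reference_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("z-shim reference stack: %d x %d in-plane, %d slices, %d steps\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Binary cord mask
#'
#' A 3D mask on the same in-plane/slice grid as the EPI data, marking the
#' spinal cord cross-section. Segmentation is upstream of this package; the
#' mask is an input (the simulator produces exact cylinder masks for testing).
#'
#' @param data 3D array with values in \{0, 1\} (logical accepted).
#' @return An object of class `cord_mask`.
#' @export
cord_mask <- function(data) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  data <- (data != 0) * 1L
  structure(list(data = data), class = "cord_mask")
}

#' Mean reference volume
#'
#' Voxelwise mean across the z-shim step axis. In the scanner workflow this
#' mean image is the segmentation input (it averages over respiratory states
#' and over dropout patterns); here it is exposed for mask QC and for users
#' running their own segmentation.
#'
#' @param stack a [reference_stack()].
#' @return 3D array `[x, y, slice]`.
#' @export
mean_reference_volume <- function(stack) {
  stopifnot(inherits(stack, "reference_stack"))
  d <- dim(stack$data)
  array(rowMeans(matrix(stack$data, prod(d[1:3]), d[4])), d[1:3])
}

#' Slice-by-step intensity matrix
#'
#' Mean cord signal per slice and z-shim step: entry `(s, k)` is the mean of
#' volume `k`, slice `s` over mask voxels in that slice. With the standard
#' protocol (24 slices, 21 steps) this is the 24 x 21 matrix the selection
#' works on. Slices with an empty mask get `NA` (never 0, which would fake an
#' argmax winner) and are reported via the `"empty_slices"` attribute.
#'
#' @param stack a [reference_stack()].
#' @param mask a [cord_mask()] aligned with the stack.
#' @return `n_slices x n_steps` numeric matrix; attribute `empty_slices`
#'   lists slices with no mask voxels.
#' @export
intensity_matrix <- function(stack, mask) {
  stopifnot(inherits(stack, "reference_stack"), inherits(mask, "cord_mask"))
  d <- dim(stack$data)
  if (!identical(dim(mask$data), d[1:3]))
    stop("mask geometry does not match the reference stack")
  if (sum(mask$data) == 0) stop("mask is empty")
  n_slices <- d[3]; n_steps <- d[4]
  m <- matrix(NA_real_, n_slices, n_steps)
  for (s in seq_len(n_slices)) {
    idx <- mask$data[, , s] != 0
    if (!any(idx)) next
    for (k in seq_len(n_steps))
      m[s, k] <- mean(stack$data[, , s, k][idx])
  }
  empty <- which(apply(m, 1L, function(r) all(is.na(r))))
  attr(m, "empty_slices") <- empty
  m
}

#' EPI-reference-based z-shim selection
#'
#' For each slice, pick the z-shim step whose reference volume has the
#' highest mean cord intensity. Ties resolve toward the smaller compensation
#' magnitude, then the lower index; slices with missing rows (empty mask)
#' fall back to the neutral index with a warning.
#'
#' @param x an intensity matrix (`n_slices x n_steps`, from
#'   [intensity_matrix()]) or a [reference_stack()].
#' @param grid [zshim_grid()] (taken from the stack if `x` is one).
#' @param params [acq_params()] (idem).
#' @param mask [cord_mask()], required when `x` is a stack.
#' @return A [zshim_selection()] with `method = "epi"`.
#' @export
select_zshim_epi <- function(x, grid = NULL, params = NULL, mask = NULL) {
  if (inherits(x, "reference_stack")) {
    if (is.null(mask)) stop("'mask' is required when passing a reference stack")
    grid <- x$grid; params <- x$params
    x <- intensity_matrix(x, mask)
  }
  stopifnot(is.matrix(x), inherits(grid, "zshim_grid"),
            inherits(params, "acq_params"))
  if (ncol(x) != grid$n_steps)
    stop("matrix column count does not match grid steps")
  n_slices <- nrow(x)
  neutral <- neutral_index(grid)
  absg <- abs(grid$values)
  indices <- integer(n_slices)
  flags <- character(n_slices)
  for (s in seq_len(n_slices)) {
    row <- x[s, ]
    if (all(is.na(row))) {
      indices[s] <- neutral
      flags[s] <- "empty_mask:neutral_fallback"
      next
    }
    mx <- max(row, na.rm = TRUE)
    cand <- which(row == mx)
    indices[s] <- cand[order(absg[cand], cand)][1L]
  }
  if (any(nzchar(flags)))
    warning(sprintf("%d slice(s) had an empty mask; neutral index used",
                    sum(nzchar(flags))), call. = FALSE)
  zshim_selection(indices, grid, params, method = "epi", flags = flags)
}
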