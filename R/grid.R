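#' Discrete z-shim compensation grid
#'
#' A z-shim sequence can only apply a finite set of compensation gradients
#' (equivalently, gradient moments once scaled by TE). The grid is equidistant
#' and symmetric about zero, so an odd number of steps guarantees an exact
#' "no z-shim" (neutral) value. The standard protocol uses 21 steps spanning
#' +0.21 to -0.21 mT/m, i.e. steps of 0.021 mT/m, with the neutral value at
#' index 11. Indices are 1-based throughout the package, matching the index
#' file read by the scanner sequence.
#'
#' A grid may equally be expressed in gradient moment units (mT/m*ms); the
#' arithmetic is identical, only the interpretation of `g_max` changes.
#'
#' @param n_steps odd positive integer, number of compensation values.
#' @param g_max magnitude of the grid's first value (mT/m for a gradient grid).
#' @param ordering `"descending"` (default: +g_max at index 1, the usual
#'   acquisition order) or `"ascending"`.
#' @return An object of class `zshim_grid` with fields `n_steps`, `g_max`,
#'   `ordering` and the precomputed `values` vector.
#' @examples
#' g <- zshim_grid(21, 0.21)
#' grid_spacing(g)        # 0.021
#' neutral_index(g)       # 11
#' gradient_for_index(g, 1)   # +0.21
#' @export
zshim_grid <- function(n_steps = 21L, g_max = 0.21,
                       ordering = c("descending", "ascending")) {
  ordering <- match.arg(ordering)
  n_steps <- as.integer(n_steps)
  if (length(n_steps) != 1L || is.na(n_steps) || n_steps < 1L)
    stop("'n_steps' must be a positive integer")
  if (n_steps %% 2L == 0L)
    stop("'n_steps' must be odd so that an exact zero (neutral) value exists")
  if (!is.numeric(g_max) || length(g_max) != 1L || !is.finite(g_max) || g_max < 0)
    stop("'g_max' must be a finite non-negative number")
  if (n_steps > 1L && g_max == 0)
    stop("'g_max' must be positive for a multi-step grid")
  spacing <- if (n_steps == 1L) 0 else 2 * g_max / (n_steps - 1)
  values <- if (ordering == "descending")
    g_max - (seq_len(n_steps) - 1) * spacing
  else
    -g_max + (seq_len(n_steps) - 1) * spacing
  # force the central value to exact zero (guards float round-off)
  values[(n_steps + 1L) / 2] <- 0
  structure(list(n_steps = n_steps, g_max = g_max, ordering = ordering,
                 values = values),
            class = "zshim_grid")
}

#' @export
print.zshim_grid <- function(x, ...) {
  cat(sprintf("z-shim grid: %d steps, %s from %+g to %+g (spacing %g)\n",
              x$n_steps, x$ordering,
              x$values[1L], x$values[x$n_steps], grid_spacing(x)))
  cat(sprintf("neutral index: %d\n", neutral_index(x)))
  invisible(x)
}

#' Grid spacing
#'
#' Increment between adjacent compensation values: `2 * g_max / (n_steps - 1)`.
#'
#' @param grid a [zshim_grid()].
#' @return Spacing in the grid's gradient units.
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "zshim_grid"))
  if (grid$n_steps == 1L) 0 else 2 * grid$g_max / (grid$n_steps - 1)
}

#' Neutral (no z-shim) index
#'
#' The 1-based index whose compensation value is exactly zero:
#' `(n_steps + 1) / 2`. For the 21-step protocol grid this is 11; for the
#' 15-step validation grid it is 8.
#'
#' @inheritParams grid_spacing
#' @return Integer index.
#' @export
neutral_index <- function(grid) {
  stopifnot(inherits(grid, "zshim_grid"))
  as.integer((grid$n_steps + 1L) / 2L)
}

#' Compensation gradient at a grid index
#'
#' @inheritParams grid_spacing
#' @param index 1-based index (vectorised).
#' @return Compensation value(s) in the grid's units; exactly 0 at the
#'   neutral index.
#' @export
gradient_for_index <- function(grid, index) {
  stopifnot(inherits(grid, "zshim_grid"))
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index > grid$n_steps))
    stop(sprintf("index out of range 1..%d", grid$n_steps))
  grid$values[index]
}

#' Nearest grid index for an arbitrary gradient
#'
#' Rounds an estimated through-slice gradient onto the discrete grid, as done
#' when converting a fitted dephasing moment to a scanner setting. Values
#' beyond the grid range are clamped to the end index with a warning (the
#' scanner can only apply grid values); exact midpoints between two grid
#' values resolve toward the value of smaller magnitude (the smaller
#' perturbation is the safer choice when the estimate is uncertain).
#'
#' @inheritParams grid_spacing
#' @param g gradient value(s), same units as the grid.
#' @return 1-based index (vectorised over `g`).
#' @export
nearest_index <- function(grid, g) {
  stopifnot(inherits(grid, "zshim_grid"))
  if (any(!is.finite(g))) stop("'g' must be finite")
  tol <- 1e-12 * max(1, grid$g_max)   # float-safe midpoint detection
  vapply(g, function(gi) {
    d <- abs(grid$values - gi)
    cand <- which(d - min(d) <= tol)
    if (length(cand) > 1L)  # midpoint tie: smaller |gradient| wins, then lower index
      cand <- cand[order(abs(grid$values[cand]), cand)][1L]
    if (gi > max(grid$values) || gi < min(grid$values))
      warning(sprintf("gradient %g outside grid range [%g, %g]; clamped",
                      gi, min(grid$values), max(grid$values)), call. = FALSE)
    as.integer(cand)
  }, integer(1L))
}

#' Gradient moment at a grid index
#'
#' The pulsed-gradient moment is the compensation gradient scaled by the echo
#' time, `g * TE` (mT/m * ms). Because the sequence scales the moment with TE,
#' a selected index remains valid across echo times.
#'
#' @inheritParams gradient_for_index
#' @param params an [acq_params()] object supplying `te` (ms).
#' @return Moment(s) in mT/m*ms.
#' @export
moment_for_index <- function(grid, index, params) {
  stopifnot(inherits(params, "acq_params"))
  gradient_for_index(grid, index) * params$te
}

#' EPI acquisition parameters
#'
#' The parameters of the EPI protocol that the selection methods need: echo
#' time, slice thickness, slice count, and the field-map sampling interval
#' along the EPI slice axis. Defaults follow a typical cervical-cord protocol
#' at 3 T (TE 40 ms, 24 slices of 5 mm, 1 mm resampled field-map sampling).
#'
#' @param te echo time, ms.
#' @param slice_thickness EPI slice thickness, mm.
#' @param n_slices number of EPI slices.
#' @param slice_spacing_fm field-map sampling interval along the slice axis, mm.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(te = 40, slice_thickness = 5, n_slices = 24L,
                       slice_spacing_fm = 1) {
  vals <- c(te = te, slice_thickness = slice_thickness,
            n_slices = n_slices, slice_spacing_fm = slice_spacing_fm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be strictly positive")
  structure(list(te = te, slice_thickness = slice_thickness,
                 n_slices = as.integer(n_slices),
                 slice_spacing_fm = slice_spacing_fm),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("acquisition: TE %g ms, %d slices of %g mm, FM sampling %g mm\n",
              x$te, x$n_slices, x$slice_thickness, x$slice_spacing_fm))
  invisible(x)
}

#' Ernst angle
#'
#' Flip angle maximising spoiled gradient-echo signal for a given TR and T1:
#' `acos(exp(-TR/T1))`, in degrees. For TR 2312 ms and a cervical-cord gray
#' matter T1 of about 1000 ms this is about 84 degrees, the protocol's flip
#' angle.
#'
#' @param tr_ms repetition time, ms.
#' @param t1_ms longitudinal relaxation time, ms.
#' @return Angle in degrees.
#' @export
ernst_angle <- function(tr_ms, t1_ms) {
  stopifnot(tr_ms > 0, t1_ms > 0)
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}
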