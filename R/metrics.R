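#' Per-slice mean signal profile
#'
#' Mean intensity over cord-mask voxels, one value per slice. Slices with no
#' mask voxels get `NA` and are listed in the `empty_slices` attribute.
#'
#' @param volume 3D array `[x, y, slice]`.
#' @param mask a [cord_mask()] on the same grid.
#' @return An object of class `slice_profile`: numeric vector of per-slice
#'   means with attribute `empty_slices`.
#' @export
slicewise_mean <- function(volume, mask) {
  stopifnot(length(dim(volume)) == 3L, inherits(mask, "cord_mask"))
  if (!identical(dim(mask$data), dim(volume)))
    stop("mask geometry does not match the volume")
  if (sum(mask$data) == 0) stop("mask is empty")
  n <- dim(volume)[3]
  vals <- vapply(seq_len(n), function(s) {
    idx <- mask$data[, , s] != 0
    if (!any(idx)) NA_real_ else mean(volume[, , s][idx])
  }, numeric(1))
  structure(vals, empty_slices = which(is.na(vals)), class = "slice_profile")
}

#' @export
print.slice_profile <- function(x, ...) {
  cat(sprintf("slice profile, %d slices (mean %.3f, cv %.4f)\n",
              length(x), mean(unclass(x), na.rm = TRUE),
              profile_summary(x)$cv))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Summary of a slice profile
#'
#' Mean, sample variance (n-1 denominator) and coefficient of variation
#' (SD/mean) of the per-slice values. The CV is the scale-free measure of
#' signal variability along the cord: slice-specific z-shimming should lower
#' it by recovering signal in dropout slices.
#'
#' @param p a [slicewise_mean()] profile or plain numeric vector.
#' @return List with `mean`, `variance`, `cv` (`cv` is `NA` with a warning
#'   when the mean is zero).
#' @export
profile_summary <- function(p) {
  v <- as.numeric(p)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 non-missing slices")
  m <- mean(v)
  va <- stats::var(v)
  cv <- if (m == 0) {
    warning("zero mean: coefficient of variation undefined", call. = FALSE)
    NA_real_
  } else sqrt(va) / m
  list(mean = m, variance = va, cv = cv)
}

#' Temporal SNR map
#'
#' Voxelwise temporal mean divided by temporal standard deviation (sample
#' SD, n-1 denominator) of a 4D series. Voxels with zero temporal SD (e.g. a
#' noiseless simulation) get `Inf`; their count is attached as attribute
#' `n_zero_sd`.
#'
#' @param series 4D array `[x, y, slice, volume]` with at least 2 volumes.
#' @return 3D tSNR array with attribute `n_zero_sd`.
#' @export
tsnr_map <- function(series) {
  stopifnot(length(dim(series)) == 4L)
  d <- dim(series)
  if (d[4] < 2L) stop("need at least 2 volumes")
  m <- matrix(series, prod(d[1:3]), d[4])
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (d[4] - 1))
  tsnr <- ifelse(sd == 0, Inf, mu / sd)
  structure(array(tsnr, d[1:3]), n_zero_sd = sum(sd == 0))
}

#' Outlier-volume detection via dVARS and refRMS
#'
#' Two spike/motion indicators, computed over cord-mask voxels:
#' dVARS (RMS of the voxelwise difference to the preceding volume; undefined
#' for the first volume) and refRMS (RMS of the difference to the temporal
#' mean volume). A volume is flagged when either metric exceeds its own run
#' mean by more than `threshold_sd` run standard deviations (default 2);
#' flags are the union of the two criteria. The first volume's dVARS is `NA`
#' and excluded from that metric's mean/SD. When a metric's run SD is zero
#' (e.g. a constant series) that metric flags nothing.
#'
#' @param series 4D array with at least 3 volumes.
#' @param mask a [cord_mask()]; `NULL` uses the whole volume.
#' @param threshold_sd flagging threshold in run SDs.
#' @return An object of class `outlier_flags`: list with per-volume `dvars`,
#'   `refrms`, logical `flagged`.
#' @export
detect_outlier_volumes <- function(series, mask = NULL, threshold_sd = 2.0) {
  stopifnot(length(dim(series)) == 4L)
  d <- dim(series)
  if (d[4] < 3L) stop("need at least 3 volumes")
  m <- matrix(series, prod(d[1:3]), d[4])
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "cord_mask"))
    if (!identical(dim(mask$data), d[1:3]))
      stop("mask geometry does not match the series")
    m <- m[as.vector(mask$data != 0), , drop = FALSE]
    if (nrow(m) == 0L) stop("mask is empty")
  }
  dvars <- c(NA_real_,
             sqrt(colMeans((m[, -1L, drop = FALSE] -
                            m[, -d[4], drop = FALSE])^2)))
  refvol <- rowMeans(m)
  refrms <- sqrt(colMeans((m - refvol)^2))
  flag_metric <- function(x) {
    ok <- !is.na(x)
    mu <- mean(x[ok]); s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    !is.na(x) & x > mu + threshold_sd * s
  }
  structure(list(dvars = dvars, refrms = refrms,
                 flagged = flag_metric(dvars) | flag_metric(refrms),
                 threshold_sd = threshold_sd),
            class = "outlier_flags")
}

#' @export
print.outlier_flags <- function(x, ...) {
  cat(sprintf("outlier flags: %d of %d volumes flagged (threshold %g SD)\n",
              sum(x$flagged), length(x$flagged), x$threshold_sd))
  if (any(x$flagged))
    cat("flagged volumes:", paste(which(x$flagged), collapse = ", "), "\n")
  invisible(x)
}

#' Censored temporal SNR
#'
#' tSNR recomputed over unflagged volumes only. Excluding a flagged volume
#' is equivalent to modelling it with its own delta regressor of no
#' interest, up to degrees-of-freedom bookkeeping (the surviving-volume
#' sample SD uses n_survivors - 1).
#'
#' @param series 4D array.
#' @param flags an [detect_outlier_volumes()] result (or logical vector).
#' @return 3D tSNR array over surviving volumes.
#' @export
censored_tsnr <- function(series, flags) {
  keep <- if (inherits(flags, "outlier_flags")) !flags$flagged else !flags
  stopifnot(length(keep) == dim(series)[4])
  if (sum(keep) < 2L) stop("fewer than 2 unflagged volumes remain")
  if (sum(keep) == 2L)
    warning("only 2 unflagged volumes remain; tSNR is unstable", call. = FALSE)
  tsnr_map(series[, , , keep, drop = FALSE])
}

#' Artificially reconstruct an EPI volume from a reference scan
#'
#' Builds a single volume by taking, for each slice, that slice from the
#' reference volume the selection chose — the reconstruction used to compare
#' shim conditions without reacquiring data. An all-neutral selection simply
#' returns the neutral volume.
#'
#' @param stack a [reference_stack()].
#' @param selection a [zshim_selection()] with one index per stack slice.
#' @return 3D array `[x, y, slice]`.
#' @export
reconstruct_from_reference <- function(stack, selection) {
  stopifnot(inherits(stack, "reference_stack"),
            inherits(selection, "zshim_selection"))
  d <- dim(stack$data)
  if (length(selection$indices) != d[3])
    stop("selection has a different slice count than the stack")
  if (any(selection$indices < 1L) || any(selection$indices > d[4]))
    stop("selection index out of stack range")
  out <- array(0, d[1:3])
  for (s in seq_len(d[3]))
    out[, , s] <- stack$data[, , s, selection$indices[s]]
  out
}

#' Step differences from the neutral setting
#'
#' Per-slice absolute difference between the selected index and the neutral
#' index, plus the fraction of slices in the step-difference categories
#' 0, 1, 2, 3 and >3 — the slice-by-slice characterisation of how much
#' z-shimming each slice needed.
#'
#' @param selection a [zshim_selection()].
#' @param grid grid defining the neutral index (defaults to the selection's).
#' @return List with integer `steps` (per slice) and named `fractions`
#'   (categories `"0", "1", "2", "3", ">3"`, summing to 1).
#' @export
step_difference_profile <- function(selection, grid = selection$grid) {
  stopifnot(inherits(selection, "zshim_selection"),
            inherits(grid, "zshim_grid"))
  steps <- abs(selection$indices - neutral_index(grid))
  cats <- cut(steps, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("0", "1", "2", "3", ">3"))
  fractions <- as.vector(table(cats)) / length(steps)
  names(fractions) <- levels(cats)
  list(steps = as.integer(steps), fractions = fractions)
}

#' Paired percentage difference with bootstrap CI
#'
#' Percentage difference of means between paired conditions,
#' `100 * (mean(a) - mean(b)) / mean(b)`, with a percentile bootstrap 95%
#' confidence interval obtained by resampling the paired units (e.g.
#' participants or replicates) with replacement.
#'
#' @param a,b paired per-unit values (equal length >= 2); `b` is the
#'   reference condition.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param conf confidence level.
#' @return List with `pct_diff`, `ci_low`, `ci_high`, `n_boot`.
#' @export
percent_difference_ci <- function(a, b, n_boot = 10000L, seed = NULL,
                                  conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (mean(b) == 0) stop("reference mean is zero; percentage undefined")
  n <- length(a)
  boots <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    am <- rowMeans(matrix(a[idx], n_boot, n))
    bm <- rowMeans(matrix(b[idx], n_boot, n))
    100 * (am - bm) / bm
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                        na.rm = TRUE)
  list(pct_diff = 100 * (mean(a) - mean(b)) / mean(b),
       ci_low = ci[1], ci_high = ci[2], n_boot = n_boot)
}
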