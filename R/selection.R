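#' Per-slice z-shim selection
#'
#' The common result type of both selection methods: for every EPI slice, the
#' chosen 1-based grid index, the corresponding compensation gradient and
#' gradient moment, plus per-slice warning flags (empty mask, failed fit,
#' clamped out-of-range gradient).
#'
#' @param indices integer vector of 1-based grid indices, one per slice.
#' @param grid the [zshim_grid()] the indices refer to.
#' @param params [acq_params()] (supplies TE for the moments).
#' @param method one of `"epi"`, `"fm_fit"`, `"fm_histogram"`, `"manual"`,
#'   `"neutral"`.
#' @param flags optional character vector of per-slice flags (`""` = clean).
#' @return An object of class `zshim_selection`.
#' @export
zshim_selection <- function(indices, grid, params,
                            method = c("epi", "fm_fit", "fm_histogram",
                                       "manual", "neutral"),
                            flags = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "zshim_grid"), inherits(params, "acq_params"))
  indices <- as.integer(indices)
  if (any(is.na(indices)) || any(indices < 1L) || any(indices > grid$n_steps))
    stop("selection indices out of grid range")
  if (is.null(flags)) flags <- rep("", length(indices))
  stopifnot(length(flags) == length(indices))
  gradients <- gradient_for_index(grid, indices)
  structure(list(indices = indices,
                 gradients = gradients,
                 moments = gradients * params$te,
                 method = method,
                 grid = grid,
                 params = params,
                 flags = flags),
            class = "zshim_selection")
}

#' @export
print.zshim_selection <- function(x, ...) {
  cat(sprintf("z-shim selection (%s method), %d slices\n",
              x$method, length(x$indices)))
  cat("indices:", paste(x$indices, collapse = " "), "\n")
  nflag <- sum(nzchar(x$flags))
  if (nflag > 0L)
    cat(sprintf("%d slice(s) flagged: %s\n", nflag,
                paste(which(nzchar(x$flags)), collapse = ", ")))
  invisible(x)
}

#' @export
summary.zshim_selection <- function(object, ...) {
  sd_prof <- step_difference_profile(object)
  out <- list(method = object$method,
              n_slices = length(object$indices),
              neutral = neutral_index(object$grid),
              step_differences = sd_prof$steps,
              category_fractions = sd_prof$fractions,
              n_flagged = sum(nzchar(object$flags)))
  class(out) <- "summary.zshim_selection"
  out
}

#' @export
print.summary.zshim_selection <- function(x, ...) {
  cat(sprintf("z-shim selection (%s), %d slices, neutral index %d\n",
              x$method, x$n_slices, x$neutral))
  cat("step differences from neutral:\n")
  print(x$category_fractions)
  if (x$n_flagged > 0L) cat(x$n_flagged, "slice(s) flagged\n")
  invisible(x)
}

#' @export
as.data.frame.zshim_selection <- function(x, ...) {
  data.frame(slice = seq_along(x$indices),
             index = x$indices,
             gradient_mT_per_m = x$gradients,
             moment_mT_per_m_ms = x$moments,
             flag = x$flags,
             stringsAsFactors = FALSE)
}

#' @export
plot.zshim_selection <- function(x, ...) {
  n <- length(x$indices)
  plot(seq_len(n), x$indices, type = "b", pch = 16,
       xlab = "EPI slice", ylab = "z-shim index",
       ylim = c(1, x$grid$n_steps),
       main = sprintf("z-shim selection (%s)", x$method), ...)
  abline(h = neutral_index(x$grid), lty = 2, col = "grey50")
  invisible(x)
}

#' All-neutral selection
#'
#' The "no z-shim" condition: every slice at the neutral index.
#'
#' @inheritParams zshim_selection
#' @param n_slices number of slices (defaults to `params$n_slices`).
#' @export
neutral_selection <- function(grid, params, n_slices = params$n_slices) {
  zshim_selection(rep(neutral_index(grid), n_slices), grid, params,
                  method = "neutral")
}
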