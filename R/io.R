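#' Read a NIfTI volume
#'
#' Thin wrapper around [RNifti::readNifti()] returning the data array plus
#' the geometry the package needs. Axis 3 must be the EPI slice axis;
#' inputs in another orientation have to be reoriented upstream — this is
#' asserted by dimensionality only, never silently fixed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param ndim required dimensionality (3 or 4); `NULL` accepts either.
#' @return List with `data` (array) and `voxel_size` (mm, per spatial axis).
#' @export
read_nifti <- function(path, ndim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  nd <- length(dim(data))
  if (!is.null(ndim) && nd != ndim)
    stop(sprintf("%s: expected a %dD image, got %dD", path, ndim, nd))
  if (nd < 3L) stop(sprintf("%s: expected a 3D or 4D image", path))
  pd <- RNifti::pixdim(img)
  list(data = data, voxel_size = as.numeric(pd[1:3]))
}

#' Write an array as NIfTI
#'
#' @param data 3D or 4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size spatial voxel size, mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size,
                           rep(1, length(dim(data)) - 3L))[seq_len(length(dim(data)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the scanner index file
#'
#' The export the z-shim sequence reads back: one 1-based index per line,
#' `n_slices` lines, LF-terminated, nothing else. This is a lossy export
#' (indices only); the JSON record is the canonical output.
#'
#' @param selection a [zshim_selection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_txt <- function(selection, path) {
  stopifnot(inherits(selection, "zshim_selection"))
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(as.character(selection$indices), con, sep = "\n")
  invisible(path)
}

#' Read a scanner index file
#'
#' @param path path to a file written by [write_selection_txt()].
#' @return Integer vector of 1-based indices.
#' @export
read_selection_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("^[0-9]+$", lines)))
    stop(sprintf("%s: non-integer line in selection file", path))
  as.integer(lines)
}

#' Write the canonical JSON selection record
#'
#' @param selection a [zshim_selection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  stopifnot(inherits(selection, "zshim_selection"))
  rec <- list(indices = selection$indices,
              gradients_mT_per_m = selection$gradients,
              moments_mT_per_m_ms = selection$moments,
              method = selection$method,
              grid = list(n_steps = selection$grid$n_steps,
                          g_max_mT_per_m = selection$grid$g_max,
                          ordering = selection$grid$ordering),
              te_ms = selection$params$te,
              flags = selection$flags)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run configuration for the selection workflows
#'
#' Validated container for one selection run. Typically built from a YAML or
#' JSON config file via [read_run_config()].
#'
#' @param method `"epi"`, `"fm_fit"` or `"fm_histogram"`.
#' @param grid [zshim_grid()].
#' @param params [acq_params()].
#' @param stack_path 4D reference-stack NIfTI (EPI method).
#' @param fieldmap_path 3D frequency-offset NIfTI in Hz, or 4D phase NIfTI in
#'   radians with `echo_times_ms` given (FM methods).
#' @param mask_path 3D binary cord-mask NIfTI (on the grid of the input it
#'   is used with).
#' @param out_dir output directory.
#' @param echo_times_ms echo times when `fieldmap_path` is a phase series.
#' @param smooth_sigma_mm,slab_margin_mm,n_bins field-map options.
#' @return An object of class `run_config`.
#' @export
run_config <- function(method = c("epi", "fm_fit", "fm_histogram"),
                       grid = zshim_grid(), params = acq_params(),
                       stack_path = NULL, fieldmap_path = NULL,
                       mask_path = NULL, out_dir = ".",
                       echo_times_ms = NULL, smooth_sigma_mm = 1.0,
                       slab_margin_mm = 2.0, n_bins = 21L) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "zshim_grid"), inherits(params, "acq_params"))
  need <- if (method == "epi") stack_path else fieldmap_path
  if (is.null(need))
    stop(sprintf("method '%s' requires %s", method,
                 if (method == "epi") "'stack_path'" else "'fieldmap_path'"))
  if (is.null(mask_path)) stop("'mask_path' is required")
  for (p in c(need, mask_path))
    if (!file.exists(p)) stop(sprintf("input not found: %s", p))
  structure(list(method = method, grid = grid, params = params,
                 stack_path = stack_path, fieldmap_path = fieldmap_path,
                 mask_path = mask_path, out_dir = out_dir,
                 echo_times_ms = echo_times_ms,
                 smooth_sigma_mm = smooth_sigma_mm,
                 slab_margin_mm = slab_margin_mm, n_bins = as.integer(n_bins)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Expected keys: `method`; `grid: {n_steps, g_max_mT_per_m, ordering}`;
#' `params: {te_ms, slice_thickness_mm, n_slices, slice_spacing_fm_mm}`;
#' `paths: {stack, fieldmap, mask, out_dir}`; optional `echo_times_ms`,
#' `smooth_sigma_mm`, `slab_margin_mm`, `n_bins`.
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  g <- cfg$grid %||% list()
  p <- cfg$params %||% list()
  paths <- cfg$paths %||% list()
  run_config(method = cfg$method %||% "epi",
             grid = zshim_grid(g$n_steps %||% 21L,
                               g$g_max_mT_per_m %||% 0.21,
                               g$ordering %||% "descending"),
             params = acq_params(p$te_ms %||% 40,
                                 p$slice_thickness_mm %||% 5,
                                 p$n_slices %||% 24L,
                                 p$slice_spacing_fm_mm %||% 1),
             stack_path = paths$stack, fieldmap_path = paths$fieldmap,
             mask_path = paths$mask, out_dir = paths$out_dir %||% ".",
             echo_times_ms = cfg$echo_times_ms,
             smooth_sigma_mm = cfg$smooth_sigma_mm %||% 1.0,
             slab_margin_mm = cfg$slab_margin_mm %||% 2.0,
             n_bins = cfg$n_bins %||% 21L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an automated z-shim selection workflow
#'
#' Dispatches to the EPI-reference or field-map pipeline, writes the scanner
#' index file, the JSON selection record and a CSV diagnostic table
#' (intensity matrix or per-slice fit table) into `config$out_dir`, and
#' prints a per-slice report.
#'
#' @param config a [run_config()].
#' @param quiet suppress the report.
#' @return The [zshim_selection()], invisibly; attributes `"report_paths"`
#'   list the files written.
#' @export
run_select <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mask_img <- read_nifti(config$mask_path, ndim = 3L)
  mask <- cord_mask(mask_img$data)
  if (config$method == "epi") {
    st <- read_nifti(config$stack_path, ndim = 4L)
    stack <- reference_stack(st$data, config$grid, config$params)
    imat <- intensity_matrix(stack, mask)
    sel <- select_zshim_epi(imat, config$grid, config$params)
    csv_path <- file.path(config$out_dir, "intensity_matrix.csv")
    utils::write.csv(as.data.frame(imat), csv_path, row.names = FALSE)
  } else {
    fmi <- read_nifti(config$fieldmap_path)
    fm <- if (length(dim(fmi$data)) == 4L) {
      if (is.null(config$echo_times_ms))
        stop("phase-series input requires 'echo_times_ms'")
      ser <- phase_series(fmi$data, config$echo_times_ms,
                          voxel_size = fmi$voxel_size)
      frequency_from_multiecho(ser)
    } else {
      field_map(fmi$data, voxel_size = fmi$voxel_size)
    }
    sel <- zshim_from_fieldmap(fm, mask, config$grid, config$params,
                               estimator = if (config$method == "fm_fit")
                                 "fit" else "histogram",
                               smooth_sigma_mm = config$smooth_sigma_mm,
                               slab_margin_mm = config$slab_margin_mm,
                               n_bins = config$n_bins)
    csv_path <- file.path(config$out_dir, "slice_fits.csv")
    utils::write.csv(as.data.frame(attr(sel, "fits")), csv_path,
                     row.names = FALSE)
  }
  txt_path <- file.path(config$out_dir, "zshim_indices.txt")
  json_path <- file.path(config$out_dir, "zshim_selection.json")
  write_selection_txt(sel, txt_path)
  write_selection_json(sel, json_path)
  if (!quiet) {
    print(sel)
    df <- as.data.frame(sel)
    print(df, row.names = FALSE)
    cat(sprintf("wrote %s, %s, %s\n", txt_path, json_path, csv_path))
    cat(sprintf("elapsed: %.2f s\n",
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  attr(sel, "report_paths") <- c(txt = txt_path, json = json_path,
                                 csv = csv_path)
  invisible(sel)
}
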