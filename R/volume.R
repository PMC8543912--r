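#' Construct a multi-b-value DWI volume
#'
#' A `dwi_volume` wraps a 4D array of signal intensities indexed
#' `(x, y, z, b)` together with its b-value scheme and voxel spacing.  The
#' fourth dimension must match the scheme length.
#'
#' @param data 4D numeric array, non-negative, dims `(nx, ny, nz, nb)`.
#' @param bvalues Numeric b-value scheme (see [validate_bvalues()]).
#' @param spacing Numeric length-3 voxel size in mm per axis, all positive.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, bvalues, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4) {
    stop("`data` must be a 4D array (x, y, z, b)", call. = FALSE)
  }
  validate_bvalues(bvalues)
  if (dim(data)[4] != length(bvalues)) {
    stop("4th dimension of `data` must equal the number of b-values", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) stop("signal intensities must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  }
  structure(
    list(data = data, bvalues = as.numeric(bvalues), spacing = spacing),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dwi_volume> %d x %d x %d voxels, %d b-values (%g-%g s/mm^2), spacing %s mm\n",
    d[1], d[2], d[3], d[4], min(x$bvalues), max(x$bvalues),
    paste(signif(x$spacing, 3), collapse = " x ")
  ))
  invisible(x)
}

#' @export
dim.dwi_volume <- function(x) dim(x$data)

# Extract one 3D b-volume by b-value (exact match).
b_volume <- function(volume, b) {
  i <- match(b, volume$bvalues)
  if (is.na(i)) stop(sprintf("b = %g not present in the scheme", b), call. = FALSE)
  volume$data[, , , i, drop = FALSE][, , , 1]
}

#' Construct a quantitative parameter map
#'
#' One 3D map produced by voxel-wise fitting (or a ground-truth map from the
#' phantom generator), carrying its model and parameter identity, units and
#' voxel spacing.  Voxels that were not fitted (outside the mask, or flagged
#' invalid) are `NA`.
#'
#' @param values 3D numeric array.
#' @param model One of `"ME"`, `"BE_IVIM"`, `"SE"`, `"DKI"`.
#' @param parameter Map name, e.g. `"ADC_all-b"` or `"D*"`; see [map_names()].
#' @param units Unit string, e.g. `"mm^2/s"`.
#' @param spacing Voxel size in mm per axis.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, model, parameter, units, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  model <- match.arg(model, c("ME", "BE_IVIM", "SE", "DKI"))
  structure(
    list(values = values, model = model, parameter = parameter,
         units = units, spacing = as.numeric(spacing)),
    class = "parameter_map"
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<parameter_map> %s / %s [%s], %d x %d x %d, %d fitted voxels, range %s\n",
    x$model, x$parameter, x$units, d[1], d[2], d[3], length(v),
    if (length(v)) paste(signif(range(v), 3), collapse = " .. ") else "-"
  ))
  invisible(x)
}

#' Names and identities of the nine standard parameter maps
#'
#' The map suite comprises nine quantitative maps: ME `ADC_all-b` (fitted on
#' the full scheme) and `ADC_0-1000` (b = 0 and 1000 only), IVIM `D`, `D*`
#' and `f`, SE `DDC` and `alpha`, and DKI `K` and `D_kurt`.
#'
#' @return A tibble with columns `map`, `model`, `parameter`, `units`.
#' @export
map_names <- function() {
  tibble::tibble(
    map = c("ADC_all-b", "ADC_0-1000", "D", "D*", "f", "DDC", "alpha", "K", "D_kurt"),
    model = c("ME", "ME", "BE_IVIM", "BE_IVIM", "BE_IVIM", "SE", "SE", "DKI", "DKI"),
    parameter = c("ADC", "ADC", "D", "Dstar", "f", "DDC", "alpha", "K", "D"),
    units = c("mm^2/s", "mm^2/s", "mm^2/s", "mm^2/s", "1", "mm^2/s", "1", "1", "mm^2/s")
  )
}

#' Read and write DWI data in NIfTI form
#'
#' `read_dwi()` reads a 4D NIfTI file plus a plain-text b-value sidecar (one
#' value per line or one whitespace-separated row, the FSL bval dialect);
#' `write_dwi()` writes them back.  `read_mask()`/`write_mask()` handle 3D
#' binary masks.  Voxel spacing is taken from the NIfTI header.
#'
#' @param nifti_file Path to a `.nii`/`.nii.gz` file.
#' @param bval_file Path to the b-value sidecar.
#' @return `read_dwi()` returns a [dwi_volume()]; `read_mask()` a logical 3D
#'   array with a `spacing` attribute.
#' @name dwi_io
#' @export
read_dwi <- function(nifti_file, bval_file) {
  img <- RNifti::readNifti(nifti_file)
  bvals <- scan(bval_file, quiet = TRUE)
  spacing <- RNifti::pixdim(img)[1:3]
  dwi_volume(unclass(img)[, , , , drop = FALSE], bvals, spacing)
}

#' @rdname dwi_io
#' @param volume A [dwi_volume()].
#' @export
write_dwi <- function(volume, nifti_file, bval_file) {
  img <- RNifti::asNifti(volume$data, reference = NULL)
  RNifti::pixdim(img) <- c(volume$spacing, 1)
  RNifti::writeNifti(img, nifti_file)
  writeLines(paste(format(volume$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_file)
  invisible(c(nifti_file, bval_file))
}

#' @rdname dwi_io
#' @export
read_mask <- function(nifti_file) {
  img <- RNifti::readNifti(nifti_file)
  m <- unclass(img) > 0.5
  dim(m) <- dim(img)[1:3]
  attr(m, "spacing") <- RNifti::pixdim(img)[1:3]
  m
}

#' @rdname dwi_io
#' @param mask Logical or 0/1 3D array.
#' @param spacing Voxel size in mm (used when the mask has no spacing
#'   attribute).
#' @export
write_mask <- function(mask, nifti_file, spacing = attr(mask, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, nifti_file)
  invisible(nifti_file)
}

#' Write a parameter map as NIfTI with a JSON sidecar
#'
#' The sidecar records model, parameter and units so a map directory is
#' self-describing.
#'
#' @param map A [parameter_map()].
#' @param nifti_file Output `.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return The NIfTI path, invisibly.
#' @export
write_parameter_map <- function(map, nifti_file) {
  vals <- map$values
  vals[!is.finite(vals)] <- 0
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, nifti_file)
  side <- sub("\\.nii(\\.gz)?$", ".json", nifti_file)
  jsonlite::write_json(
    list(model = map$model, parameter = map$parameter, units = map$units),
    side, auto_unbox = TRUE
  )
  invisible(nifti_file)
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(nifti_file) {
  img <- RNifti::readNifti(nifti_file)
  side <- sub("\\.nii(\\.gz)?$", ".json", nifti_file)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else
    list(model = "ME", parameter = "ADC", units = "mm^2/s")
  vals <- unclass(img)
  dim(vals) <- dim(img)[1:3]
  parameter_map(vals, meta$model, meta$parameter, meta$units,
                RNifti::pixdim(img)[1:3])
}
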