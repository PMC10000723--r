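#' Multi-contrast MR volume container
#'
#' A `contrast_volume` wraps a 3-D intensity array together with its voxel
#' spacing and a contrast label. Sagittal slices are indexed along
#' `slice_axis` (the third array dimension by default); in-plane rows run
#' cranio-caudal and columns antero-posterior.
#'
#' @param data Numeric 3-D array of intensities (all finite).
#' @param spacing Numeric length-3 vector of mm per voxel, strictly positive.
#'   Order matches the array dimensions.
#' @param contrast One of `"T1"`, `"T2"`, `"T2FS"`, `"SYNTH_T2FS"`.
#' @param slice_axis Index of the sagittal axis (default 3).
#' @return An object of class `contrast_volume`.
#' @export
#' @examples
#' v <- contrast_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 3), contrast = "T1")
#' dim(v$data)
contrast_volume <- function(data, spacing = c(1, 1, 1), contrast = "T1",
                            slice_axis = 3L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array")
  if (!all(is.finite(data))) abort("volume intensities must all be finite")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three strictly positive mm values")
  contrast <- match.arg(contrast, c("T1", "T2", "T2FS", "SYNTH_T2FS"))
  if (!slice_axis %in% 1:3) abort("`slice_axis` must be 1, 2 or 3")
  structure(
    list(data = data, spacing = as.numeric(spacing), contrast = contrast,
         slice_axis = as.integer(slice_axis)),
    class = "contrast_volume"
  )
}

#' @export
print.contrast_volume <- function(x, ...) {
  cat(sprintf("<contrast_volume %s  %s voxels  %s mm>\n", x$contrast,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.contrast_volume <- function(x) dim(x$data)

n_slices <- function(vol) dim(vol$data)[vol$slice_axis]

get_slice <- function(vol, i) {
  switch(vol$slice_axis,
         vol$data[i, , ],
         vol$data[, i, ],
         vol$data[, , i])
}

set_slice <- function(vol, i, m) {
  switch(vol$slice_axis,
         vol$data[i, , ] <- m,
         vol$data[, i, ] <- m,
         vol$data[, , i] <- m)
  vol
}

inplane_axes <- function(vol) setdiff(1:3, vol$slice_axis)

#' Read or write a contrast volume as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry spacing and the contrast label (stored in the NIfTI description
#' field on write, recovered on read when present).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param contrast Contrast label to attach on read if none is stored.
#' @param slice_axis Sagittal axis index on read.
#' @return `read_contrast_volume()` returns a [contrast_volume()];
#'   `write_contrast_volume()` returns `path` invisibly.
#' @export
read_contrast_volume <- function(path, contrast = "T1", slice_axis = 3L) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  desc <- RNifti::niftiHeader(img)$descrip
  if (is.character(desc) && desc %in% c("T1", "T2", "T2FS", "SYNTH_T2FS"))
    contrast <- desc
  contrast_volume(array(as.numeric(img), dim = dim(img)),
                  spacing = as.numeric(pix[1:3]),
                  contrast = contrast, slice_axis = slice_axis)
}

#' @rdname read_contrast_volume
#' @param vol A [contrast_volume()].
#' @export
write_contrast_volume <- function(vol, path) {
  dat <- vol$data
  attr(dat, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(dat, datatype = "double")
  img <- RNifti::asNifti(img, reference = list(descrip = vol$contrast))
  RNifti::writeNifti(img, path)
  invisible(path)
}
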