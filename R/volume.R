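#' Bundle a 3D intensity volume with a binary region of interest
#'
#' The unit of feature extraction: a scalar 3D grid (e.g. CT intensities in
#' Hounsfield units), a binary mask delineating the region of interest (ROI),
#' and the physical voxel spacing in millimetres. Spacing may be anisotropic,
#' as is typical for CT (in-plane resolution finer than slice thickness).
#'
#' @param intensity Numeric 3D array of voxel intensities.
#' @param mask Logical (or 0/1) array with the same dimensions; `TRUE` marks
#'   ROI voxels. Must contain at least one foreground voxel.
#' @param spacing Numeric length-3 vector, voxel spacing in mm along each
#'   array dimension.
#' @return An object of class `volume_with_mask`: a list with elements
#'   `intensity`, `mask` (logical array) and `spacing`.
#' @examples
#' vol <- array(rnorm(4^3, 50, 10), c(4, 4, 4))
#' msk <- array(TRUE, c(4, 4, 4))
#' vm <- volume_with_mask(vol, msk, spacing = c(1, 1, 3))
#' @export
volume_with_mask <- function(intensity, mask, spacing = c(1, 1, 1)) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("`intensity` must be a 3D array", call. = FALSE)
  if (is.numeric(mask)) mask <- array(mask != 0, dim(mask))
  if (!is.logical(mask)) stop("`mask` must be logical or 0/1", call. = FALSE)
  if (!identical(dim(intensity), dim(mask)))
    stop("`intensity` and `mask` dimensions differ", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  if (!any(mask)) stop("mask is empty: no ROI voxels", call. = FALSE)
  structure(list(intensity = intensity, mask = mask, spacing = spacing),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<volume_with_mask> grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm, %d ROI voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$mask)))
  invisible(x)
}

#' Intensities of the masked voxels
#'
#' @param vm A [volume_with_mask()] object.
#' @return Numeric vector of ROI voxel intensities.
#' @export
masked_values <- function(vm) {
  stopifnot(inherits(vm, "volume_with_mask"))
  vm$intensity[vm$mask]
}

#' Read an image/mask NIfTI pair as a volume with mask
#'
#' Voxel spacing is taken from the image header (`pixdim`); the mask is
#' binarised at 0.5.
#'
#' @param image_path,mask_path Paths to NIfTI files (.nii or .nii.gz).
#' @return A [volume_with_mask()] object.
#' @export
read_volume_with_mask <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  volume_with_mask(array(as.numeric(img), dim(img)[seq_len(3)]),
                   array(as.numeric(msk) > 0.5, dim(msk)[seq_len(3)]),
                   spacing)
}

#' Write a volume with mask as a NIfTI pair
#'
#' @param vm A [volume_with_mask()] object.
#' @param image_path,mask_path Output NIfTI paths.
#' @return Invisibly, the two paths.
#' @export
write_volume_nifti <- function(vm, image_path, mask_path) {
  stopifnot(inherits(vm, "volume_with_mask"))
  img <- RNifti::asNifti(vm$intensity)
  RNifti::pixdim(img) <- vm$spacing
  msk <- RNifti::asNifti(array(as.integer(vm$mask), dim(vm$mask)))
  RNifti::pixdim(msk) <- vm$spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}
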