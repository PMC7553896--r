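# Shape features: volume (mesh and voxel counting), surface area, sphericity.

#' Voxel-counting volume of a mask
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param spacing Numeric length-3 voxel spacing (mm).
#' @return Foreground voxel count times the voxel volume, in mm^3.
#' @examples
#' voxel_volume(array(c(rep(1, 10), rep(0, 17)), c(3, 3, 3)), c(1, 1, 3))
#' @export
voxel_volume <- function(mask, spacing = c(1, 1, 1)) {
  if (is.numeric(mask)) mask <- mask != 0
  sum(mask) * prod(as.numeric(spacing))
}

#' Sphericity from volume and surface area
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A`: exactly 1 for a sphere and smaller
#' for any other shape. Computed from the mesh-based volume and area in the
#' feature pipeline.
#'
#' @param volume Volume in mm^3 (> 0).
#' @param area Surface area in mm^2 (> 0).
#' @return Dimensionless sphericity.
#' @examples
#' r <- 7
#' sphericity(4 / 3 * pi * r^3, 4 * pi * r^2)  # exactly 1
#' sphericity(10^3, 6 * 10^2)                  # cube: (pi/6)^(1/3)
#' @export
sphericity <- function(volume, area) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be > 0", call. = FALSE)
  if (!is.finite(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Shape features of a masked volume
#'
#' Triangulates the mask surface ([mask_to_mesh()]) and reports the mesh
#' volume, mesh surface area, sphericity (from the mesh quantities) and the
#' voxel-counting volume. The mesh volume is the canonical `volume` feature;
#' the voxel-counting volume is reported alongside as `volume_voxel`.
#'
#' @param vm A [volume_with_mask()] (only mask and spacing are used).
#' @param smooth_iterations Passed to [mask_to_mesh()].
#' @return Named list: `volume`, `volume_voxel`, `area`, `sphericity`.
#' @export
shape_features <- function(vm, smooth_iterations = 80L) {
  stopifnot(inherits(vm, "volume_with_mask"))
  mesh <- mask_to_mesh(vm$mask, vm$spacing, smooth_iterations)
  v <- mesh_volume(mesh, check = FALSE)
  a <- mesh_area(mesh)
  list(volume = v,
       volume_voxel = voxel_volume(vm$mask, vm$spacing),
       area = a,
       sphericity = sphericity(v, a))
}
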