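#' Calibrated 3D intensity volume
#'
#' Container for a single-channel confocal stack.  Voxels are stored in
#' z-y-x order: `intensities[z, y, x]`, 1-based in R, with `voxel_size_um`
#' giving the physical edge lengths `(dz, dy, dx)` in micrometers.
#'
#' @param intensities numeric 3D array, finite and non-negative.
#' @param voxel_size_um numeric length-3 `(dz, dy, dx)`, all positive.
#' @param channel character label of the stained channel (e.g. `"WGA"`).
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size_um, channel = "WGA") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (z, y, x)")
  if (!all(is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 positive numbers (dz, dy, dx)")
  structure(
    list(intensities = intensities,
         voxel_size_um = voxel_size_um,
         channel = as.character(channel)[1L]),
    class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "voxel_stack: %d x %d x %d voxels (z-y-x), %.3g x %.3g x %.3g um, channel '%s'\n",
    d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
    x$voxel_size_um[3], x$channel))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$intensities)

is_voxel_stack <- function(x) inherits(x, "voxel_stack")

#' Segmentation masks of a membrane-stained stack
#'
#' Holds the boolean partition of a stack into membrane signal, cell
#' interior, t-tubules and surface sarcolemma.  The t-tubule mask is the
#' part of the membrane signal inside the (eroded) cell; the surface mask
#' is the membrane signal in the boundary shell; the two are disjoint.
#'
#' @param membrane_mask,cell_mask,tubule_mask,surface_mask logical arrays
#'   of one common dimension.
#' @return An object of class `segmentation_masks`.
#' @export
segmentation_masks <- function(membrane_mask, cell_mask, tubule_mask,
                               surface_mask) {
  d <- dim(membrane_mask)
  for (m in list(cell_mask, tubule_mask, surface_mask))
    if (!identical(dim(m), d)) stop("all masks must share one dimension")
  if (any(tubule_mask & !(membrane_mask & cell_mask)))
    stop("tubule_mask must be a subset of membrane_mask & cell_mask")
  if (any(tubule_mask & surface_mask))
    stop("tubule_mask and surface_mask must be disjoint")
  structure(
    list(membrane_mask = membrane_mask, cell_mask = cell_mask,
         tubule_mask = tubule_mask, surface_mask = surface_mask),
    class = "segmentation_masks")
}

#' Anisotropy-aware Euclidean distance transform
#'
#' Exact 3D Euclidean distance (in micrometers) from every voxel to the
#' nearest `TRUE` voxel of `mask`, honouring anisotropic voxel sizes.
#' Computed by the separable lower-envelope (parabola) algorithm, one pass
#' per axis.
#'
#' @param mask logical 3D array of feature voxels.
#' @param voxel_size_um numeric length-3 voxel edge lengths `(dz, dy, dx)`.
#' @return Numeric array of distances (um), `Inf` if `mask` is empty.
#' @export
distance_transform <- function(mask, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  d2 <- cpp_edt_sq(as.logical(mask), dim(mask), voxel_size_um)
  out <- sqrt(d2)
  out[out > 1e14] <- Inf
  array(out, dim(mask))
}
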