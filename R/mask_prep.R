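#' Morphological closing of an airway mask
#'
#' Closing (dilation followed by erosion) with a spherical structuring
#' element, used to re-connect airway segments that were disconnected by the
#' segmentation step. The element radius is given in millimetres and
#' converted per axis to voxels (rounded up, minimum 1 voxel), so the element
#' is an ellipsoid in voxel space but a sphere in world space.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm element radius in mm; \code{0} returns the input
#'   unchanged. The default closes over a 1-voxel gap (radius = smallest
#'   voxel dimension).
#' @return A \code{binary_mask}.
#' @export
morphological_close <- function(mask, radius_mm = min(mask$spacing)) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  if (radius_mm == 0) return(mask)
  rvox <- pmax(1L, as.integer(ceiling(radius_mm / mask$spacing)))
  dims <- dim(mask$data)
  d <- cpp_dilate(as.logical(mask$data), dims, rvox)
  e <- cpp_erode(d, dims, rvox)
  out <- mask
  out$data <- array(e, dim = dims)
  out
}

#' Keep the largest connected component
#'
#' Retains only the largest 26-connected foreground component of the mask
#' (the airway tree), discarding disconnected islands. Ties in size are
#' broken in favour of the component containing the lowest voxel index
#' (column-major raster order), which makes the operation deterministic.
#'
#' @param mask a [binary_mask()].
#' @return A \code{binary_mask} with a single connected component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  dims <- dim(mask$data)
  lab <- cpp_label_components(as.logical(mask$data), dims)
  if (all(lab == 0L)) stop("mask contains no foreground voxels")
  sizes <- tabulate(lab)
  # labels are issued in raster-seed order, so which.max picks the component
  # with the lowest seed index among equally sized ones
  keep <- which.max(sizes)
  out <- mask
  out$data <- array(lab == keep, dim = dims)
  out
}
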