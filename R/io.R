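#' In-memory CT volume
#'
#' Container for a 3D scalar grid in Hounsfield units on a regular,
#' axis-aligned voxel lattice. All downstream geometry is computed in world
#' millimetres: the world position of voxel \code{(i, j, k)} (0-based) is
#' \code{origin + c(i, j, k) * spacing}.
#'
#' Axis convention: after loading, volumes are reoriented so that the first
#' axis increases towards the patient's Right, the second towards Anterior,
#' and the third towards Superior ("RAS"). The lobe classifier and the
#' trachea-seed heuristic rely on this fixed convention.
#'
#' @param data 3D numeric array (HU).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world mm position of voxel (0,0,0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values, got: ",
         paste(spacing, collapse = ", "))
  if (any(!is.finite(data)))
    stop("volume contains non-finite values (NaN/Inf)")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), axis_codes = "RAS"),
            class = "image_volume")
}

#' Binary airway mask co-registered to a CT volume
#'
#' @param data 3D array; any non-zero voxel is foreground.
#' @param spacing,origin as in [image_volume()].
#' @param reference optional \code{image_volume}; when given, grid shape and
#'   spacing must match (spacing within 1e-3 mm).
#' @return An object of class \code{binary_mask} whose \code{data} is a
#'   logical array.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0), reference = NULL) {
  if (length(dim(data)) != 3L)
    stop("mask must be a 3D array")
  if (!is.null(reference)) {
    if (!identical(dim(data), dim(reference$data)))
      stop("mask grid ", paste(dim(data), collapse = "x"),
           " does not match reference grid ",
           paste(dim(reference$data), collapse = "x"))
    if (any(abs(as.numeric(spacing) - reference$spacing) > 1e-3))
      stop("mask spacing (", paste(spacing, collapse = ", "),
           ") does not match reference spacing (",
           paste(reference$spacing, collapse = ", "), ") within 1e-3 mm")
  }
  m <- array(data != 0, dim = dim(data))
  if (!any(m)) stop("mask contains no foreground voxels")
  structure(list(data = m, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axis_codes = "RAS"),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(format(x$spacing), collapse = " x "), "mm (RAS)\n")
  cat("  HU range:", paste(format(range(x$data)), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(dim(x$data), collapse = " x "),
      "voxels,", sum(x$data), "foreground\n")
  invisible(x)
}

.nifti_geometry <- function(img) {
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  orig <- if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  list(spacing = as.numeric(sp), origin = orig)
}

.read_ras <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI image, got ", length(dim(img)),
         " dimensions in ", path)
  code <- attr(RNifti::xform(img), "code")
  if (!is.null(code) && code > 0 && RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  img
}

#' Load a CT volume from NIfTI
#'
#' Reads a 3D NIfTI image, reorients it to canonical RAS axis order, and
#' returns an [image_volume()] with spacing/origin taken from the header.
#' Voxel values (HU) are not rescaled.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An \code{image_volume}.
#' @export
load_volume <- function(path) {
  img <- .read_ras(path)
  g <- .nifti_geometry(img)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = g$spacing, origin = g$origin)
}

#' Load a binary airway mask from NIfTI
#'
#' Any non-zero label is mapped to foreground. The mask must be voxel-aligned
#' with the reference volume: identical grid shape and spacing within
#' 1e-3 mm. No resampling is performed.
#'
#' @param path path to the mask NIfTI.
#' @param reference the paired [image_volume()].
#' @return A \code{binary_mask}.
#' @export
load_mask <- function(path, reference) {
  img <- .read_ras(path)
  g <- .nifti_geometry(img)
  binary_mask(array(as.numeric(img), dim = dim(img)),
              spacing = g$spacing, origin = g$origin, reference = reference)
}

#' Write a volume or mask to NIfTI
#'
#' @param x an \code{image_volume} or \code{binary_mask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- if (inherits(x, "binary_mask")) array(as.integer(x$data),
                                               dim = dim(x$data)) else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  xf <- diag(c(x$spacing, 1))
  xf[1:3, 4] <- x$origin
  attr(xf, "code") <- 2L
  RNifti::`qform<-`(img, xf) -> img
  RNifti::`sform<-`(img, xf) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Display windowing of HU values
#'
#' Linear window/level display transform used for standardised airway
#' viewing: HU at or below \code{level - width/2} map to 0, at or above
#' \code{level + width/2} to 1, linearly in between. Defaults are the
#' standard airway window (level -500 HU, width 1500 HU).
#'
#' @param volume an \code{image_volume} (or plain numeric array).
#' @param level window centre in HU.
#' @param width window width in HU; must be > 0.
#' @return array of the same shape, scaled to \code{[0, 1]}.
#' @export
apply_display_window <- function(volume, level = -500, width = 1500) {
  if (width <= 0) stop("window width must be > 0, got ", width)
  dat <- if (inherits(volume, "image_volume")) volume$data else volume
  pmin(pmax((dat - (level - width / 2)) / width, 0), 1)
}

# world-mm coordinates of 0-based voxel indices (n x 3 matrix)
.voxel_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
}
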