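#' Construct a 3D image stack with physical voxel sizes
#'
#' An `image_stack` is the raw confocal input: a 3D grid of non-negative
#' intensities indexed `[x, y, z]` together with the physical voxel size in
#' micrometres per axis. The default voxel sizes correspond to a typical
#' high-NA confocal acquisition (0.089 µm laterally, 0.313 µm axially), where
#' the axial step is coarser than the lateral pixel.
#'
#' @param data numeric 3D array, dimensions ordered (x, y, z); all values
#'   must be finite and non-negative.
#' @param voxel_size numeric length-3, µm per voxel along (x, y, z).
#' @return An object of class `image_stack` with elements `data` and
#'   `voxel_size`.
#' @export
image_stack <- function(data, voxel_size = c(0.089, 0.089, 0.313)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array ordered (x, y, z)")
  if (any(dim(data) < 3L))
    stop("stack must have at least 3 voxels per axis")
  if (anyNA(data) || any(data < 0))
    stop("intensities must be finite and non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (µm)")
  structure(list(data = data, voxel_size = voxel_size), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, voxel size %.3f/%.3f/%.3f um (x/y/z)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Define a rectangular membrane region of interest inside a stack
#'
#' A `membrane_roi` selects an axis-aligned sub-volume containing one cell
#' membrane, declares the projection axis (the membrane-normal direction along
#' which the maximum-intensity projection is taken) and carries a polarity
#' label. Bounds are 0-based and half-open, i.e. voxel indices
#' `start <= i < end` along each axis.
#'
#' @param id character label for the ROI.
#' @param bounds integer 3x2 matrix (rows x/y/z, columns start/end), 0-based
#'   half-open.
#' @param projection_axis one of `"x"`, `"y"`, `"z"`: axis collapsed by the
#'   maximum-intensity projection.
#' @param polarity_label one of `"apical"`, `"basal"`, `"lateral"`,
#'   `"unspecified"`.
#' @param cell_id optional cell identifier for per-cell aggregation.
#' @return An object of class `membrane_roi`.
#' @export
membrane_roi <- function(id, bounds, projection_axis = c("z", "x", "y"),
                         polarity_label = c("unspecified", "apical", "basal", "lateral"),
                         cell_id = NA_character_) {
  projection_axis <- match.arg(projection_axis)
  polarity_label <- match.arg(polarity_label)
  bounds <- matrix(as.integer(round(bounds)), nrow = 3L, ncol = 2L,
                   dimnames = list(c("x", "y", "z"), c("start", "end")))
  if (anyNA(bounds) || any(bounds[, 1] < 0L) || any(bounds[, 2] <= bounds[, 1]))
    stop("`bounds` must be a 3x2 matrix of 0-based half-open indices with end > start")
  structure(list(id = as.character(id), bounds = bounds,
                 projection_axis = projection_axis,
                 polarity_label = polarity_label,
                 cell_id = as.character(cell_id)),
            class = "membrane_roi")
}

#' @export
print.membrane_roi <- function(x, ...) {
  cat(sprintf("<membrane_roi> %s: x[%d,%d) y[%d,%d) z[%d,%d), project along %s, %s\n",
              x$id, x$bounds[1, 1], x$bounds[1, 2], x$bounds[2, 1], x$bounds[2, 2],
              x$bounds[3, 1], x$bounds[3, 2], x$projection_axis, x$polarity_label))
  invisible(x)
}

.axis_index <- function(axis) match(axis, c("x", "y", "z"))

.check_roi_in_stack <- function(stack, roi) {
  d <- dim(stack$data)
  if (any(roi$bounds[, 2] > d))
    stop(sprintf("ROI '%s' exceeds stack dimensions", roi$id))
  invisible(TRUE)
}

#' Construct a 2D plane image (e.g. a maximum-intensity projection)
#'
#' @param intensities numeric matrix of pixel intensities.
#' @param pixel_size numeric length-2, µm per pixel along the two in-plane
#'   axes (rows, columns of `intensities`).
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(intensities, pixel_size) {
  if (!is.matrix(intensities)) stop("`intensities` must be a matrix")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (length(pixel_size) != 2L || any(!is.finite(pixel_size)) || any(pixel_size <= 0))
    stop("`pixel_size` must be 1 or 2 positive values (µm)")
  structure(list(intensities = intensities, pixel_size = pixel_size),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("<plane_image> %d x %d px, pixel size %.3f x %.3f um\n",
              nrow(x$intensities), ncol(x$intensities),
              x$pixel_size[1], x$pixel_size[2]))
  invisible(x)
}
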