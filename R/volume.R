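# Voxelized image container for the MLEM estimate.

#' Image volume
#'
#' Container for the voxelized activity estimate. Values are stored as a 3D
#' array indexed (x, y, z), x fastest. Voxel indexing is 0-based half-open in
#' the on-disk sidecar convention; the world coordinate of voxel center
#' (i, j, k) (0-based) is `origin + (i + 1/2, j + 1/2, k + 1/2) * voxel_mm`.
#' The default grid is 40 x 40 x 40 voxels of 1 mm^3 centered on the origin.
#'
#' @param values 3D array of nonnegative voxel values (or a scalar to fill).
#' @param dims integer length-3 grid dimensions.
#' @param voxel_mm voxel edge length, mm.
#' @param origin world coordinate of the grid's low corner, mm.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values = 1, dims = c(40L, 40L, 40L), voxel_mm = 1,
                         origin = -dims * voxel_mm / 2) {
  dims <- as.integer(dims)
  if (length(values) == 1) values <- array(values, dim = dims)
  stopifnot(all(dim(values) == dims), all(values >= 0), voxel_mm > 0)
  structure(list(values = values, dims = dims, voxel_mm = voxel_mm,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Voxel center coordinates along one axis
#' @param volume an [image_volume()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel center world coordinates, mm.
#' @export
voxel_centers <- function(volume, axis) {
  volume$origin[axis] + (seq_len(volume$dims[axis]) - 0.5) * volume$voxel_mm
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %d x %d x %d voxels of %g mm, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_mm,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  total %.6g, max %.6g at voxel (%s)\n",
              sum(x$values), max(x$values),
              paste(which(x$values == max(x$values), arr.ind = TRUE)[1, ],
                    collapse = ", ")))
  invisible(x)
}

# grid spec passed to the C++ projectors
vol_spec <- function(volume) {
  list(dims = as.integer(volume$dims), origin = as.numeric(volume$origin),
       voxel = as.numeric(volume$voxel_mm))
}
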