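#' Voxel geometry of a co-registered study grid
#'
#' Describes the shared 3-D grid of a study: in-plane voxel edge length,
#' slice thickness, and grid dimensions. All volumes and masks of one study
#' live on a single grid; no resampling happens inside this package.
#' Indexing is 1-based `(row, col, slice)` in R's column-major arrays.
#'
#' @param in_plane In-plane voxel edge length in mm (square voxels).
#' @param thickness Slice thickness in mm.
#' @param dim Integer vector `(rows, cols, slices)`.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry(0.5, 1, c(64, 64, 10))
#' voxel_volume_ul(g)  # 0.25 uL per voxel
#' @export
voxel_geometry <- function(in_plane, thickness, dim) {
  stopifnot(length(in_plane) == 1, length(thickness) == 1, length(dim) == 3)
  if (in_plane <= 0 || thickness <= 0)
    stop("voxel spacings must be > 0")
  dim <- as.integer(dim)
  if (any(dim < 1)) stop("grid dimensions must be >= 1")
  structure(list(in_plane = as.numeric(in_plane),
                 thickness = as.numeric(thickness),
                 dim = dim),
            class = "voxel_geometry")
}

#' Volume of a single voxel in microlitres
#'
#' 1 mm^3 equals 1 uL, so the voxel volume is `in_plane^2 * thickness`.
#'
#' @param geometry A [voxel_geometry()].
#' @return Voxel volume in uL.
#' @export
voxel_volume_ul <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$in_plane^2 * geometry$thickness
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d x %d x %d grid, %.3g x %.3g x %.3g mm (%.3g uL/voxel)\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$in_plane, x$in_plane, x$thickness, voxel_volume_ul(x)))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$in_plane, b$in_plane)) &&
    isTRUE(all.equal(a$thickness, b$thickness)) &&
    identical(a$dim, b$dim)
}

check_same_geometry <- function(a, b, what = "objects") {
  if (!same_geometry(a, b))
    stop("geometry mismatch between ", what, " (co-registration is assumed)")
  invisible(TRUE)
}
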