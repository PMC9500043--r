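#' Physical sampling grid of a 3-D volume
#'
#' A `grid3d` describes the geometry of a regularly sampled 3-D volume:
#' array dimensions, voxel spacing in mm, and the world position of the
#' centre of voxel `(0,0,0)`. All volumes in the package are canonicalized
#' to a fixed axis order compatible with the Allen Common Coordinate
#' Framework: index axis 1 runs anterior to posterior (AP), axis 2 superior
#' to inferior (DV), axis 3 left to right (ML). World coordinates are
#' measured in mm along these axes, so `world = origin + index * spacing`
#' (0-based indices, voxel-centre convention, no shear).
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#'   A single value is recycled.
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of voxel (0,0,0). Default `c(0,0,0)`.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(round(shape))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be 3 positive reals (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid origin must be 3 finite reals (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axes = c("AP", "DV", "ML")),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels (%s)\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(x$axes, collapse = ", ")))
  cat(sprintf("  spacing: %s mm   extent: %s mm\n",
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$shape * x$spacing), collapse = " x ")))
  cat(sprintf("  origin:  (%s) mm\n", paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a grid
#'
#' @param grid a [grid3d()].
#' @return numeric length-3 vector, `shape * spacing` in mm per axis.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [grid3d()].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- rbind_coerce(idx)
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Convert world coordinates to (fractional, 0-based) voxel indices
#'
#' @param grid a [grid3d()].
#' @param xyz numeric matrix (n x 3) of world coordinates in mm, or a
#'   length-3 vector.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_coerce(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L) else x
}

#' World coordinates of every voxel centre
#'
#' @param grid a [grid3d()].
#' @return an n x 3 matrix (n = prod(shape)) in array (column-major) order.
#' @export
grid_coordinates <- function(grid) {
  n <- grid$shape
  i <- (seq_len(n[1]) - 1)
  j <- (seq_len(n[2]) - 1)
  k <- (seq_len(n[3]) - 1)
  cbind(rep(i, times = n[2] * n[3]) * grid$spacing[1] + grid$origin[1],
        rep(rep(j, each = n[1]), times = n[3]) * grid$spacing[2] + grid$origin[2],
        rep(k, each = n[1] * n[2]) * grid$spacing[3] + grid$origin[3])
}

#' Physical bounding box
#'
#' Bounding boxes carry the physical extent of a working volume. Two named
#' boxes matter for atlas work in the Allen reference space: the native
#' Allen box and an extended box that leaves room for extra-cerebral
#' structures (skull, soft tissue) that CT-based alignment relies on.
#' Extents are in canonical (AP, DV, ML) axis order.
#'
#' @param extent numeric length-3, mm per axis (AP, DV, ML).
#' @param notes free-text provenance tag.
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(extent, notes = "") {
  extent <- as.numeric(extent)
  if (length(extent) != 3L || any(!is.finite(extent)) || any(extent <= 0))
    stop("bounding box extent must be 3 positive reals (mm)")
  structure(list(extent = extent, notes = notes), class = "bounding_box")
}

#' @rdname bounding_box
#' @details `ara_native_box()` is the Allen reference volume's own extent,
#'   13.2 x 8.0 x 11.4 mm (AP, DV, ML); `extended_head_box()` is the
#'   enlarged working box, 16.1 x 9.6 x 12.1 mm, which contains the native
#'   box on every axis.
#' @export
ara_native_box <- function() bounding_box(c(13.2, 8.0, 11.4), "ARA native")

#' @rdname bounding_box
#' @export
extended_head_box <- function() bounding_box(c(16.1, 9.6, 12.1), "extended head box")

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> %s mm (AP x DV x ML)%s\n",
              paste(format(x$extent), collapse = " x "),
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}
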