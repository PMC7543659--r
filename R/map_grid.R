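#' Construct a MapGrid volume
#'
#' A `mapgrid` is the universal real-space carrier in this package: a real-valued
#' 3-D volume on an orthogonal grid, with a voxel size and an origin giving the
#' absolute position (in Angstrom) of grid point (0,0,0).
#'
#' @param values Numeric 3-D array of map values (arbitrary potential units).
#' @param voxel Numeric length-3 vector of voxel edge lengths in Angstrom
#'   (a scalar is recycled).
#' @param origin Numeric length-3 vector, Angstrom offset of grid point
#'   (0,0,0). Defaults to `c(0, 0, 0)`.
#' @return An object of class `mapgrid` with fields `values`, `voxel`, `origin`.
#' @examples
#' m <- map_grid(array(0, c(8, 8, 8)), voxel = 1)
#' map_dims(m)
#' @export
map_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (any(dim(values) < 4L))
    stop("each grid dimension must be at least 4")
  if (!all(is.finite(values)))
    stop("map values must all be finite")
  voxel <- rep_len(as.numeric(voxel), 3L)
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("voxel sizes must be positive and finite")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(values = values, voxel = voxel, origin = origin),
            class = "mapgrid")
}

#' Grid dimensions of a MapGrid or FourierMap
#' @param m A `mapgrid` or `fouriermap`.
#' @return Integer vector of length 3.
#' @export
map_dims <- function(m) {
  if (inherits(m, "fouriermap")) return(dim(m$terms))
  dim(m$values)
}

#' Test whether two volumes share the same grid
#'
#' Two grids are "aligned" iff dimensions, voxel size and origin match exactly.
#'
#' @param a,b `mapgrid` or `fouriermap` objects.
#' @return Logical scalar.
#' @export
is_aligned <- function(a, b) {
  identical(map_dims(a), map_dims(b)) &&
    isTRUE(all(a$voxel == b$voxel)) &&
    isTRUE(all(a$origin == b$origin))
}

stop_if_misaligned <- function(a, b, what = "maps") {
  if (!is_aligned(a, b)) stop(what, " are not aligned (dims/voxel/origin differ)")
  invisible(TRUE)
}

#' @export
print.mapgrid <- function(x, ...) {
  d <- map_dims(x)
  cat(sprintf("<mapgrid> %d x %d x %d, voxel %.4g x %.4g x %.4g A\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) A; value range [%.4g, %.4g], mean %.4g\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# Absolute Angstrom coordinates of every grid point along one axis.
axis_coords <- function(m, axis) {
  n <- map_dims(m)[axis]
  m$origin[axis] + (seq_len(n) - 1) * m$voxel[axis]
}

# Distance (A) of each grid point from the geometric center of the box,
# returned as an array aligned with m$values.
center_distance <- function(m) {
  d <- map_dims(m)
  cx <- (d - 1) / 2 * m$voxel
  ax <- ((seq_len(d[1]) - 1) * m$voxel[1] - cx[1])^2
  ay <- ((seq_len(d[2]) - 1) * m$voxel[2] - cx[2])^2
  az <- ((seq_len(d[3]) - 1) * m$voxel[3] - cx[3])^2
  sqrt(outer(outer(ax, ay, "+"), az, "+"))
}

#' Replace the values of a MapGrid, keeping its geometry
#' @param m A `mapgrid`.
#' @param values Replacement array of the same dimensions.
#' @return A `mapgrid`.
#' @export
with_values <- function(m, values) {
  map_grid(values, m$voxel, m$origin)
}
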