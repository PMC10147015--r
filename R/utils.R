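# Internal geometry / array helpers.
#
# Conventions used package-wide:
#  * channel arrays have dim = c(nz, ny, nx)  (slice, row, column);
#  * voxel sizes are (vz, vy, vx) in micrometres;
#  * the physical coordinate of voxel (k, j, i) (1-based) is
#    ((i - 0.5) * vx, (j - 0.5) * vy, (k - 0.5) * vz), reported as (x, y, z);
#  * all geometry downstream of the rasterizer is in physical micrometres and
#    never assumes isotropic voxels.

`%||%` <- function(a, b) if (is.null(a)) b else a

.normalize01 <- function(x) {
  r <- range(x)
  if (r[2] <= r[1]) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Min-max normalize a channel to [0, 1]
#'
#' @param ch numeric 3D array.
#' @return array of the same shape with range [0, 1] (all zeros if constant).
#' @export
normalizeChannel <- function(ch) {
  out <- .normalize01(ch)
  dim(out) <- dim(ch)
  out
}

# physical (x,y,z) of 1-based voxel (k,j,i)
.voxelCenter <- function(kji, voxel) {
  cbind(x = (kji[, 3] - 0.5) * voxel[3],
        y = (kji[, 2] - 0.5) * voxel[2],
        z = (kji[, 1] - 0.5) * voxel[1])
}

# 1-based (k,j,i) of physical points (x,y,z), clamped into the array
.voxelOf <- function(xyz, dims, voxel) {
  xyz <- matrix(xyz, ncol = 3)
  k <- pmin(pmax(ceiling(xyz[, 3] / voxel[1]), 1L), dims[1])
  j <- pmin(pmax(ceiling(xyz[, 2] / voxel[2]), 1L), dims[2])
  i <- pmin(pmax(ceiling(xyz[, 1] / voxel[3]), 1L), dims[3])
  cbind(k = as.integer(k), j = as.integer(j), i = as.integer(i))
}

# 0-based linear index for the C++ side (integer: grids stay below 2^31)
.linearIndex0 <- function(kji, dims) {
  as.integer((kji[, 1] - 1L) +
               dims[1] * ((kji[, 2] - 1L) + dims[2] * (kji[, 3] - 1L)))
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# Rodrigues rotation of v by angle about (unit) axis
.rotate <- function(v, angle, axis) {
  axis <- .unit(axis)
  v * cos(angle) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# an arbitrary unit vector perpendicular to dir
.perp <- function(dir) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(c(dir[2] * ref[3] - dir[3] * ref[2],
          dir[3] * ref[1] - dir[1] * ref[3],
          dir[1] * ref[2] - dir[2] * ref[1]))
}

# Resample a polyline (rows = points xyz) so consecutive points are at most
# `spacing` apart; keeps original vertices.
.resamplePolyline <- function(pts, spacing) {
  if (nrow(pts) < 2) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (e in seq_len(nrow(pts) - 1)) {
    p <- pts[e, ]; q <- pts[e + 1, ]
    len <- sqrt(sum((q - p)^2))
    nsub <- max(1L, ceiling(len / spacing))
    ts <- seq_len(nsub) / nsub
    out[[e + 1]] <- cbind(p[1] + ts * (q[1] - p[1]),
                          p[2] + ts * (q[2] - p[2]),
                          p[3] + ts * (q[3] - p[3]))
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

.edgeLengths <- function(nodes, edges) {
  if (nrow(edges) == 0) return(numeric(0))
  d <- nodes[edges[, 1], c("x", "y", "z"), drop = FALSE] -
       nodes[edges[, 2], c("x", "y", "z"), drop = FALSE]
  sqrt(rowSums(as.matrix(d)^2))
}

.assertScalarPos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
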