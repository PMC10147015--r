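# Debris surface detection and multi-criteria selection.
#
# Bright antibody deposits are small, intense and nearly spherical, unlike
# the larger, linear microglial processes; surfaces are rendered around
# supra-threshold components, scored for shape, and selected by stacked
# (conjunctive) filters for masking.

#' Label supra-threshold surface objects and score their shape
#'
#' Connected components (26-connectivity) of voxels above \code{threshold},
#' each summarized as a surface object: voxel count, physical volume, mean
#' intensity, centroid, isosurface-mesh surface area (marching tetrahedra at
#' the threshold level on the intensity field, so anisotropic voxels and
#' partial-volume edges are handled), sphericity and moment-based
#' ellipticities. Labels are assigned in order of each component's
#' (z,y,x)-first voxel, so output order is deterministic.
#'
#' @param ch 3D channel array.
#' @param threshold surface creation threshold (channel units); values
#'   outside the channel range yield an empty result with a warning.
#' @param voxelSize (z, y, x) voxel size in um.
#' @param detailUm isosurface detail (um); retained for interface
#'   compatibility in [0.1, 0.3] (the mesh resolves to voxel pitch).
#' @return data.frame with one row per object: \code{label},
#'   \code{voxel_count}, \code{volume_um3}, \code{mean_intensity},
#'   \code{surface_area_um2}, \code{sphericity}, \code{ellipticity_oblate},
#'   \code{ellipticity_prolate}, \code{centroid_x/y/z}; the label array is
#'   attached as \code{attr(, "labels")}.
#' @export
labelSurfaces <- function(ch, threshold, voxelSize, detailUm = 0.2) {
  rng <- range(ch)
  if (threshold < rng[1] || threshold > rng[2]) {
    warning(sprintf("threshold %g outside channel range [%g, %g]; no surfaces created",
                    threshold, rng[1], rng[2]))
    out <- .emptySurfaceTable()
    attr(out, "labels") <- array(0L, dim(ch))
    return(out)
  }
  dims <- dim(ch)
  mask <- ch > threshold
  labels <- cpp_label26(as.vector(mask), as.integer(dims))
  nlab <- max(labels)
  voxvol <- prod(voxelSize)
  rows <- vector("list", nlab)
  idxAll <- which(labels != 0)
  labOf <- labels[idxAll]
  # voxel (k,j,i) of linear indices
  kji <- cbind(((idxAll - 1L) %% dims[1]) + 1L,
               (((idxAll - 1L) %/% dims[1]) %% dims[2]) + 1L,
               ((idxAll - 1L) %/% (dims[1] * dims[2])) + 1L)
  for (l in seq_len(nlab)) {
    sel <- labOf == l
    vox <- kji[sel, , drop = FALSE]
    vals <- ch[idxAll[sel]]
    nvox <- nrow(vox)
    vol <- nvox * voxvol
    area <- .objectMeshArea(ch, labels, l, vox, threshold, voxelSize)
    shp <- shapeStats(vox, voxelSize, area = area)
    cen <- .voxelCenter(vox, voxelSize)
    rows[[l]] <- data.frame(
      label = l, voxel_count = nvox, volume_um3 = vol,
      mean_intensity = mean(vals), surface_area_um2 = area,
      sphericity = shp["sphericity"],
      ellipticity_oblate = shp["ellipticity_oblate"],
      ellipticity_prolate = shp["ellipticity_prolate"],
      centroid_x = mean(cen[, "x"]), centroid_y = mean(cen[, "y"]),
      centroid_z = mean(cen[, "z"]))
  }
  out <- if (nlab > 0) do.call(rbind, rows) else .emptySurfaceTable()
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

.emptySurfaceTable <- function() {
  data.frame(label = integer(0), voxel_count = integer(0),
             volume_um3 = numeric(0), mean_intensity = numeric(0),
             surface_area_um2 = numeric(0), sphericity = numeric(0),
             ellipticity_oblate = numeric(0), ellipticity_prolate = numeric(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             centroid_z = numeric(0))
}

# mesh area of one labelled object: crop its bounding box (2-voxel pad),
# suppress voxels of other objects to the crop background level, and mesh
# the intensity field at the threshold. The linear interpolation of the
# marching tetrahedra relies on the field having a resolved (PSF/partial-
# volume) edge, which acquired and simulated stacks have; a hard binary
# mask would bias the area upward by a few percent.
.objectMeshArea <- function(ch, labels, lab, vox, threshold, voxelSize) {
  dims <- dim(ch)
  k0 <- max(1L, min(vox[, 1]) - 2L); k1 <- min(dims[1], max(vox[, 1]) + 2L)
  j0 <- max(1L, min(vox[, 2]) - 2L); j1 <- min(dims[2], max(vox[, 2]) + 2L)
  i0 <- max(1L, min(vox[, 3]) - 2L); i1 <- min(dims[3], max(vox[, 3]) + 2L)
  sub <- ch[k0:k1, j0:j1, i0:i1, drop = FALSE]
  slab <- labels[k0:k1, j0:j1, i0:i1, drop = FALSE]
  other <- slab != 0L & slab != lab
  if (any(other)) sub[other] <- min(sub)
  cpp_isosurface_area(as.vector(sub), as.integer(dim(sub)),
                      as.numeric(voxelSize), threshold, min(sub))
}

#' Shape statistics of a voxel object
#'
#' Sphericity is the classical ratio
#' \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}: the surface area of the
#' equal-volume sphere over the object's (mesh) surface area, 1 for a
#' sphere. Ellipticities come from the second central moments of the voxel
#' center coordinates with solid-ellipsoid scaling (semi-axis
#' \eqn{\sqrt{5\lambda}}): with semi-axes \eqn{a \ge b \ge c},
#' oblate ellipticity \eqn{= 1 - c/b} (disc -> 1) and prolate ellipticity
#' \eqn{= 1 - b/a} (needle -> 1); both 0 for a sphere. A single-voxel object
#' has both ellipticities 0 by convention.
#'
#' @param vox integer matrix of voxel indices (k, j, i), one row per voxel.
#' @param voxelSize (z, y, x) voxel size in um.
#' @param area precomputed surface area (um^2); when \code{NA} the returned
#'   sphericity is \code{NA}.
#' @return named numeric: sphericity, ellipticity_oblate,
#'   ellipticity_prolate.
#' @export
shapeStats <- function(vox, voxelSize, area = NA_real_) {
  vox <- matrix(vox, ncol = 3)
  if (nrow(vox) < 1) stop("object must contain at least one voxel")
  voxvol <- prod(voxelSize)
  V <- nrow(vox) * voxvol
  psi <- if (is.na(area) || area <= 0) NA_real_ else
    pi^(1 / 3) * (6 * V)^(2 / 3) / area
  if (nrow(vox) == 1)
    return(c(sphericity = psi, ellipticity_oblate = 0,
             ellipticity_prolate = 0))
  cen <- .voxelCenter(vox, voxelSize)
  cv <- stats::cov(cen) * (nrow(cen) - 1) / nrow(cen)  # population moments
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  semi <- sqrt(5 * ev)
  obl <- if (semi[2] > 0) 1 - semi[3] / semi[2] else 0
  pro <- if (semi[1] > 0) 1 - semi[2] / semi[1] else 0
  c(sphericity = psi, ellipticity_oblate = obl, ellipticity_prolate = pro)
}

#' Select debris objects by stacked criteria
#'
#' The conjunction of every supplied criterion (low volume AND high
#' intensity AND high sphericity, plus optionally high oblate ellipticity);
#' \code{NA} criteria pass. Tightening any criterion can only shrink the
#' selection.
#'
#' @param objs data.frame from \code{\link{labelSurfaces}}.
#' @param criteria a \code{\link{DebrisCriteria}}.
#' @return integer vector of selected labels.
#' @export
selectDebris <- function(objs, criteria) {
  validObject(criteria)
  if (nrow(objs) == 0) return(integer(0))
  keep <- rep(TRUE, nrow(objs))
  if (!is.na(criteria@maxVolumeUm3))
    keep <- keep & objs$volume_um3 <= criteria@maxVolumeUm3
  if (!is.na(criteria@minIntensity))
    keep <- keep & objs$mean_intensity >= criteria@minIntensity
  if (!is.na(criteria@minSphericity))
    keep <- keep & objs$sphericity >= criteria@minSphericity
  if (!is.na(criteria@minOblateEllipticity))
    keep <- keep & objs$ellipticity_oblate >= criteria@minOblateEllipticity
  objs$label[keep]
}

#' Rasterize one anti-aliased ball into a blank field
#'
#' Convenience wrapper used for calibration and validation fixtures: a
#' single sphere of radius \code{radiusUm} painted at \code{value} over a
#' zero background with a one-voxel partial-volume edge.
#'
#' @param dims (nz, ny, nx).
#' @param voxelSize (z, y, x) um.
#' @param center (x, y, z) um.
#' @param radiusUm,value sphere radius and intensity.
#' @param edgeUm width of the partial-volume intensity ramp at the sphere
#'   boundary (default two lateral voxels, a resolved edge as a real
#'   acquisition would show).
#' @return 3D array.
#' @export
rasterizeBall <- function(dims, voxelSize, center, radiusUm, value = 1,
                          edgeUm = 2 * min(voxelSize)) {
  seg <- matrix(c(center, center, radiusUm, radiusUm, value), nrow = 1)
  cpp_rasterize_capsules(as.integer(dims), as.numeric(voxelSize), seg,
                         edgeUm, 0)
}
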