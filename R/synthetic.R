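# Synthetic microglia scene generator: parametric branching cells with exact
# ground-truth skeletons, rasterized into two-channel z-stacks (membrane
# marker "iba1", nuclear marker "dapi") with PSF blur and shot/read noise.

#' Morphological state presets
#'
#' Fixed parameter sets for the four canonical microglial reactivity states.
#' The states are ordered so that, in expectation over sampled cells,
#' total process length and Sholl intersection sum increase along
#' ameboid < transitional < surveillance < hyper_ramified, and the ameboid
#' convex hull volume is smallest of the four: the compact ameboid state has
#' few short processes (pro-phagocytic/pro-inflammatory profile), the
#' surveillance state is the classically ramified resting form, and the
#' hyper-ramified ("bushy") state carries the densest arbor. The numeric
#' values are the package's own calibration; only these ordinal relations
#' are contractual.
#'
#' @param name one of \code{"ameboid"}, \code{"transitional"},
#'   \code{"surveillance"}, \code{"hyper_ramified"}.
#' @return a \code{\link{CellSpec}}.
#' @examples
#' morphologyPreset("ameboid")
#' @export
morphologyPreset <- function(name) {
  presets <- list(
    ameboid = CellSpec(
      somaRadiusUm = 4.5, nucleusRadiusUm = 3.2, nPrimary = 3,
      branchProb = 0.15, segmentLengthMeanUm = 3.5, segmentLengthSdUm = 0.8,
      maxOrder = 2, tortuosity = 0.35, processRadiusUm = 0.7, taper = 0.8),
    transitional = CellSpec(
      somaRadiusUm = 4.0, nucleusRadiusUm = 2.8, nPrimary = 4,
      branchProb = 0.35, segmentLengthMeanUm = 5, segmentLengthSdUm = 1.2,
      maxOrder = 3, tortuosity = 0.4, processRadiusUm = 0.6, taper = 0.85),
    surveillance = CellSpec(
      somaRadiusUm = 3.5, nucleusRadiusUm = 2.5, nPrimary = 5,
      branchProb = 0.5, segmentLengthMeanUm = 6, segmentLengthSdUm = 1.5,
      maxOrder = 4, tortuosity = 0.45, processRadiusUm = 0.5, taper = 0.85),
    hyper_ramified = CellSpec(
      somaRadiusUm = 3.5, nucleusRadiusUm = 2.5, nPrimary = 6,
      branchProb = 0.7, segmentLengthMeanUm = 5.5, segmentLengthSdUm = 1.5,
      maxOrder = 5, tortuosity = 0.55, processRadiusUm = 0.5, taper = 0.9))
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets))
    stop("unknown morphology preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Sample a random filament tree from a cell specification
#'
#' Grows a rooted tree from a soma node: \code{nPrimary} processes leave the
#' soma surface in random directions, grow in ~1 um steps with per-step
#' angular jitter \code{tortuosity}, and bifurcate with probability
#' \code{branchProb} at segment ends until \code{maxOrder}. Directions are
#' damped along z (factor 0.3 before renormalization) so arbors stay inside
#' thin optical sections, as microglia in 50 um slices do. Consumes the R
#' session RNG; seed with \code{set.seed} for reproducibility.
#'
#' @param spec a \code{\link{CellSpec}}.
#' @param somaCenter numeric (x, y, z) in um.
#' @param cellId label for the resulting graph.
#' @return a \code{\link{FilamentGraph}} rooted at the soma node (id 1).
#' @examples
#' set.seed(1)
#' g <- sampleTree(morphologyPreset("ameboid"), c(30, 30, 10))
#' @export
sampleTree <- function(spec, somaCenter, cellId = "cell") {
  validObject(spec)
  stopifnot(length(somaCenter) == 3)
  zdamp <- 0.3
  stepUm <- 1.0

  xs <- somaCenter[1]; ys <- somaCenter[2]; zs <- somaCenter[3]
  nodeMat <- matrix(NA_real_, 256, 4)
  nodeMat[1, ] <- c(xs, ys, zs, spec@somaRadiusUm)
  nodeCount <- 1L
  edges <- list()
  addNode <- function(p, r) {
    if (nodeCount == nrow(nodeMat))
      nodeMat <<- rbind(nodeMat, matrix(NA_real_, nrow(nodeMat), 4))
    nodeCount <<- nodeCount + 1L
    nodeMat[nodeCount, ] <<- c(p, r)
    nodeCount
  }
  addEdge <- function(a, b) edges[[length(edges) + 1]] <<- c(a, b)

  randDir <- function() {
    v <- rnorm(3)
    v[3] <- v[3] * zdamp
    .unit(v)
  }
  # primary directions keep a minimum angular separation: two primaries
  # inside one tube radius would rasterize as a single fused trunk, making
  # the stored skeleton inconsistent with its own rendered image
  primaryDirs <- function(k, minAngle = 0.5) {
    dirs <- list()
    for (p in seq_len(k)) {
      d <- randDir()
      for (try in seq_len(50)) {
        ok <- all(vapply(dirs, function(e)
          acos(min(max(sum(d * e), -1), 1)) >= minAngle, TRUE))
        if (ok) break
        d <- randDir()
      }
      dirs[[p]] <- d
    }
    dirs
  }

  # Growth is self-avoidant: a candidate step must keep an anisotropic
  # clearance (~2 tube-plus-PSF radii laterally; larger axially, where the
  # PSF and 0.8 um slicing fuse structures over a longer range) from every
  # previously grown node except the segment's own local neighbourhood.
  # Microglial processes tile space without touching, and, just as
  # importantly, branches closer than this fuse in the rendered image,
  # which would make the stored skeleton unrecoverable from its own
  # rasterization.
  selfDist <- c(1.3, 1.3, 2.2)   # (x, y, z) semi-axes, um
  scaledDist <- function(pts, p) {
    sqrt(((pts[, 1] - p[1]) / selfDist[1])^2 +
           ((pts[, 2] - p[2]) / selfDist[2])^2 +
           ((pts[, 3] - p[3]) / selfDist[3])^2)
  }
  grow <- function(fromId, pos, dir, order) {
    r <- spec@processRadiusUm * spec@taper^(order - 1)
    len <- max(0.5, rnorm(1, spec@segmentLengthMeanUm, spec@segmentLengthSdUm))
    nsub <- max(1L, ceiling(len / stepUm))
    sub <- len / nsub
    cur <- fromId
    # nodes near the segment start belong to this segment's own origin
    # (junction vicinity) and do not count as collisions
    startPos <- pos
    for (s in seq_len(nsub)) {
      base <- dir
      pts <- nodeMat[seq_len(nodeCount), 1:3, drop = FALSE]
      dStart <- scaledDist(pts, startPos)
      obstacle <- which(dStart >= 1 &
                          seq_len(nodeCount) != cur &
                          seq_len(nodeCount) != 1L &
                          seq_len(nodeCount) <= nodeCount - 3L)
      d2 <- base
      for (try in 1:8) {
        d2 <- base
        if (spec@tortuosity > 0 && (s > 1 || try > 1)) {
          theta <- rnorm(1, 0, spec@tortuosity * (1 + 0.5 * (try - 1)))
          d2 <- .unit(.rotate(base, theta, .perp(base)))
        }
        if (spec@tortuosity == 0 || length(obstacle) == 0) break
        cand <- pos + d2 * sub
        if (all(scaledDist(pts[obstacle, , drop = FALSE], cand) >= 1))
          break
      }
      dir <- d2
      pos <- pos + dir * sub
      nid <- addNode(pos, r)
      addEdge(cur, nid)
      cur <- nid
    }
    if (order < spec@maxOrder && runif(1) < spec@branchProb) {
      axis <- .perp(dir)
      phi <- 0.5 + 0.2 * abs(rnorm(1))
      for (sgn in c(1, -1)) {
        d2 <- .rotate(dir, sgn * phi, axis)
        d2[3] <- d2[3] * zdamp
        grow(cur, pos, .unit(d2), order + 1)
      }
    }
    invisible(NULL)
  }

  if (spec@nPrimary > 0) {
    dirs <- primaryDirs(spec@nPrimary)
    for (p in seq_len(spec@nPrimary)) {
      dir <- dirs[[p]]
      start <- c(xs, ys, zs) + dir * spec@somaRadiusUm
      rid <- addNode(start, spec@processRadiusUm)
      addEdge(1L, rid)
      grow(rid, start, dir, 1L)
    }
  }

  nm <- nodeMat[seq_len(nodeCount), , drop = FALSE]
  nodesDf <- data.frame(x = nm[, 1], y = nm[, 2], z = nm[, 3],
                        radius = nm[, 4])
  ed <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), ncol = 2)
  FilamentGraph(nodesDf, ed, somaNode = 1L, cellId = cellId,
                meta = list(spec = spec))
}

#' Analytic reference metrics of an exact skeleton
#'
#' The independent oracle for the morphometry module: total length as the
#' exact sum of edge lengths, the Sholl profile by dense polyline resampling
#' (0.01 um) and sign-change counting, and the convex hull of all node
#' coordinates. Intended for ground-truth skeletons; agreement with
#' \code{\link{measureCell}} on the same graph validates the production path.
#'
#' @param tree a rooted \code{\link{FilamentGraph}}.
#' @param shollResolutionUm Sholl shell spacing (um).
#' @return a \code{\link{CellMetrics}}.
#' @export
analyticMetrics <- function(tree, shollResolutionUm = 1.0) {
  if (!is(tree, "FilamentGraph")) stop("tree must be a FilamentGraph")
  validObject(tree)
  nodes <- tree@nodes
  edges <- tree@edges
  len <- sum(.edgeLengths(nodes, edges))

  center <- as.numeric(nodes[tree@somaNode, c("x", "y", "z")])
  prof <- .shollDense(tree, shollResolutionUm, sampleUm = 0.01)

  h <- convexHullMetrics(tree)

  new("CellMetrics", cellId = tree@cellId, animalId = tree@animalId,
      group = tree@group, age = tree@age, totalLengthUm = len,
      filamentVolumeUm3 = filamentVolume(tree),
      shollProfile = prof, shollSum = sum(prof),
      hullVolumeUm3 = h$volume, hullAreaUm2 = h$area,
      sphericity = if (h$degenerate || h$area <= 0) 0 else
        sphericity(h$volume, h$area),
      nucleusOk = TRUE, degenerateHull = h$degenerate)
}

# Brute-force Sholl profile: every directed edge (soma outward) is sampled
# densely; intersections at shell r = number of sign changes of (d >= r)
# along the sample sequence, which realizes the half-open crossing rule
# (d_prev < r <= d_next counts, d_prev >= r > d_next counts).
.shollDense <- function(tree, resolutionUm, sampleUm = 0.01) {
  nodes <- tree@nodes
  center <- as.numeric(nodes[tree@somaNode, c("x", "y", "z")])
  dirEdges <- .orientEdges(tree)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  dmax <- if (nrow(xyz) > 1)
    max(sqrt(colSums((t(xyz) - center)^2))) else 0
  nshell <- floor(dmax / resolutionUm + 1e-9)
  if (nshell < 1 || nrow(dirEdges) == 0)
    return(setNames(numeric(0), character(0)))
  shells <- seq_len(nshell) * resolutionUm
  counts <- numeric(nshell)
  for (e in seq_len(nrow(dirEdges))) {
    p <- xyz[dirEdges[e, 1], ]; q <- xyz[dirEdges[e, 2], ]
    elen <- sqrt(sum((q - p)^2))
    if (elen == 0) next
    nsub <- max(1L, ceiling(elen / sampleUm))
    ts <- (0:nsub) / nsub
    pts <- outer(ts, q - p) + rep(p, each = nsub + 1)
    d <- sqrt(rowSums((pts - rep(center, each = nsub + 1))^2))
    ge <- outer(d, shells, ">=")
    counts <- counts + colSums(abs(diff(ge)))
  }
  setNames(counts, format(shells, trim = TRUE))
}

# directed edges parent -> child via BFS from the soma
.orientEdges <- function(tree) {
  n <- nrow(tree@nodes)
  ed <- tree@edges
  if (nrow(ed) == 0) return(matrix(integer(0), ncol = 2))
  adj <- vector("list", n)
  for (r in seq_len(nrow(ed))) {
    a <- ed[r, 1]; b <- ed[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- matrix(0L, nrow(ed), 2)
  seen <- logical(n)
  queue <- tree@somaNode
  seen[queue] <- TRUE
  pos <- 1L; cnt <- 0L
  while (pos <= length(queue)) {
    u <- queue[pos]; pos <- pos + 1L
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        cnt <- cnt + 1L
        out[cnt, ] <- c(u, v)
        queue <- c(queue, v)
      }
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

#' Rasterize a synthetic scene into a two-channel image stack
#'
#' Soma spheres and process capsules (swept spheres along skeleton edges,
#' with node radii) are painted into the "iba1" channel by exact
#' point-to-segment distance in physical um (max over overlapping
#' primitives, one-lateral-voxel anti-aliased edge); nucleus spheres are
#' painted into "dapi". The stack is blurred with a per-axis Gaussian PSF,
#' Poisson and Gaussian noise are applied, and values are quantized to the
#' 16-bit range with background at 2 percent of full scale.
#'
#' The RNG is seeded from \code{scene@seed}; the stream order is fixed and
#' documented: (1) soma placement, (2) per-cell tree growth in cell order,
#' (3) debris placement, (4) noise. Identical (scene, specs) therefore give
#' byte-identical stacks.
#'
#' @param scene a \code{\link{SceneSpec}}.
#' @param specs list of \code{\link{CellSpec}}, length \code{scene@nCells}.
#' @param centers optional matrix of soma centers (x, y, z um), overriding
#'   rejection-sampled placement (used e.g. to build nucleus-at-border QC
#'   fixtures).
#' @return list with elements \code{stack} (\code{\link{ImageStack}}) and
#'   \code{truth} (\code{\link{SceneGroundTruth}}).
#' @export
rasterizeScene <- function(scene, specs, centers = NULL) {
  validObject(scene)
  if (length(specs) != scene@nCells)
    stop("length(specs) must equal scene@nCells")
  lapply(specs, validObject)

  nx <- as.integer(round(scene@fieldXYUm / scene@voxelXYUm))
  ny <- nx
  nz <- as.integer(scene@nSlices)
  dims <- c(nz, ny, nx)
  voxel <- c(scene@voxelZUm, scene@voxelXYUm, scene@voxelXYUm)
  depth <- nz * scene@voxelZUm
  bg <- 0.02

  set.seed(scene@seed)

  # --- 1. soma placement (rejection sampling, bounded attempts) -------------
  n <- scene@nCells
  if (is.null(centers)) {
    centers <- matrix(numeric(0), ncol = 3)
    if (n > 0) {
      maxAttempts <- 200L * n
      attempts <- 0L
      while (nrow(centers) < n && attempts < maxAttempts) {
        attempts <- attempts + 1L
        sp <- specs[[nrow(centers) + 1]]
        margin <- sp@somaRadiusUm + 2
        if (2 * margin >= scene@fieldXYUm)
          stop("field too small for soma placement")
        cand <- c(runif(1, margin, scene@fieldXYUm - margin),
                  runif(1, margin, scene@fieldXYUm - margin),
                  runif(1, 0.4 * depth, 0.6 * depth))
        ok <- nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >=
                scene@minSomaSeparationUm)
        if (ok) centers <- rbind(centers, cand)
      }
      if (nrow(centers) < n)
        stop(sprintf("soma placement failed: placed %d of %d cells within %d attempts",
                     nrow(centers), n, maxAttempts))
    }
  } else {
    centers <- matrix(centers, ncol = 3)
    if (nrow(centers) != n) stop("centers must have one row per cell")
  }

  # --- 2. tree growth -------------------------------------------------------
  graphs <- vector("list", n)
  for (i in seq_len(n))
    graphs[[i]] <- sampleTree(specs[[i]], centers[i, ],
                              cellId = sprintf("cell%02d", i))

  # --- primitives -----------------------------------------------------------
  segsIba <- list(); segsDapi <- list()
  for (i in seq_len(n)) {
    g <- graphs[[i]]; sp <- specs[[i]]
    cen <- centers[i, ]
    segsIba[[length(segsIba) + 1]] <-
      c(cen, cen, sp@somaRadiusUm, sp@somaRadiusUm, sp@intensitySoma)
    nd <- g@nodes; ed <- g@edges
    if (nrow(ed) > 0) {
      for (r in seq_len(nrow(ed))) {
        a <- ed[r, 1]; b <- ed[r, 2]
        ra <- if (a == g@somaNode) nd$radius[b] else nd$radius[a]
        rb <- if (b == g@somaNode) nd$radius[a] else nd$radius[b]
        segsIba[[length(segsIba) + 1]] <-
          c(nd$x[a], nd$y[a], nd$z[a], nd$x[b], nd$y[b], nd$z[b],
            ra, rb, sp@intensityProcess)
      }
    }
    segsDapi[[length(segsDapi) + 1]] <-
      c(cen, cen, sp@nucleusRadiusUm, sp@nucleusRadiusUm, 0.9)
  }

  # --- 3. debris ------------------------------------------------------------
  nd <- scene@nDebris
  debris <- matrix(numeric(0), ncol = 3)
  if (nd > 0) {
    m <- scene@debrisRadiusUm + 0.5
    debris <- cbind(runif(nd, m, scene@fieldXYUm - m),
                    runif(nd, m, scene@fieldXYUm - m),
                    runif(nd, m, depth - m))
    for (r in seq_len(nd))
      segsIba[[length(segsIba) + 1]] <-
        c(debris[r, ], debris[r, ], scene@debrisRadiusUm,
          scene@debrisRadiusUm, scene@debrisIntensity)
  }

  toMat <- function(lst) if (length(lst)) do.call(rbind, lst) else
    matrix(numeric(0), ncol = 9)
  edge <- scene@voxelXYUm
  iba <- cpp_rasterize_capsules(dims, voxel, toMat(segsIba), edge, bg)
  dapi <- cpp_rasterize_capsules(dims, voxel, toMat(segsDapi), edge, bg)

  # --- PSF blur -------------------------------------------------------------
  sigVox <- scene@psfSigmaUm / voxel
  if (any(sigVox > 0)) {
    iba <- cpp_gaussian_blur(iba, dims, sigVox)
    dapi <- cpp_gaussian_blur(dapi, dims, sigVox)
  }

  # --- 4. noise + 16-bit quantization --------------------------------------
  quantize <- function(img) {
    if (scene@noisePoissonScale > 0)
      img <- rpois(length(img), pmax(img, 0) * scene@noisePoissonScale) /
        scene@noisePoissonScale
    if (scene@noiseGaussianSd > 0)
      img <- img + rnorm(length(img), 0, scene@noiseGaussianSd)
    img <- pmin(pmax(round(img * 65535), 0), 65535)
    dim(img) <- dims
    img
  }
  stack <- ImageStack(list(iba1 = quantize(iba), dapi = quantize(dapi)),
                      voxelSize = voxel, bitDepth = 16,
                      provenance = sprintf("synthetic scene, seed %d",
                                           as.integer(scene@seed)))

  metrics <- lapply(graphs, analyticMetrics)
  truth <- new("SceneGroundTruth", graphs = graphs, metrics = metrics,
               somaCenters = centers, debrisCenters = debris)
  list(stack = stack, truth = truth)
}
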