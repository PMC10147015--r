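# Soma/seed detection and intensity-guided filament tracing.
#
# The tracer realizes autopathing as intensity-weighted geodesics on the
# 26-connected voxel grid: edge weight = physical step length *
# (0.01 + 1 - I)^gamma with I the min-max normalized intensity. Voxels below
# the intensity floor stay traversable at a large constant penalty so that
# paths can bridge faint gaps; removeDisconnectedSegments() then deletes
# branches whose bridged (sub-floor) run exceeds the configured maximum gap
# length. All tie-breaks are lexicographic on (z, y, x); the module contains
# no randomness.

.GAP_PENALTY <- 100
.COST_EPS <- 0.01

# scale-normalized Laplacian-of-Gaussian response for bright blobs
.logResponse <- function(ch, sigmaUm, voxelSize) {
  dims <- dim(ch)
  sigVox <- sigmaUm / voxelSize
  bl <- cpp_gaussian_blur(ch, as.integer(dims), sigVox)
  resp <- -sigmaUm^2 * cpp_laplacian(bl, as.integer(dims),
                                     as.numeric(voxelSize))
  dim(resp) <- dims
  resp
}

#' Detect soma starting points in the colocalization channel
#'
#' Local maxima of the scale-normalized Laplacian-of-Gaussian response at
#' the soma scale (sigma = startingDiameter / (2 sqrt(3))), thresholded at
#' \code{params@startThreshold} and greedily suppressed to a minimum
#' pairwise separation of one starting diameter (strongest response wins;
#' ties break lexicographically on (z, y, x)).
#'
#' @param coloc colocalization channel (normalized internally).
#' @param params a \code{\link{TraceParams}}.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return data.frame: \code{x}, \code{y}, \code{z} (um),
#'   \code{diameter_um}, \code{score}, ordered by descending score.
#' @export
detectStartingPoints <- function(coloc, params, voxelSize) {
  validObject(params)
  ch <- .normalize01(coloc)
  dim(ch) <- dim(coloc)
  sigma <- params@startingDiameterUm / (2 * sqrt(3))
  resp <- .logResponse(ch, sigma, voxelSize)
  mx <- cpp_local_maxima(as.vector(resp), as.integer(dim(ch)),
                         params@startThreshold, 0)
  if (nrow(mx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      diameter_um = numeric(0), score = numeric(0)))
  kji <- mx + 1L
  score <- resp[kji]
  pos <- .voxelCenter(kji, voxelSize)
  ord <- order(-score, kji[, 1], kji[, 2], kji[, 3])
  pos <- pos[ord, , drop = FALSE]; score <- score[ord]
  keep <- logical(length(score))
  for (i in seq_along(score)) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- pos[keep, , drop = FALSE]
    keep[i] <- all(sqrt(rowSums((prev - rep(pos[i, ], each = nrow(prev)))^2)) >=
                     params@startingDiameterUm)
  }
  out <- data.frame(x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
                    diameter_um = params@startingDiameterUm,
                    score = score[keep])
  # sub-voxel refinement on the detection channel (z pitch is coarse; the
  # soma exclusion and collapse radii assume an accurate center)
  .refinePoints(out, ch, params@startingDiameterUm / 2, voxelSize)
}

#' Keep only starting points whose cell has a nucleus inside the stack
#'
#' A point passes iff some supra-threshold DAPI component overlaps its
#' starting sphere and that component touches neither the first nor the
#' last z slice (a nucleus clipped by the stack border disqualifies the
#' cell).
#'
#' @param points data.frame from \code{\link{detectStartingPoints}}.
#' @param dapi nuclear channel.
#' @param nucleusThreshold threshold on the min-max normalized DAPI channel.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return the subset of \code{points} passing the rule, with a
#'   \code{nucleus_ok} column added (all TRUE in the returned subset).
#' @export
filterByNucleus <- function(points, dapi, nucleusThreshold, voxelSize) {
  if (nrow(points) == 0) return(cbind(points, nucleus_ok = logical(0)))
  dims <- dim(dapi)
  ch <- .normalize01(dapi)
  labels <- cpp_label26(as.vector(ch > nucleusThreshold), as.integer(dims))
  dim(labels) <- dims
  borderLabs <- unique(c(labels[1, , ], labels[dims[1], , ]))
  borderLabs <- borderLabs[borderLabs != 0]
  ok <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    r <- points$diameter_um[p] / 2
    cen <- c(points$x[p], points$y[p], points$z[p])
    lo <- .voxelOf(cen - r, dims, voxelSize)
    hi <- .voxelOf(cen + r, dims, voxelSize)
    ks <- lo[1]:hi[1]; js <- lo[2]:hi[2]; is <- lo[3]:hi[3]
    sub <- labels[ks, js, is, drop = FALSE]
    if (all(sub == 0)) next
    # restrict to voxels actually inside the sphere
    grid <- expand.grid(k = ks, j = js, i = is)
    cenv <- .voxelCenter(as.matrix(grid), voxelSize)
    inside <- sqrt((cenv[, "x"] - cen[1])^2 + (cenv[, "y"] - cen[2])^2 +
                     (cenv[, "z"] - cen[3])^2) <= r
    labs <- unique(labels[as.matrix(grid)[inside, , drop = FALSE]])
    labs <- labs[labs != 0]
    ok[p] <- length(setdiff(labs, borderLabs)) > 0
  }
  out <- points[ok, , drop = FALSE]
  out$nucleus_ok <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect process seed points in the membrane channel
#'
#' Ridge-tolerant local maxima of the LoG response at the process scale
#' (sigma = seedDiameter / (2 sqrt(3))): a voxel qualifies when its response
#' exceeds \code{seedThreshold} and is within 5 percent of its strongest
#' 26-neighbor, so seeds follow the nearly-flat response along tube axes
#' instead of collapsing onto isolated maxima. Seeds closer than
#' \code{removeSeedRadiusFactor} starting radii to any starting point are
#' removed, mitigating false hair-like filaments around the bright soma rim.
#'
#' @param iba1 membrane channel (normalized internally).
#' @param params a \code{\link{TraceParams}}.
#' @param startingPoints data.frame from \code{\link{detectStartingPoints}}.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return data.frame: \code{x}, \code{y}, \code{z}, \code{diameter_um},
#'   \code{score}.
#' @export
detectSeedPoints <- function(iba1, params, startingPoints, voxelSize) {
  validObject(params)
  ch <- .normalize01(iba1)
  dim(ch) <- dim(iba1)
  sigma <- params@seedDiameterUm / (2 * sqrt(3))
  resp <- .logResponse(ch, sigma, voxelSize)
  mx <- cpp_local_maxima(as.vector(resp), as.integer(dim(ch)),
                         params@seedThreshold, 0.05)
  if (nrow(mx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      diameter_um = numeric(0), score = numeric(0)))
  kji <- mx + 1L
  pos <- .voxelCenter(kji, voxelSize)
  score <- resp[kji]
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    diameter_um = params@seedDiameterUm, score = score)
  # snap seeds onto the tube axis (centroid refinement), then collapse
  # duplicates from the same cross-section; without this, seeds from
  # opposite tube walls spawn parallel traced lanes
  out <- .refinePoints(out, ch, params@seedDiameterUm / 2, voxelSize)
  out <- .dedupePoints(out, params@seedDiameterUm / 4)
  excl <- params@removeSeedRadiusFactor * params@startingDiameterUm / 2
  if (excl > 0 && nrow(startingPoints) > 0) {
    sp <- as.matrix(startingPoints[, c("x", "y", "z")])
    pos <- as.matrix(out[, c("x", "y", "z")])
    keep <- vapply(seq_len(nrow(pos)), function(i) {
      all(sqrt(rowSums((sp - rep(pos[i, ], each = nrow(sp)))^2)) >= excl)
    }, TRUE)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# iterated intensity-weighted centroid (squared weights, sharpening the
# pull to the brightest core) over a ball of the given radius; recovers a
# blob/ridge center to well below one voxel, which matters in z where
# slices are 0.8 um apart
.centroidRefine <- function(mat, ch, radiusUm, voxelSize, iters = 2) {
  dims <- dim(ch)
  extent <- rev(dims) * rev(voxelSize)  # (x, y, z)
  for (p in seq_len(nrow(mat))) {
    cen <- mat[p, ]
    for (it in seq_len(iters)) {
      lo <- .voxelOf(cen - radiusUm, dims, voxelSize)
      hi <- .voxelOf(cen + radiusUm, dims, voxelSize)
      grid <- as.matrix(expand.grid(k = lo[1]:hi[1], j = lo[2]:hi[2],
                                    i = lo[3]:hi[3]))
      pos <- .voxelCenter(grid, voxelSize)
      inside <- (pos[, "x"] - cen[1])^2 + (pos[, "y"] - cen[2])^2 +
        (pos[, "z"] - cen[3])^2 <= radiusUm^2
      if (!any(inside)) break
      w <- ch[grid[inside, , drop = FALSE]]^2
      if (sum(w) <= 0) break
      cen <- c(sum(pos[inside, "x"] * w), sum(pos[inside, "y"] * w),
               sum(pos[inside, "z"] * w)) / sum(w)
      cen <- pmin(pmax(cen, 1e-6), extent - 1e-6)
    }
    mat[p, ] <- cen
  }
  mat
}

# data.frame (x, y, z, ...) wrapper for detected point tables
.refinePoints <- function(points, ch, radiusUm, voxelSize, iters = 2) {
  if (nrow(points) == 0) return(points)
  mat <- .centroidRefine(as.matrix(points[, c("x", "y", "z")]), ch,
                         radiusUm, voxelSize, iters)
  points$x <- mat[, 1]; points$y <- mat[, 2]; points$z <- mat[, 3]
  points
}

# greedy deduplication: order by descending score, keep points at least
# minSep apart (deterministic; ties already ordered by (z,y,x) upstream)
.dedupePoints <- function(points, minSep) {
  if (nrow(points) <= 1) return(points)
  ord <- order(-points$score)
  pos <- as.matrix(points[ord, c("x", "y", "z")])
  keep <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- pos[keep, , drop = FALSE]
    keep[i] <- all(sqrt(rowSums((prev - rep(pos[i, ], each = nrow(prev)))^2)) >=
                     minSep)
  }
  out <- points[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- internal tracing machinery -------------------------------------------

# Union of seed-to-source geodesics with redundant-path suppression.
# Seeds are processed farthest (geodesic cost) first, so distal tips lay
# down the skeleton; each later path is walked from its seed toward the
# source only until it reaches a voxel already in the tree, or comes within
# mergeRadius of an existing node, and attaches there. In flat-intensity
# tube cores, geodesics from nearby seeds otherwise run in parallel voxel
# lanes that never meet; the proximity join collapses those lanes into
# short stubs that the spur pruner removes.
.voxelTree <- function(pred, seedLin0, seedCost, sourceLin0, dims,
                       voxelSize, mergeRadius, iba1n = NULL,
                       floorVal = 0) {
  # mergeRadius is an (x, y, z) semi-axis vector: lanes one z-slice apart
  # must merge on anisotropic grids, but the lateral merge ball stays at
  # the seed radius so slowly-diverging daughter branches are not fused
  posOf <- function(lin) {
    kji <- cbind(lin %% dims[1] + 1, (lin %/% dims[1]) %% dims[2] + 1,
                 lin %/% (dims[1] * dims[2]) + 1)
    .voxelCenter(kji, voxelSize)
  }
  P <- list(posOf(sourceLin0)[1, ])
  parent <- list(0L)
  nodeAt <- new.env(hash = TRUE)      # voxel linear index -> node id
  assign(as.character(sourceLin0), 1L, envir = nodeAt)
  hash <- new.env(hash = TRUE)        # spatial grid cell -> node ids
  cellOf <- function(p) paste(floor(p / mergeRadius), collapse = " ")
  addHash <- function(id, p) {
    key <- cellOf(p)
    assign(key, c(if (exists(key, hash, inherits = FALSE))
      get(key, hash) else integer(0), id), envir = hash)
  }
  addHash(1L, P[[1]])
  # a proximity join is only allowed when the straight bridge to the
  # candidate node stays bright: parallel voxel lanes of the SAME tube
  # have a bright interior between them, while two distinct branches one
  # z-slice apart have a dim interstice and must not be fused
  bridgeOk <- function(a, b) {
    if (is.null(iba1n)) return(TRUE)
    mid <- (a + b) / 2
    v <- cpp_trilinear(iba1n, as.integer(dims), as.numeric(voxelSize),
                       matrix(mid, 1))
    va <- cpp_trilinear(iba1n, as.integer(dims), as.numeric(voxelSize),
                        matrix(a, 1))
    !is.na(v) && v >= max(floorVal, 0.6 * va)
  }
  nearNode <- function(p) {
    base <- floor(p / mergeRadius)
    bestId <- 0L; bestD <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      key <- paste(base + c(dx, dy, dz), collapse = " ")
      if (!exists(key, hash, inherits = FALSE)) next
      for (id in get(key, hash)) {
        d <- sqrt(sum(((P[[id]] - p) / mergeRadius)^2))
        if (d < bestD && bridgeOk(p, P[[id]])) { bestD <- d; bestId <- id }
      }
    }
    bestId
  }

  for (s in order(-seedCost)) {
    v <- as.integer(seedLin0[s])
    if (exists(as.character(v), nodeAt, inherits = FALSE)) next
    chainLin <- integer(0)
    chainPos <- list()
    attachId <- 0L
    while (TRUE) {
      pos <- posOf(v)[1, ]
      nid <- nearNode(pos)
      if (nid > 0L) { attachId <- nid; break }
      chainLin <- c(chainLin, v)
      chainPos[[length(chainPos) + 1]] <- pos
      p <- pred[v + 1L]
      if (p < 0L) { attachId <- 1L; break }   # reached the source
      v <- p
      if (exists(as.character(v), nodeAt, inherits = FALSE)) {
        attachId <- get(as.character(v), nodeAt)
        break
      }
    }
    if (length(chainLin) == 0) next
    # commit the chain from the attachment point outward to the seed
    prev <- attachId
    for (i in rev(seq_along(chainLin))) {
      P[[length(P) + 1]] <- chainPos[[i]]
      parent[[length(parent) + 1]] <- prev
      id <- length(P)
      assign(as.character(chainLin[i]), id, envir = nodeAt)
      addHash(id, chainPos[[i]])
      prev <- id
    }
  }
  list(P = do.call(rbind, P), parent = unlist(parent), root = 1L)
}

# contract the connected sub-floor ... soma-interior region (nodes within
# rs of the soma center, connected to the root) into a single soma node at
# `center`; exterior branches attach via a node on the sphere surface
.collapseSoma <- function(P, parent, root, center, rs) {
  n <- nrow(P)
  d <- sqrt(colSums((t(P) - center)^2))
  children <- split(seq_len(n), factor(parent, levels = 0:n))[-1]
  # BFS from root through d < rs
  interior <- logical(n)
  if (d[root] < rs) {
    queue <- root; interior[root] <- TRUE; pos <- 1L
    while (pos <= length(queue)) {
      u <- queue[pos]; pos <- pos + 1L
      for (v in children[[u]])
        if (!interior[v] && d[v] < rs) { interior[v] <- TRUE; queue <- c(queue, v) }
    }
  }
  newP <- list(center)      # node 1 = soma
  newParent <- list(0L)
  mapid <- integer(n)       # old id -> new id (0 = dropped)
  # process in an order where parents come first (BFS from root)
  ordq <- root; pos <- 1L
  while (pos <= length(ordq)) {
    u <- ordq[pos]; pos <- pos + 1L
    ordq <- c(ordq, children[[u]])
  }
  for (u in ordq) {
    if (interior[u]) { mapid[u] <- 1L; next }
    pu <- parent[u]
    if (pu == 0L || !interior[pu]) {
      newP[[length(newP) + 1]] <- P[u, ]
      newParent[[length(newParent) + 1]] <- if (pu == 0L) 1L else mapid[pu]
      mapid[u] <- length(newP)
    } else {
      # parent interior, u exterior: insert boundary node on segment pu -> u
      a <- P[pu, ]; b <- P[u, ]
      # solve |a + t(b-a) - c| = rs for t in [0,1]
      ab <- b - a; ac <- a - center
      A <- sum(ab^2); B <- 2 * sum(ab * ac); C <- sum(ac^2) - rs^2
      disc <- max(B^2 - 4 * A * C, 0)
      t <- if (A > 0) (-B + sqrt(disc)) / (2 * A) else 0
      t <- min(max(t, 0), 1)
      bd <- a + t * ab
      newP[[length(newP) + 1]] <- bd
      newParent[[length(newParent) + 1]] <- 1L
      bdid <- length(newP)
      if (sqrt(sum((bd - b)^2)) > 1e-9) {
        newP[[length(newP) + 1]] <- b
        newParent[[length(newParent) + 1]] <- bdid
        mapid[u] <- length(newP)
      } else {
        mapid[u] <- bdid
      }
    }
  }
  P2 <- do.call(rbind, newP)
  par2 <- unlist(newParent)
  # paths that exit the soma, crawl its blurred shell and dip back inside
  # the sphere are phantoms: every legitimate interior node was contracted
  # above, so delete the subtree of any remaining clearly-interior node
  # (boundary nodes sit at d == rs and are kept)
  d2 <- sqrt(colSums((t(P2) - center)^2))
  bad <- which(d2 < rs - 0.3)
  bad <- bad[bad != 1L]
  if (length(bad) > 0) {
    n2 <- nrow(P2)
    kids <- split(seq_len(n2), factor(par2, levels = 0:n2))[-1]
    killed <- logical(n2)
    for (b in bad) {
      if (killed[b]) next
      q <- b; pos <- 1L
      while (pos <= length(q)) {
        w <- q[pos]; pos <- pos + 1L
        killed[w] <- TRUE
        q <- c(q, kids[[w]])
      }
    }
    keep <- which(!killed)
    remap <- integer(n2); remap[keep] <- seq_along(keep)
    par2 <- par2[keep]
    par2[par2 > 0] <- remap[par2[par2 > 0]]
    P2 <- P2[keep, , drop = FALSE]
  }
  list(P = P2, parent = par2, root = 1L)
}

# decompose a parent-pointer tree into chains between key nodes
# (root, junctions, leaves); each chain is the node-id path key ... key
.chainsOf <- function(parent, root) {
  n <- length(parent)
  nkids <- tabulate(parent[parent > 0], nbins = n)
  key <- (seq_len(n) == root) | (nkids >= 2) | (nkids == 0)
  chains <- list()
  for (leafKey in which(key)) {
    if (leafKey == root) next
    # walk up from this key node to the previous key node
    path <- leafKey
    v <- parent[leafKey]
    while (v != 0 && !key[v]) { path <- c(path, v); v <- parent[v] }
    if (v != 0) path <- c(path, v)
    chains[[length(chains) + 1]] <- rev(path)  # from upper key to lower key
  }
  chains
}

# Chain smoothing: voxel-grid geodesics staircase around the tube axis
# (up to half a voxel laterally, half a slice axially), which inflates
# Euclidean path length by several percent on anisotropic grids. A
# moving-average filter with a ~1 um half-window suppresses that jitter
# while leaving genuine branch curvature (whose sagitta over the window is
# well below the tube radius) essentially untouched; endpoints stay fixed
# so junction and tip geometry is preserved.
.smoothChain <- function(pts, halfWindowUm = 1.0, passes = 2) {
  m <- nrow(pts)
  if (m <= 2) return(pts)
  # convert the physical half-window into a point half-width from the
  # median step length of this chain
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-m, , drop = FALSE])^2))
  med <- stats::median(steps)
  h <- max(1L, min(4L, round(halfWindowUm / max(med, 1e-6))))
  for (pass in seq_len(passes)) {
    sm <- pts
    for (i in 2:(m - 1)) {
      lo <- max(1L, i - h); hi <- min(m, i + h)
      sm[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
    }
    pts <- sm
  }
  pts
}

#' Trace per-cell filament skeletons by intensity-weighted geodesics
#'
#' For every starting point a shortest-path tree is grown over the voxel
#' grid (Dijkstra; edge weight = physical length x (0.01 + 1 - I)^gamma on
#' the min-max normalized channel; sub-floor voxels carry a large constant
#' penalty so faint gaps can be bridged and later pruned by
#' \code{\link{removeDisconnectedSegments}}). Each seed is assigned to the
#' starting point of minimal geodesic cost, the union of seed-to-soma
#' geodesics forms the cell's tree (redundant parallel paths are merged
#' within a resolution-aware radius), the soma interior (within one
#' starting radius of the starting point) is collapsed into the soma node,
#' chains are smoothed to remove the voxel staircase, polylines are
#' resampled to at most 0.5 um node spacing, terminal spurs shorter than
#' \code{params@pruneSpurUm} are pruned, and tips are extended to the
#' half-maximum edge of the tube end.
#'
#' @param iba1 membrane channel.
#' @param startingPoints,seeds data.frames from the detectors (positions in
#'   um).
#' @param params a \code{\link{TraceParams}}.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return list of \code{\link{FilamentGraph}}, one per starting point.
#' @export
traceFilaments <- function(iba1, startingPoints, seeds, params, voxelSize) {
  validObject(params)
  if (nrow(startingPoints) == 0)
    stop("no starting points; tracing requires at least one", call. = FALSE)
  dims <- dim(iba1)
  chn <- .normalize01(iba1)
  dim(chn) <- dims
  f <- (.COST_EPS + 1 - chn)^params@costExponent
  f[chn < params@intensityFloor] <- .GAP_PENALTY

  srcKji <- .voxelOf(as.matrix(startingPoints[, c("x", "y", "z")]),
                     dims, voxelSize)
  srcLin <- .linearIndex0(srcKji, dims)
  nS <- nrow(startingPoints)

  seedLin <- if (nrow(seeds) > 0)
    .linearIndex0(.voxelOf(as.matrix(seeds[, c("x", "y", "z")]),
                           dims, voxelSize), dims) else integer(0)

  dists <- vector("list", nS); preds <- vector("list", nS)
  for (s in seq_len(nS)) {
    res <- cpp_dijkstra(as.vector(f), as.integer(dims),
                        as.numeric(voxelSize), as.integer(srcLin[s]),
                        as.integer(c(seedLin, srcLin)))
    dists[[s]] <- res$dist; preds[[s]] <- res$pred
  }

  seedOwner <- integer(0)
  seedCost <- numeric(0)
  if (length(seedLin) > 0) {
    costs <- vapply(seq_len(nS), function(s) dists[[s]][seedLin + 1L],
                    numeric(length(seedLin)))
    costs <- matrix(costs, nrow = length(seedLin))
    best <- apply(costs, 1, function(r) {
      if (all(!is.finite(r))) NA_integer_ else which.min(r)
    })
    reach <- !is.na(best)
    seedLin <- seedLin[reach]
    seedOwner <- best[reach]
    seedCost <- costs[cbind(seq_len(nrow(costs)), best)][reach]
  }

  graphs <- vector("list", nS)
  for (s in seq_len(nS)) {
    mySeeds <- seedLin[seedOwner == s]
    myCosts <- seedCost[seedOwner == s]
    center <- as.numeric(startingPoints[s, c("x", "y", "z")])
    rs <- params@startingDiameterUm / 2
    somaRadius <- rs
    if (length(mySeeds) == 0) {
      nodes <- data.frame(x = center[1], y = center[2], z = center[3],
                          radius = somaRadius)
      graphs[[s]] <- FilamentGraph(nodes, matrix(integer(0), ncol = 2),
                                   somaNode = 1L,
                                   cellId = sprintf("cell%02d", s),
                                   meta = list(params = params))
      next
    }
    # per-axis merge radii: at least the seed radius, and never below the
    # voxel pitch of that axis (paths one z-slice apart must merge on
    # anisotropic grids without fattening the lateral merge ball)
    mergeR <- pmax(params@seedDiameterUm / 2, 1.1 * rev(voxelSize))
    vt <- .voxelTree(preds[[s]], mySeeds, myCosts, srcLin[s], dims,
                     voxelSize, mergeRadius = mergeR,
                     iba1n = as.vector(chn),
                     floorVal = params@intensityFloor)
    cs <- .collapseSoma(vt$P, vt$parent, vt$root, center, rs)
    # straighten + resample chains, then assemble the final tree
    chains <- .chainsOf(cs$parent, cs$root)
    keyIds <- sort(unique(c(cs$root,
                            unlist(lapply(chains, function(ch) ch[c(1, length(ch))])))))
    newIdOfKey <- setNames(seq_along(keyIds), keyIds)
    P2 <- lapply(keyIds, function(u) cs$P[u, ])
    parent2 <- rep(NA_integer_, length(keyIds))
    parent2[newIdOfKey[as.character(cs$root)]] <- 0L
    for (ch in chains) {
      pts <- cs$P[ch, , drop = FALSE]
      if (nrow(pts) > 2) {
        # re-center interior points on the intensity ridge (geodesics cut
        # through the bright soma halo near curved proximal trunks), then
        # smooth the voxel staircase
        interior <- 2:(nrow(pts) - 1)
        pts[interior, ] <- .centroidRefine(pts[interior, , drop = FALSE],
                                           chn, params@seedDiameterUm / 2,
                                           voxelSize, iters = 1)
        pts <- .smoothChain(pts)
      }
      pts <- .resamplePolyline(pts, 0.5)
      a <- newIdOfKey[as.character(ch[1])]
      b <- newIdOfKey[as.character(ch[length(ch)])]
      prev <- a
      if (nrow(pts) > 2) {
        for (r in 2:(nrow(pts) - 1)) {
          P2[[length(P2) + 1]] <- pts[r, ]
          parent2 <- c(parent2, prev)
          prev <- length(P2)
        }
      }
      parent2[b] <- prev
    }
    P2 <- do.call(rbind, P2)
    parent2 <- as.integer(parent2)
    root2 <- which(parent2 == 0L)

    pr <- .pruneSpursIter(P2, parent2, root2, params@pruneSpurUm)
    P2 <- pr$P; parent2 <- pr$parent; root2 <- pr$root
    ext <- .extendTips(P2, parent2, root2, chn, dims, voxelSize,
                       params@intensityFloor, somaRadius = rs)
    P2 <- ext$P; parent2 <- ext$parent

    ord <- .bfsOrder(parent2, root2)
    remap <- integer(length(parent2)); remap[ord] <- seq_along(ord)
    nodes <- data.frame(x = P2[ord, 1], y = P2[ord, 2], z = P2[ord, 3],
                        radius = params@seedDiameterUm / 2)
    nodes$radius[1] <- somaRadius
    edges <- cbind(remap[parent2[ord[-1]]], seq_along(ord)[-1])
    graphs[[s]] <- FilamentGraph(nodes, edges, somaNode = 1L,
                                 cellId = sprintf("cell%02d", s),
                                 meta = list(params = params,
                                             startingPoint = center))
  }
  graphs
}

# extend each terminal branch outward along its final direction while the
# interpolated intensity stays above half the on-tip value (and the floor):
# seed detection places the last seed slightly inside the tip, so without
# this every terminal branch ends ~half a seed radius short
.extendTips <- function(P, parent, root, iba1n, dims, voxelSize, floorVal,
                        stepUm = 0.1, maxUm = 2, somaRadius = 0) {
  n <- nrow(P)
  if (n < 2) return(list(P = P, parent = parent))
  isLeaf <- !(seq_len(n) %in% parent) & seq_len(n) != root
  for (u in which(isLeaf)) {
    p <- parent[u]
    dirv <- P[u, ] - P[p, ]
    nl <- sqrt(sum(dirv^2))
    if (nl == 0) next
    dirv <- dirv / nl
    v0 <- cpp_trilinear(as.vector(iba1n), as.integer(dims),
                        as.numeric(voxelSize), matrix(P[u, ], 1))
    if (is.na(v0) || v0 < floorVal) next
    lim <- max(floorVal, v0 / 2)
    steps <- seq(stepUm, maxUm, by = stepUm)
    smp <- P[rep(u, length(steps)), , drop = FALSE] + outer(steps, dirv)
    vals <- cpp_trilinear(as.vector(iba1n), as.integer(dims),
                          as.numeric(voxelSize), smp)
    vals[is.na(vals)] <- -Inf
    # never extend into the soma sphere (intensity rises there, which
    # would pull shell-hugging tips inward indefinitely)
    if (somaRadius > 0) {
      dcen <- sqrt(rowSums((smp - matrix(P[root, ], nrow(smp), 3,
                                         byrow = TRUE))^2))
      vals[dcen < somaRadius] <- -Inf
    }
    stop_at <- which(vals < lim)[1]
    if (is.na(stop_at)) stop_at <- length(steps) + 1L
    if (stop_at <= 1L) next
    extLen <- steps[stop_at - 1L]
    # keep the <= 0.5 um node spacing of the resampled tree
    nseg <- max(1L, ceiling(extLen / 0.5))
    prev <- u
    for (sgm in seq_len(nseg)) {
      P <- rbind(P, P[u, ] + dirv * extLen * sgm / nseg)
      parent <- c(parent, prev)
      prev <- nrow(P)
    }
  }
  list(P = P, parent = parent)
}

.bfsOrder <- function(parent, root) {
  n <- length(parent)
  children <- split(seq_len(n), factor(parent, levels = 0:n))[-1]
  ordq <- root; pos <- 1L
  while (pos <= length(ordq)) {
    u <- ordq[pos]; pos <- pos + 1L
    ordq <- c(ordq, children[[u]])
  }
  ordq
}

# iterative spur pruning (see .pruneSpurs): delete terminal chains shorter
# than minLen, shortest first, re-deriving chains after each deletion
.pruneSpursIter <- function(P, parent, root, minLen) {
  repeat {
    n <- nrow(P)
    if (n <= 1) break
    nkids <- tabulate(parent[parent > 0], nbins = n)
    chains <- .chainsOf(parent, root)
    term <- Filter(function(ch) nkids[ch[length(ch)]] == 0, chains)
    if (length(term) == 0) break
    lens <- vapply(term, function(ch) {
      sum(sqrt(rowSums((P[ch[-1], , drop = FALSE] -
                          P[ch[-length(ch)], , drop = FALSE])^2)))
    }, 0)
    short <- which(lens < minLen)
    if (length(short) == 0) break
    victim <- term[[short[which.min(lens[short])]]]
    drop <- victim[-1]
    keep <- setdiff(seq_len(n), drop)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    newParent <- parent[keep]
    newParent[newParent > 0] <- remap[newParent[newParent > 0]]
    P <- P[keep, , drop = FALSE]
    parent <- newParent
    root <- remap[root]
  }
  list(P = P, parent = parent, root = root)
}

#' Remove branches attached across over-long sub-floor gaps
#'
#' Walks the tree from the soma outward, accumulating the length of
#' contiguous runs of nodes whose normalized intensity lies below the trace
#' floor; as soon as a run exceeds \code{maxGapUm}, the run and everything
#' distal to it are deleted. This is the automated counterpart of capping
#' the maximum gap length so that autopathing cannot make an unnecessary
#' leap across the field to a seed in another structure.
#'
#' @param graph a \code{\link{FilamentGraph}} from
#'   \code{\link{traceFilaments}}.
#' @param iba1 the membrane channel the graph was traced on.
#' @param maxGapUm maximum bridgeable gap (um); defaults to the traced
#'   parameters. \code{Inf} is the identity.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return a pruned \code{\link{FilamentGraph}}.
#' @export
removeDisconnectedSegments <- function(graph, iba1, maxGapUm = NULL,
                                       voxelSize) {
  params <- graph@meta$params
  if (is.null(maxGapUm)) maxGapUm <- params@maxGapUm
  if (!is.finite(maxGapUm)) return(graph)
  floorVal <- if (!is.null(params)) params@intensityFloor else 0.08
  dims <- dim(iba1)
  chn <- .normalize01(iba1)
  dim(chn) <- dims
  nodes <- graph@nodes
  vals <- cpp_trilinear(as.vector(chn), as.integer(dims),
                        as.numeric(voxelSize),
                        as.matrix(nodes[, c("x", "y", "z")]))
  below <- is.na(vals) | vals < floorVal
  below[graph@somaNode] <- FALSE

  dirE <- .orientEdges(graph)
  n <- nrow(nodes)
  childList <- split(dirE[, 2], factor(dirE[, 1], levels = seq_len(n)))
  elen <- sqrt(rowSums((as.matrix(nodes[dirE[, 1], c("x", "y", "z")]) -
                          as.matrix(nodes[dirE[, 2], c("x", "y", "z")]))^2))
  elenOf <- new.env(hash = TRUE)
  for (r in seq_len(nrow(dirE)))
    assign(paste(dirE[r, 1], dirE[r, 2]), elen[r], envir = elenOf)

  killed <- logical(n)
  # DFS with per-node accumulated sub-floor run length. Two details
  # matter: (1) the run only resets after >= 1 um of contiguous
  # supra-floor path (hysteresis) — under shot noise a few percent of
  # background voxels poke above the floor, and a single bright speck
  # must not break a gap in two; (2) once a run exceeds the maximum gap,
  # deletion starts at the FIRST node of the run, so the whole bridged
  # gap disappears along with everything distal to it.
  resetRunUm <- 1.0
  stack <- list(list(node = graph@somaNode, run = 0, bright = resetRunUm,
                     runStart = NA_integer_))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    u <- top$node
    for (v in childList[[u]]) {
      el <- get(paste(u, v), envir = elenOf)
      runStart <- top$runStart
      if (below[v]) {
        run <- top$run + el
        bright <- 0
        if (top$run == 0 || is.na(runStart)) runStart <- v
      } else {
        bright <- top$bright + el
        if (bright >= resetRunUm) { run <- 0; runStart <- NA_integer_ }
        else run <- top$run
      }
      isLeaf <- length(childList[[v]]) == 0
      if (run > maxGapUm || (isLeaf && run > 0)) {
        # delete the run from its first node, with its whole subtree: a
        # gap is only a bridge if it lands on real structure, so an
        # over-long run — or one still active at a leaf — goes entirely
        q <- runStart; pos <- 1L
        while (pos <= length(q)) {
          w <- q[pos]; pos <- pos + 1L
          killed[w] <- TRUE
          q <- c(q, childList[[w]])
        }
      } else {
        stack[[length(stack) + 1]] <- list(node = v, run = run,
                                           bright = bright,
                                           runStart = runStart)
      }
    }
  }
  if (!any(killed)) return(graph)
  keep <- which(!killed)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  ed <- graph@edges
  ekeep <- !killed[ed[, 1]] & !killed[ed[, 2]]
  FilamentGraph(graph@nodes[keep, , drop = FALSE],
                cbind(remap[ed[ekeep, 1]], remap[ed[ekeep, 2]]),
                somaNode = remap[graph@somaNode],
                somaVolumeUm3 = graph@somaVolumeUm3,
                cellId = graph@cellId, animalId = graph@animalId,
                group = graph@group, age = graph@age, meta = graph@meta)
}

#' Fit node radii from image intensity (FWHM)
#'
#' For every non-soma node, eight rays are cast in the plane normal to the
#' local tangent; along each ray the radius is the distance at which the
#' interpolated intensity first falls below half the on-axis value
#' (linearly interpolated between 0.05 um samples; full width at half
#' maximum). The node radius is the mean over rays, clamped to
#' [0.1 um, startingDiameter / 2]. The soma node keeps its radius.
#'
#' @param graph a \code{\link{FilamentGraph}}.
#' @param iba1 membrane channel.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return the graph with fitted radii.
#' @export
fitDiameters <- function(graph, iba1, voxelSize) {
  params <- graph@meta$params
  rmax <- if (!is.null(params)) params@startingDiameterUm / 2 else 5
  dims <- dim(iba1)
  chn <- .normalize01(iba1)
  dim(chn) <- dims
  nodes <- graph@nodes
  n <- nrow(nodes)
  if (n <= 1) return(graph)
  dirE <- .orientEdges(graph)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])

  nbr <- vector("list", n)
  for (r in seq_len(nrow(dirE))) {
    nbr[[dirE[r, 1]]] <- c(nbr[[dirE[r, 1]]], dirE[r, 2])
    nbr[[dirE[r, 2]]] <- c(nbr[[dirE[r, 2]]], dirE[r, 1])
  }
  stepUm <- 0.05
  rseq <- seq(stepUm, rmax, by = stepUm)
  nray <- 8L
  nstep <- length(rseq)
  radii <- nodes$radius
  ids <- which(seq_len(n) != graph@somaNode &
                 vapply(nbr, length, 1L) > 0)
  if (length(ids) == 0) return(graph)

  # ray directions per node: 8 spokes in the plane normal to the tangent
  raysOf <- function(u) {
    nb <- nbr[[u]]
    tang <- if (length(nb) == 1) .unit(xyz[u, ] - xyz[nb, ]) else
      .unit(xyz[nb[length(nb)], ] - xyz[nb[1], ])
    if (all(tang == 0) || anyNA(tang)) tang <- c(1, 0, 0)
    e1 <- .perp(tang)
    e2 <- .unit(c(tang[2] * e1[3] - tang[3] * e1[2],
                  tang[3] * e1[1] - tang[1] * e1[3],
                  tang[1] * e1[2] - tang[2] * e1[1]))
    ang <- 2 * pi * (seq_len(nray) - 1) / nray
    outer(cos(ang), e1) + outer(sin(ang), e2)    # nray x 3
  }
  dirs <- lapply(ids, raysOf)

  v0 <- cpp_trilinear(as.vector(chn), as.integer(dims),
                      as.numeric(voxelSize), xyz[ids, , drop = FALSE])
  # one interpolation call for every node x ray x radial step
  smp <- do.call(rbind, lapply(seq_along(ids), function(ii) {
    base <- xyz[ids[ii], ]
    dd <- dirs[[ii]]
    do.call(rbind, lapply(seq_len(nray), function(q)
      rep(base, each = nstep) + outer(rseq, dd[q, ])))
  }))
  vals <- cpp_trilinear(as.vector(chn), as.integer(dims),
                        as.numeric(voxelSize), smp)
  vals[is.na(vals)] <- 0
  dim(vals) <- c(nstep, nray, length(ids))

  for (ii in seq_along(ids)) {
    u <- ids[ii]
    if (is.na(v0[ii]) || v0[ii] <= 0) next
    half <- v0[ii] / 2
    rayR <- rep(NA_real_, nray)
    for (q in seq_len(nray)) {
      vq <- vals[, q, ii]
      idx <- which(vq < half)[1]
      # a ray that never falls below half-maximum is running along a
      # neighbouring structure (junction, adjacent branch): exclude it
      if (is.na(idx)) next
      if (idx == 1) {
        frac <- (v0[ii] - half) / max(v0[ii] - vq[1], 1e-12)
        rayR[q] <- frac * stepUm
      } else {
        frac <- (vq[idx - 1] - half) / max(vq[idx - 1] - vq[idx], 1e-12)
        rayR[q] <- rseq[idx - 1] + frac * stepUm
      }
    }
    fit <- if (all(is.na(rayR))) rmax else mean(rayR, na.rm = TRUE)
    radii[u] <- min(max(fit, 0.1), rmax)
  }
  nodes$radius <- radii
  graph@nodes <- nodes
  graph
}

#' Import soma volumes from the colocalization channel
#'
#' For each graph, the supra-threshold colocalization component containing
#' its soma node supplies the soma volume (component voxel count times
#' voxel volume), and the soma node radius is refined to the equal-volume
#' sphere — the imported soma replaces the starting-point sphere, so hull
#' and filament-volume metrics use the measured body rather than the
#' user-supplied starting diameter. When no component contains the soma
#' the volume falls back to the sphere implied by the starting diameter
#' and the graph is flagged (\code{meta$somaFallback}).
#'
#' @param graphs list of \code{\link{FilamentGraph}}.
#' @param coloc colocalization channel.
#' @param threshold component threshold on the (already [0,1]) channel.
#' @param voxelSize (z, y, x) voxel size in um.
#' @return the graphs with \code{somaVolumeUm3} set.
#' @export
importSomas <- function(graphs, coloc, threshold, voxelSize) {
  dims <- dim(coloc)
  labels <- cpp_label26(as.vector(coloc > threshold), as.integer(dims))
  dim(labels) <- dims
  voxvol <- prod(voxelSize)
  counts <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  lapply(graphs, function(g) {
    soma <- as.numeric(g@nodes[g@somaNode, c("x", "y", "z")])
    kji <- .voxelOf(soma, dims, voxelSize)
    lab <- labels[kji]
    if (lab > 0) {
      g@somaVolumeUm3 <- counts[lab] * voxvol
      # the imported soma replaces the starting-point sphere: refine the
      # soma node radius to the equal-volume sphere so downstream hull and
      # volume use the measured body, not the (oversized) starting diameter
      g@nodes$radius[g@somaNode] <- (3 * g@somaVolumeUm3 / (4 * pi))^(1 / 3)
      g@meta$somaFallback <- FALSE
    } else {
      r <- g@nodes$radius[g@somaNode]
      g@somaVolumeUm3 <- 4 / 3 * pi * r^3
      g@meta$somaFallback <- TRUE
    }
    g
  })
}
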