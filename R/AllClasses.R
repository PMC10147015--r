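#' @useDynLib MicrogliaMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif rpois quantile wilcox.test kruskal.test
#'   ks.test pnorm pchisq aggregate sd setNames cov
#' @importFrom utils write.csv read.csv head
NULL

# ---------------------------------------------------------------- CellSpec --

#' Parametric description of a synthetic microglia-like cell
#'
#' A \code{CellSpec} holds the generative parameters of one branching cell:
#' soma and nucleus size, number of primary processes, per-junction
#' bifurcation probability, segment length distribution, maximum branch
#' order, step-angle tortuosity, initial process radius and per-order radius
#' taper, and the fluorescence intensities (arbitrary units on a [0, 1] full
#' scale) painted into the membrane channel for soma and processes.
#'
#' @slot somaRadiusUm,nucleusRadiusUm soma / nucleus radius (um); the nucleus
#'   must fit inside the soma.
#' @slot nPrimary number of primary processes leaving the soma.
#' @slot branchProb probability of a bifurcation at the end of each segment
#'   (while below \code{maxOrder}).
#' @slot segmentLengthMeanUm,segmentLengthSdUm segment length distribution (um).
#' @slot maxOrder maximum branch order.
#' @slot tortuosity step-angle jitter (radians, sd) applied per ~1 um growth
#'   step; 0 gives straight processes.
#' @slot processRadiusUm radius of first-order processes (um).
#' @slot taper radius multiplier per branch order, in (0, 1].
#' @slot intensitySoma,intensityProcess painted intensities (a.u.).
#' @export
setClass("CellSpec", representation(
  somaRadiusUm = "numeric", nucleusRadiusUm = "numeric",
  nPrimary = "numeric", branchProb = "numeric",
  segmentLengthMeanUm = "numeric", segmentLengthSdUm = "numeric",
  maxOrder = "numeric", tortuosity = "numeric",
  processRadiusUm = "numeric", taper = "numeric",
  intensitySoma = "numeric", intensityProcess = "numeric"))

setValidity("CellSpec", function(object) {
  e <- character(0)
  pos <- c(somaRadiusUm = object@somaRadiusUm,
           nucleusRadiusUm = object@nucleusRadiusUm,
           segmentLengthMeanUm = object@segmentLengthMeanUm,
           processRadiusUm = object@processRadiusUm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    e <- c(e, "all lengths must be positive")
  if (object@segmentLengthSdUm < 0) e <- c(e, "segmentLengthSdUm must be >= 0")
  if (object@branchProb < 0 || object@branchProb > 1)
    e <- c(e, "branchProb must be in [0, 1]")
  if (object@taper <= 0 || object@taper > 1)
    e <- c(e, "taper must be in (0, 1]")
  if (object@nucleusRadiusUm > object@somaRadiusUm)
    e <- c(e, "nucleusRadiusUm must not exceed somaRadiusUm")
  if (object@nPrimary < 0 || object@nPrimary != round(object@nPrimary))
    e <- c(e, "nPrimary must be a nonnegative integer")
  if (object@maxOrder < 1) e <- c(e, "maxOrder must be >= 1")
  if (object@tortuosity < 0) e <- c(e, "tortuosity must be >= 0")
  if (length(e)) e else TRUE
})

#' @rdname CellSpec-class
#' @param somaRadiusUm,nucleusRadiusUm,nPrimary,branchProb see slots.
#' @param segmentLengthMeanUm,segmentLengthSdUm,maxOrder,tortuosity see slots.
#' @param processRadiusUm,taper,intensitySoma,intensityProcess see slots.
#' @return a validated \code{CellSpec}.
#' @export
CellSpec <- function(somaRadiusUm = 3.5, nucleusRadiusUm = 2.5,
                     nPrimary = 4, branchProb = 0.4,
                     segmentLengthMeanUm = 6, segmentLengthSdUm = 1.5,
                     maxOrder = 3, tortuosity = 0.4,
                     processRadiusUm = 0.6, taper = 0.85,
                     intensitySoma = 0.75, intensityProcess = 0.55) {
  new("CellSpec", somaRadiusUm = somaRadiusUm,
      nucleusRadiusUm = nucleusRadiusUm, nPrimary = nPrimary,
      branchProb = branchProb, segmentLengthMeanUm = segmentLengthMeanUm,
      segmentLengthSdUm = segmentLengthSdUm, maxOrder = maxOrder,
      tortuosity = tortuosity, processRadiusUm = processRadiusUm,
      taper = taper, intensitySoma = intensitySoma,
      intensityProcess = intensityProcess)
}

setMethod("show", "CellSpec", function(object) {
  cat("CellSpec: soma", object@somaRadiusUm, "um, nucleus",
      object@nucleusRadiusUm, "um,", object@nPrimary,
      "primaries, branchProb", object@branchProb, ", maxOrder",
      object@maxOrder, "\n")
})

# --------------------------------------------------------------- SceneSpec --

#' Acquisition geometry and composition of a synthetic scene
#'
#' Defaults reproduce the acquisition geometry the pipeline targets: a
#' 101.54 x 101.54 um field sampled at 1440 x 1440 pixels
#' (voxel 101.54/1440 ~ 0.0705 um laterally), 0.8 um optical slicing and a
#' 16-bit dynamic range with background at 2 percent of full scale.
#'
#' @slot fieldXYUm lateral field extent (um; square field).
#' @slot nSlices number of z slices.
#' @slot voxelXYUm,voxelZUm voxel pitch (um).
#' @slot nCells number of cells to place.
#' @slot minSomaSeparationUm minimum pairwise soma distance (um).
#' @slot psfSigmaUm Gaussian PSF sigma (z, y, x) in um.
#' @slot noiseGaussianSd additive Gaussian sd on the [0, 1] scale.
#' @slot noisePoissonScale photon count at full scale for Poisson shot noise
#'   (0 disables).
#' @slot nDebris,debrisRadiusUm,debrisIntensity bright-debris field;
#'   the default intensity exceeds full scale so deposits saturate the
#'   detector after PSF blur, as antibody deposits do in real acquisitions.
#' @slot seed RNG seed; a fixed seed makes the scene byte-identical.
#' @export
setClass("SceneSpec", representation(
  fieldXYUm = "numeric", nSlices = "numeric",
  voxelXYUm = "numeric", voxelZUm = "numeric",
  nCells = "numeric", minSomaSeparationUm = "numeric",
  psfSigmaUm = "numeric", noiseGaussianSd = "numeric",
  noisePoissonScale = "numeric", nDebris = "numeric",
  debrisRadiusUm = "numeric", debrisIntensity = "numeric",
  seed = "numeric"))

setValidity("SceneSpec", function(object) {
  e <- character(0)
  if (object@fieldXYUm <= 0 || object@voxelXYUm <= 0 || object@voxelZUm <= 0)
    e <- c(e, "field and voxel sizes must be positive")
  if (object@nSlices < 1) e <- c(e, "nSlices must be >= 1")
  if (object@nCells < 0) e <- c(e, "nCells must be >= 0")
  if (length(object@psfSigmaUm) != 3 || any(object@psfSigmaUm < 0))
    e <- c(e, "psfSigmaUm must be a nonnegative 3-vector (z, y, x)")
  if (object@noiseGaussianSd < 0 || object@noisePoissonScale < 0)
    e <- c(e, "noise parameters must be nonnegative")
  if (object@nDebris < 0) e <- c(e, "nDebris must be >= 0")
  if (length(e)) e else TRUE
})

#' @rdname SceneSpec-class
#' @param fieldXYUm,nSlices,voxelXYUm,voxelZUm,nCells,minSomaSeparationUm see slots.
#' @param psfSigmaUm,noiseGaussianSd,noisePoissonScale see slots.
#' @param nDebris,debrisRadiusUm,debrisIntensity,seed see slots.
#' @return a validated \code{SceneSpec}.
#' @export
SceneSpec <- function(fieldXYUm = 101.54, nSlices = 63,
                      voxelXYUm = 101.54 / 1440, voxelZUm = 0.8,
                      nCells = 1, minSomaSeparationUm = 20,
                      psfSigmaUm = c(0.5, 0.15, 0.15),
                      noiseGaussianSd = 0.01, noisePoissonScale = 200,
                      nDebris = 0, debrisRadiusUm = 0.5,
                      debrisIntensity = 2.5, seed = 1) {
  new("SceneSpec", fieldXYUm = fieldXYUm, nSlices = nSlices,
      voxelXYUm = voxelXYUm, voxelZUm = voxelZUm, nCells = nCells,
      minSomaSeparationUm = minSomaSeparationUm, psfSigmaUm = psfSigmaUm,
      noiseGaussianSd = noiseGaussianSd,
      noisePoissonScale = noisePoissonScale, nDebris = nDebris,
      debrisRadiusUm = debrisRadiusUm, debrisIntensity = debrisIntensity,
      seed = seed)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %.4g um field, %d slices, voxel %.4g x %.4g x %.4g um (z,y,x), %d cell(s), %d debris, seed %d\n",
              object@fieldXYUm, as.integer(object@nSlices),
              object@voxelZUm, object@voxelXYUm, object@voxelXYUm,
              as.integer(object@nCells), as.integer(object@nDebris),
              as.integer(object@seed)))
})

# -------------------------------------------------------------- ImageStack --

#' Multichannel anisotropic 3D image stack
#'
#' Channels are named 3D arrays of identical shape with
#' \code{dim = c(nz, ny, nx)} (slice, row, column). Voxel sizes are stored as
#' (z, y, x) in micrometres. The physical coordinate of 1-based voxel
#' (k, j, i) is ((i-0.5)*vx, (j-0.5)*vy, (k-0.5)*vz), reported (x, y, z);
#' this single convention is used by the rasterizer, the tracer and all
#' morphometry.
#'
#' @slot channels named list of 3D numeric arrays.
#' @slot voxelSize numeric (vz, vy, vx) in um, all positive.
#' @slot bitDepth source integer bit depth (16 for the targeted acquisitions).
#' @slot provenance free-text metadata.
#' @export
setClass("ImageStack", representation(
  channels = "list", voxelSize = "numeric",
  bitDepth = "numeric", provenance = "character"))

setValidity("ImageStack", function(object) {
  e <- character(0)
  if (length(object@channels) == 0) e <- c(e, "at least one channel required")
  if (is.null(names(object@channels)) || any(names(object@channels) == ""))
    e <- c(e, "channels must be named")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    e <- c(e, "channels must be 3D arrays (nz, ny, nx)")
  else if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    e <- c(e, "all channels must share one shape")
  if (length(object@voxelSize) != 3 || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    e <- c(e, "voxelSize must be three positive values (z, y, x) in um")
  if (length(e)) e else TRUE
})

#' @rdname ImageStack-class
#' @param channels,voxelSize,bitDepth,provenance see slots.
#' @export
ImageStack <- function(channels, voxelSize, bitDepth = 16,
                       provenance = character(0)) {
  new("ImageStack", channels = channels, voxelSize = as.numeric(voxelSize),
      bitDepth = bitDepth, provenance = provenance)
}

#' @rdname ImageStack-class
#' @param x,object an \code{ImageStack}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' @rdname ImageStack-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname ImageStack-class
#' @export
setMethod("getChannel", "ImageStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel '", name, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})

#' @rdname ImageStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageStack-class
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@channels[[1]]))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat(sprintf("ImageStack: %d x %d x %d (z,y,x), %d channel(s): %s; voxel %.4g x %.4g x %.4g um; %d-bit\n",
              d[1], d[2], d[3], length(object@channels),
              paste(names(object@channels), collapse = ", "),
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              as.integer(object@bitDepth)))
})

# ----------------------------------------------------------- FilamentGraph --

#' Per-cell filament skeleton
#'
#' A rooted tree in physical micrometres: nodes carry 3D positions and radii,
#' undirected edges form a tree, and one node is designated the soma.
#'
#' @slot nodes data.frame with columns \code{x}, \code{y}, \code{z} (um) and
#'   \code{radius} (um); row order defines node ids 1..n.
#' @slot edges integer matrix, two columns of node ids; \code{nrow = n - 1}.
#' @slot somaNode integer id of the soma node.
#' @slot somaVolumeUm3 imported soma volume (um^3; \code{NA} until
#'   \code{\link{importSomas}} runs).
#' @slot cellId,animalId,group,age identifier labels.
#' @slot meta free-form list (trace parameters, flags).
#' @export
setClass("FilamentGraph", representation(
  nodes = "data.frame", edges = "matrix", somaNode = "integer",
  somaVolumeUm3 = "numeric", cellId = "character", animalId = "character",
  group = "character", age = "character", meta = "list"))

setValidity("FilamentGraph", function(object) {
  e <- character(0)
  n <- nrow(object@nodes)
  if (!all(c("x", "y", "z", "radius") %in% names(object@nodes)))
    e <- c(e, "nodes need columns x, y, z, radius")
  if (n < 1) e <- c(e, "at least one node (the soma) required")
  if (length(object@somaNode) != 1 || is.na(object@somaNode) ||
      object@somaNode < 1 || object@somaNode > n)
    e <- c(e, "somaNode must index a node")
  ed <- object@edges
  if (ncol(ed) != 2) e <- c(e, "edges must have two columns")
  else {
    if (nrow(ed) != n - 1)
      e <- c(e, "a tree on n nodes needs exactly n - 1 edges")
    if (nrow(ed) > 0 && (min(ed) < 1 || max(ed) > n))
      e <- c(e, "edge endpoints out of range")
    # connectivity (union-find); with n-1 edges, connected <=> acyclic
    if (nrow(ed) == n - 1 && n > 1 && length(e) == 0) {
      parent <- seq_len(n)
      find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
      ok <- TRUE
      for (r in seq_len(nrow(ed))) {
        ra <- find(ed[r, 1]); rb <- find(ed[r, 2])
        if (ra == rb) { ok <- FALSE; break }
        parent[ra] <- rb
      }
      if (!ok) e <- c(e, "edges contain a cycle")
    }
  }
  if (n > 0 && any(!is.finite(object@nodes$radius) | object@nodes$radius < 0))
    e <- c(e, "node radii must be nonnegative")
  if (length(e)) e else TRUE
})

#' @rdname FilamentGraph-class
#' @param nodes,edges,somaNode,somaVolumeUm3,cellId,animalId,group,age,meta see slots.
#' @export
FilamentGraph <- function(nodes, edges, somaNode = 1L,
                          somaVolumeUm3 = NA_real_, cellId = "cell",
                          animalId = NA_character_, group = NA_character_,
                          age = NA_character_, meta = list()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  new("FilamentGraph", nodes = nodes, edges = edges,
      somaNode = as.integer(somaNode), somaVolumeUm3 = somaVolumeUm3,
      cellId = cellId, animalId = as.character(animalId),
      group = as.character(group), age = as.character(age), meta = meta)
}

#' @rdname FilamentGraph-class
#' @param x a \code{FilamentGraph}.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname FilamentGraph-class
#' @export
setMethod("nNodes", "FilamentGraph", function(x) nrow(x@nodes))

#' @rdname FilamentGraph-class
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname FilamentGraph-class
#' @export
setMethod("graphNodes", "FilamentGraph", function(x) x@nodes)

#' @rdname FilamentGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname FilamentGraph-class
#' @export
setMethod("graphEdges", "FilamentGraph", function(x) x@edges)

#' @rdname FilamentGraph-class
#' @export
setGeneric("somaNode", function(x) standardGeneric("somaNode"))

#' @rdname FilamentGraph-class
#' @export
setMethod("somaNode", "FilamentGraph", function(x) x@somaNode)

#' Leaf node ids of a filament tree (degree-1 nodes other than the soma)
#' @param x a \code{FilamentGraph}.
#' @return integer vector of node ids.
#' @export
leafNodes <- function(x) {
  n <- nNodes(x)
  deg <- tabulate(c(x@edges[, 1], x@edges[, 2]), nbins = n)
  setdiff(which(deg == 1), x@somaNode)
}

setMethod("show", "FilamentGraph", function(object) {
  cat(sprintf("FilamentGraph '%s': %d nodes, %d edges, soma node %d%s\n",
              object@cellId, nrow(object@nodes), nrow(object@edges),
              object@somaNode,
              if (is.na(object@somaVolumeUm3)) ""
              else sprintf(", soma volume %.4g um^3", object@somaVolumeUm3)))
})

# ------------------------------------------------------------- TraceParams --

#' Parameters of soma / seed detection and filament tracing
#'
#' @slot startingDiameterUm soma-scale blob diameter (um); sets the
#'   Laplacian-of-Gaussian detection scale and the soma sphere used to
#'   collapse traced paths.
#' @slot seedDiameterUm process-scale blob diameter (um); must be smaller
#'   than the starting diameter.
#' @slot startThreshold,seedThreshold detector response thresholds (a.u. on
#'   the scale-normalized LoG response of the min-max normalized channel).
#' @slot removeSeedRadiusFactor seeds closer than this multiple of the
#'   starting radius to any starting point are removed (guards against false
#'   hair-like filaments around the bright soma rim).
#' @slot maxGapUm maximum sub-floor gap a traced branch may bridge before
#'   \code{\link{removeDisconnectedSegments}} deletes it.
#' @slot intensityFloor normalized intensity below which voxels count as
#'   background for tracing.
#' @slot costExponent exponent gamma of the autopath cost
#'   length * (0.01 + 1 - I)^gamma.
#' @slot pruneSpurUm terminal spurs shorter than this are pruned (um).
#' @export
setClass("TraceParams", representation(
  startingDiameterUm = "numeric", seedDiameterUm = "numeric",
  startThreshold = "numeric", seedThreshold = "numeric",
  removeSeedRadiusFactor = "numeric", maxGapUm = "numeric",
  intensityFloor = "numeric", costExponent = "numeric",
  pruneSpurUm = "numeric"))

setValidity("TraceParams", function(object) {
  e <- character(0)
  if (object@startingDiameterUm <= 0 || object@seedDiameterUm <= 0)
    e <- c(e, "diameters must be positive")
  if (object@seedDiameterUm >= object@startingDiameterUm)
    e <- c(e, "seedDiameterUm must be smaller than startingDiameterUm")
  if (object@maxGapUm <= 0) e <- c(e, "maxGapUm must be positive")
  if (object@costExponent < 0) e <- c(e, "costExponent must be >= 0")
  if (object@removeSeedRadiusFactor < 0)
    e <- c(e, "removeSeedRadiusFactor must be >= 0")
  if (length(e)) e else TRUE
})

#' @rdname TraceParams-class
#' @param startingDiameterUm,seedDiameterUm,startThreshold,seedThreshold see slots.
#' @param removeSeedRadiusFactor,maxGapUm,intensityFloor,costExponent,pruneSpurUm see slots.
#' @export
TraceParams <- function(startingDiameterUm = 9, seedDiameterUm = 1.2,
                        startThreshold = 0.05, seedThreshold = 0.04,
                        removeSeedRadiusFactor = 1.0, maxGapUm = 4,
                        intensityFloor = 0.12, costExponent = 2,
                        pruneSpurUm = 1.5) {
  new("TraceParams", startingDiameterUm = startingDiameterUm,
      seedDiameterUm = seedDiameterUm, startThreshold = startThreshold,
      seedThreshold = seedThreshold,
      removeSeedRadiusFactor = removeSeedRadiusFactor, maxGapUm = maxGapUm,
      intensityFloor = intensityFloor, costExponent = costExponent,
      pruneSpurUm = pruneSpurUm)
}

setMethod("show", "TraceParams", function(object) {
  cat(sprintf("TraceParams: starting %g um / seed %g um, thresholds %g / %g, maxGap %g um, floor %g, gamma %g\n",
              object@startingDiameterUm, object@seedDiameterUm,
              object@startThreshold, object@seedThreshold, object@maxGapUm,
              object@intensityFloor, object@costExponent))
})

# ---------------------------------------------------------- DebrisCriteria --

#' Stacked selection criteria for antibody-deposit-like debris
#'
#' Criteria are conjunctive ("stacked"): an object is debris only if it
#' passes every supplied filter; unsupplied (\code{NA}) criteria pass.
#' Deposits are small, bright and round, so the canonical stack is low
#' volume + high intensity + high sphericity.
#'
#' @slot maxVolumeUm3 upper volume bound (um^3).
#' @slot minIntensity lower mean-intensity bound (a.u.).
#' @slot minSphericity lower sphericity bound.
#' @slot minOblateEllipticity optional lower oblate-ellipticity bound.
#' @slot threshold surface creation threshold (a.u., channel units).
#' @slot detailUm isosurface mesh resolution, within [0.1, 0.3] um.
#' @export
setClass("DebrisCriteria", representation(
  maxVolumeUm3 = "numeric", minIntensity = "numeric",
  minSphericity = "numeric", minOblateEllipticity = "numeric",
  threshold = "numeric", detailUm = "numeric"))

setValidity("DebrisCriteria", function(object) {
  e <- character(0)
  if (object@detailUm < 0.1 || object@detailUm > 0.3)
    e <- c(e, "detailUm must lie in [0.1, 0.3] um")
  if (!is.finite(object@threshold)) e <- c(e, "threshold must be finite")
  if (length(e)) e else TRUE
})

#' @rdname DebrisCriteria-class
#' @param maxVolumeUm3,minIntensity,minSphericity,minOblateEllipticity,threshold,detailUm see slots.
#' @export
DebrisCriteria <- function(maxVolumeUm3 = NA_real_, minIntensity = NA_real_,
                           minSphericity = NA_real_,
                           minOblateEllipticity = NA_real_,
                           threshold = 0.5, detailUm = 0.2) {
  new("DebrisCriteria", maxVolumeUm3 = maxVolumeUm3,
      minIntensity = minIntensity, minSphericity = minSphericity,
      minOblateEllipticity = minOblateEllipticity, threshold = threshold,
      detailUm = detailUm)
}

# ------------------------------------------------------------- CellMetrics --

#' Per-cell morphometric record
#'
#' @slot cellId,animalId,group,age identifier labels.
#' @slot totalLengthUm total filament (process) length (um).
#' @slot filamentVolumeUm3 filament volume including the soma (um^3).
#' @slot shollProfile named numeric: intersections per shell radius (um).
#' @slot shollSum total Sholl intersections.
#' @slot hullVolumeUm3,hullAreaUm2 convex hull volume / area.
#' @slot sphericity hull-derived sphericity.
#' @slot nucleusOk nucleus-in-stack QC flag.
#' @slot degenerateHull TRUE when the node set was coplanar/collinear.
#' @export
setClass("CellMetrics", representation(
  cellId = "character", animalId = "character", group = "character",
  age = "character", totalLengthUm = "numeric",
  filamentVolumeUm3 = "numeric", shollProfile = "numeric",
  shollSum = "numeric", hullVolumeUm3 = "numeric", hullAreaUm2 = "numeric",
  sphericity = "numeric", nucleusOk = "logical", degenerateHull = "logical"))

setMethod("show", "CellMetrics", function(object) {
  cat(sprintf("CellMetrics '%s': length %.3g um, volume %.3g um^3, Sholl sum %d, hull %.3g um^3, sphericity %.3g\n",
              object@cellId, object@totalLengthUm, object@filamentVolumeUm3,
              as.integer(object@shollSum), object@hullVolumeUm3,
              object@sphericity))
})

#' Flatten CellMetrics objects into a tidy per-cell table
#'
#' @param metrics a \code{CellMetrics} or list of them.
#' @return data.frame, one row per cell (Sholl profiles are kept long-format
#'   by \code{\link{shollLongTable}}).
#' @export
cellTable <- function(metrics) {
  if (is(metrics, "CellMetrics")) metrics <- list(metrics)
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(cell_id = m@cellId, animal_id = m@animalId, group = m@group,
               age = m@age, total_length_um = m@totalLengthUm,
               filament_volume_um3 = m@filamentVolumeUm3,
               sholl_sum = m@shollSum, hull_volume_um3 = m@hullVolumeUm3,
               hull_area_um2 = m@hullAreaUm2, sphericity = m@sphericity,
               nucleus_ok = m@nucleusOk, degenerate_hull = m@degenerateHull,
               stringsAsFactors = FALSE)
  }))
}

#' Long-format Sholl profile table (cell_id, radius_um, n_intersections)
#' @param metrics a \code{CellMetrics} or list of them.
#' @return data.frame in long format.
#' @export
shollLongTable <- function(metrics) {
  if (is(metrics, "CellMetrics")) metrics <- list(metrics)
  do.call(rbind, lapply(metrics, function(m) {
    if (length(m@shollProfile) == 0)
      return(NULL)
    data.frame(cell_id = m@cellId,
               radius_um = as.numeric(names(m@shollProfile)),
               n_intersections = as.integer(m@shollProfile),
               stringsAsFactors = FALSE)
  }))
}

# ---------------------------------------------------------- SceneGroundTruth --

#' Ground truth of a synthetic scene
#'
#' @slot graphs list of true \code{FilamentGraph} skeletons.
#' @slot metrics list of \code{CellMetrics} from \code{\link{analyticMetrics}}.
#' @slot somaCenters matrix of soma centers (x, y, z um).
#' @slot debrisCenters matrix of debris centers (x, y, z um).
#' @export
setClass("SceneGroundTruth", representation(
  graphs = "list", metrics = "list", somaCenters = "matrix",
  debrisCenters = "matrix"))

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth: %d cell(s), %d debris\n",
              length(object@graphs), nrow(object@debrisCenters)))
})
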