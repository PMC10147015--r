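# Soma/seed detection and filament tracing.

test_that("starting points land on true somas and suppress close pairs", {
  scene <- SceneSpec(fieldXYUm = 70, nSlices = 20, voxelXYUm = 0.4,
                     nCells = 5, minSomaSeparationUm = 18,
                     noiseGaussianSd = 0, noisePoissonScale = 0, seed = 13)
  sim <- rasterizeScene(scene, replicate(5, morphologyPreset("ameboid"),
                                         simplify = FALSE))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 11, seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba),
                                 params, vs)
  expect_equal(nrow(starts), 5)
  tol <- sqrt(sum(vs^2))
  for (i in seq_len(5)) {
    d <- sqrt(rowSums((sim$truth@somaCenters -
                         matrix(unlist(starts[i, c("x", "y", "z")]),
                                5, 3, byrow = TRUE))^2))
    expect_lt(min(d), tol)
  }
  # blank channel: nothing to detect
  expect_equal(nrow(detectStartingPoints(array(0.5, c(6, 20, 20)),
                                         params, c(0.8, 0.5, 0.5))), 0)
})

test_that("two somas closer than one starting diameter collapse to one", {
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 20, voxelXYUm = 0.4,
                     nCells = 2, noiseGaussianSd = 0, noisePoissonScale = 0,
                     seed = 8)
  centers <- rbind(c(18, 20, 8), c(24, 20, 8))   # 6 um apart
  sim <- rasterizeScene(scene, replicate(2, morphologyPreset("ameboid"),
                                         simplify = FALSE),
                        centers = centers)
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  params <- TraceParams(startingDiameterUm = 11, seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params,
                                 voxelSize(sim$stack))
  expect_equal(nrow(starts), 1)
})

test_that("nucleus QC keeps interior nuclei and drops clipped or absent ones", {
  sim <- unitCellScene(seed = 3)
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- unitCellParams()
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params, vs)
  expect_equal(nrow(filterByNucleus(starts, dapi, 0.3, vs)), 1)
  # no DAPI signal at all -> dropped
  blank <- array(0, dim(dapi))
  expect_equal(nrow(filterByNucleus(starts, blank, 0.3, vs)), 0)
  # nucleus clipped at the first slice -> dropped
  scene <- SceneSpec(fieldXYUm = 62, nSlices = 26, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 3)
  simB <- rasterizeScene(scene, list(morphologyPreset("transitional")),
                         centers = matrix(c(31, 31, 1.0), 1))
  dapiB <- getChannel(simB$stack, "dapi")
  ibaB <- getChannel(simB$stack, "iba1")
  startsB <- detectStartingPoints(colocalizationChannel(dapiB, ibaB),
                                  params, vs)
  expect_equal(nrow(filterByNucleus(startsB, dapiB, 0.3, vs)), 0)
})

test_that("seeds follow process axes and respect the soma exclusion", {
  spec <- CellSpec(nPrimary = 1, branchProb = 0, tortuosity = 0,
                   segmentLengthMeanUm = 10, segmentLengthSdUm = 0,
                   maxOrder = 1)
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 20, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 17)
  sim <- rasterizeScene(scene, list(spec), centers = matrix(c(20, 20, 8), 1))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 2 * (spec@somaRadiusUm + 1),
                        seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  d2c <- sqrt((seeds$x - starts$x[1])^2 + (seeds$y - starts$y[1])^2 +
                (seeds$z - starts$z[1])^2)
  expect_gte(nrow(seeds), 5)
  expect_true(all(d2c >= params@startingDiameterUm / 2))
  # blank channel: nothing
  expect_equal(nrow(detectSeedPoints(array(0.5, dim(iba)), params, starts,
                                     vs)), 0)
  # disabling the exclusion can only add seeds
  p0 <- TraceParams(startingDiameterUm = params@startingDiameterUm,
                    seedDiameterUm = 1.2, removeSeedRadiusFactor = 0)
  seeds0 <- detectSeedPoints(iba, p0, starts, vs)
  key <- function(s) paste(round(s$x, 6), round(s$y, 6), round(s$z, 6))
  expect_true(all(key(seeds) %in% key(seeds0)))
})

test_that("tracing recovers a straight tube and handles edge cases", {
  spec <- CellSpec(nPrimary = 1, branchProb = 0, tortuosity = 0,
                   segmentLengthMeanUm = 10, segmentLengthSdUm = 0,
                   maxOrder = 1)
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 20, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 17)
  sim <- rasterizeScene(scene, list(spec), centers = matrix(c(20, 20, 8), 1))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 2 * (spec@somaRadiusUm + 1),
                        seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  g <- traceFilaments(iba, starts, seeds, params, vs)[[1]]
  truthLen <- spec@somaRadiusUm + 10
  expect_equal(totalLength(g), truthLen, tolerance = 0.05)
  validObject(g)

  # no starting points is an error; no seeds gives a soma-only graph
  expect_error(traceFilaments(iba, starts[0, ], seeds, params, vs),
               "no starting points")
  g0 <- traceFilaments(iba, starts, seeds[0, ], params, vs)[[1]]
  expect_equal(nNodes(g0), 1)
  expect_equal(totalLength(g0), 0)
})

test_that("tracing is deterministic and separates distant cells", {
  scene <- SceneSpec(fieldXYUm = 70, nSlices = 20, voxelXYUm = 0.4,
                     nCells = 2, noiseGaussianSd = 0, noisePoissonScale = 0,
                     seed = 23)
  centers <- rbind(c(20, 20, 8), c(50, 50, 8))
  sim <- rasterizeScene(scene, replicate(2, morphologyPreset("ameboid"),
                                         simplify = FALSE),
                        centers = centers)
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 11, seedDiameterUm = 1.2)
  starts <- filterByNucleus(
    detectStartingPoints(colocalizationChannel(dapi, iba), params, vs),
    dapi, 0.3, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  gs1 <- traceFilaments(iba, starts, seeds, params, vs)
  gs2 <- traceFilaments(iba, starts, seeds, params, vs)
  expect_identical(gs1[[1]]@nodes, gs2[[1]]@nodes)
  expect_identical(gs1[[2]]@edges, gs2[[2]]@edges)
  # every node belongs to its own cell's half of the field (graphs come
  # back in detection-score order, so match each to its nearest center)
  for (i in 1:2) {
    soma <- as.numeric(gs1[[i]]@nodes[gs1[[i]]@somaNode, c("x", "y", "z")])
    own <- which.min(rowSums((centers - matrix(soma, 2, 3, byrow = TRUE))^2))
    d_own <- sqrt(rowSums((as.matrix(gs1[[i]]@nodes[, c("x", "y", "z")]) -
                             matrix(centers[own, ], nNodes(gs1[[i]]), 3,
                                    byrow = TRUE))^2))
    expect_true(all(d_own < 21))
  }
})

test_that("over-long sub-floor bridges are removed, short ones kept", {
  spec <- CellSpec(nPrimary = 1, branchProb = 0, tortuosity = 0,
                   segmentLengthMeanUm = 8, segmentLengthSdUm = 0,
                   maxOrder = 1)
  scene <- SceneSpec(fieldXYUm = 50, nSlices = 20, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 33)
  sim <- rasterizeScene(scene, list(spec), centers = matrix(c(14, 25, 8), 1))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  # add a detached 5 um fragment 12 um beyond the process tip, along +x
  frag <- matrix(c(38, 25, 8, 43, 25, 8, 0.6, 0.6,
                   0.55 * 65535), nrow = 1)
  extra <- MicrogliaMorph:::cpp_rasterize_capsules(
    as.integer(dim(iba)), as.numeric(vs), frag, 0.25, 0)
  dim(extra) <- dim(iba)
  iba <- pmax(iba, extra)
  params <- TraceParams(startingDiameterUm = 2 * (spec@somaRadiusUm + 1),
                        seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  g <- traceFilaments(iba, starts, seeds, params, vs)[[1]]
  # the bridge to the fragment is traced ...
  expect_gt(max(g@nodes$x), 36)
  # ... gap 5 um: fragment (and bridge) removed
  g5 <- removeDisconnectedSegments(g, iba, maxGapUm = 5, voxelSize = vs)
  expect_lt(max(g5@nodes$x), 30)
  # an infinite gap allowance is the identity
  gInf <- removeDisconnectedSegments(g, iba, maxGapUm = Inf, voxelSize = vs)
  expect_identical(gInf@nodes, g@nodes)
  # a fully connected graph is untouched
  gOk <- removeDisconnectedSegments(g5, iba, maxGapUm = 4, voxelSize = vs)
  expect_identical(gOk@nodes, g5@nodes)
})

test_that("diameters are fitted from intensity within tolerance", {
  spec <- CellSpec(nPrimary = 1, branchProb = 0, tortuosity = 0,
                   segmentLengthMeanUm = 12, segmentLengthSdUm = 0,
                   maxOrder = 1, processRadiusUm = 0.5, taper = 1)
  scene <- SceneSpec(fieldXYUm = 44, nSlices = 20, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 19)
  sim <- rasterizeScene(scene, list(spec), centers = matrix(c(20, 20, 8), 1))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 2 * (spec@somaRadiusUm + 1),
                        seedDiameterUm = 1.2)
  starts <- detectStartingPoints(colocalizationChannel(dapi, iba), params, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  g <- traceFilaments(iba, starts, seeds, params, vs)[[1]]
  somaR <- g@nodes$radius[g@somaNode]
  g <- fitDiameters(g, iba, vs)
  # soma node keeps its radius; others clamp below the starting radius
  expect_equal(g@nodes$radius[g@somaNode], somaR)
  expect_true(all(g@nodes$radius <= params@startingDiameterUm / 2))
  # mid-process nodes (6-10 um from the soma, direction is random):
  # FWHM radius within 20 percent (PSF-broadened)
  d2c <- sqrt(rowSums((as.matrix(g@nodes[, c("x", "y", "z")]) -
                         matrix(c(20, 20, 8), nNodes(g), 3, byrow = TRUE))^2))
  mid <- setdiff(which(d2c > 6 & d2c < 10), g@somaNode)
  expect_gt(length(mid), 3)
  expect_equal(mean(g@nodes$radius[mid]), 0.5, tolerance = 0.2)
})

test_that("soma volumes import from the colocalization channel", {
  spec <- CellSpec(somaRadiusUm = 3, nucleusRadiusUm = 3, nPrimary = 2,
                   branchProb = 0, segmentLengthMeanUm = 8,
                   segmentLengthSdUm = 0, maxOrder = 1)
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 20, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1, noiseGaussianSd = 0,
                     noisePoissonScale = 0, seed = 29)
  sim <- rasterizeScene(scene, list(spec), centers = matrix(c(20, 20, 8), 1))
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- TraceParams(startingDiameterUm = 8, seedDiameterUm = 1.2)
  coloc <- colocalizationChannel(dapi, iba)
  starts <- detectStartingPoints(coloc, params, vs)
  seeds <- detectSeedPoints(iba, params, starts, vs)
  gs <- traceFilaments(iba, starts, seeds, params, vs)
  gs <- importSomas(gs, coloc, 0.5, vs)
  expect_false(gs[[1]]@meta$somaFallback)
  expect_equal(gs[[1]]@somaVolumeUm3, 4 / 3 * pi * 27, tolerance = 0.1)
  # blank colocalization -> sphere fallback, flagged
  gs2 <- importSomas(gs, array(0, dim(iba)), 0.5, vs)
  expect_true(gs2[[1]]@meta$somaFallback)
  r <- gs2[[1]]@nodes$radius[gs2[[1]]@somaNode]
  expect_equal(gs2[[1]]@somaVolumeUm3, 4 / 3 * pi * r^3)
})

test_that("SWC files round-trip skeletons", {
  set.seed(12)
  g <- sampleTree(morphologyPreset("transitional"), c(30, 30, 10),
                  cellId = "rt")
  path <- tempfile(fileext = ".swc")
  writeSWC(g, path)
  back <- readSWC(path)
  expect_equal(nrow(back@nodes), nrow(g@nodes))
  expect_equal(back@somaNode, g@somaNode)
  expect_equal(totalLength(back), totalLength(g), tolerance = 1e-5)
  unlink(path)
})
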