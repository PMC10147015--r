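# Synthetic scene generator: presets, tree sampling, analytic oracle,
# rasterization.

test_that("morphology presets are valid and reject unknown names", {
  for (p in c("ameboid", "transitional", "surveillance", "hyper_ramified"))
    expect_s4_class(morphologyPreset(p), "CellSpec")
  expect_error(morphologyPreset("amoeboid"), "valid presets")
  expect_error(morphologyPreset("amoeboid"), "ameboid.*surveillance")
})

test_that("preset ordering holds in expectation over sampled cells", {
  set.seed(7)
  stats <- sapply(c("ameboid", "transitional", "surveillance",
                    "hyper_ramified"), function(p) {
    spec <- morphologyPreset(p)
    v <- replicate(50, {
      m <- analyticMetrics(sampleTree(spec, c(0, 0, 0)))
      c(m@totalLengthUm, m@shollSum, m@hullVolumeUm3)
    })
    rowMeans(v)
  })
  expect_true(all(diff(stats[1, ]) > 0))   # length strictly increasing
  expect_true(all(diff(stats[2, ]) > 0))   # Sholl sum strictly increasing
  expect_true(all(stats[3, 1] < stats[3, -1]))  # ameboid hull smallest
})

test_that("sampleTree honours degenerate parameter settings", {
  spec <- CellSpec(nPrimary = 1, branchProb = 0, tortuosity = 0,
                   segmentLengthMeanUm = 10, segmentLengthSdUm = 0,
                   maxOrder = 1)
  set.seed(1)
  g <- sampleTree(spec, c(0, 0, 0))
  expect_length(leafNodes(g), 1)
  # one straight 10 um process beyond the soma-radius attachment edge
  expect_equal(totalLength(g), spec@somaRadiusUm + 10, tolerance = 1e-9)
  tip <- as.numeric(g@nodes[leafNodes(g), c("x", "y", "z")])
  expect_equal(sqrt(sum(tip^2)), spec@somaRadiusUm + 10, tolerance = 1e-9)

  spec4 <- CellSpec(nPrimary = 4, branchProb = 0)
  set.seed(2)
  expect_length(leafNodes(sampleTree(spec4, c(0, 0, 0))), 4)

  spec0 <- CellSpec(nPrimary = 0)
  set.seed(3)
  expect_equal(nNodes(sampleTree(spec0, c(5, 5, 5))), 1)
})

test_that("sampleTree is deterministic under a fixed seed", {
  spec <- morphologyPreset("surveillance")
  set.seed(42); g1 <- sampleTree(spec, c(30, 30, 10))
  set.seed(42); g2 <- sampleTree(spec, c(30, 30, 10))
  expect_identical(g1@nodes, g2@nodes)
  expect_identical(g1@edges, g2@edges)
})

test_that("analytic Sholl profiles match hand geometry", {
  g <- straightProcessGraph(10)
  m <- analyticMetrics(g)
  expect_equal(unname(m@shollProfile), rep(1, 10))
  expect_equal(m@shollSum, 10)

  star <- makeGraph(rbind(c(0, 0, 0), c(5.5, 0, 0), c(-5.5, 0, 0),
                          c(0, 5.5, 0), c(0, -5.5, 0)),
                    cbind(1L, 2:5))
  expect_equal(sum(analyticMetrics(star)@shollProfile), 20)
})

test_that("analytic metrics agree with measureCell on random trees", {
  set.seed(5)
  for (p in c("ameboid", "surveillance")) {
    g <- sampleTree(morphologyPreset(p), c(0, 0, 0))
    a <- analyticMetrics(g)
    m <- measureCell(g)
    expect_equal(a@totalLengthUm, m@totalLengthUm, tolerance = 1e-9)
    expect_identical(a@shollProfile, m@shollProfile)
    expect_equal(a@hullVolumeUm3, m@hullVolumeUm3, tolerance = 1e-9)
    expect_equal(a@hullAreaUm2, m@hullAreaUm2, tolerance = 1e-9)
  }
})

test_that("stored ground-truth metrics are recomputable from skeletons", {
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 16, voxelXYUm = 0.4,
                     nCells = 2, minSomaSeparationUm = 15, seed = 3)
  sim <- rasterizeScene(scene, replicate(2, morphologyPreset("ameboid"),
                                         simplify = FALSE))
  for (i in 1:2) {
    re <- analyticMetrics(sim$truth@graphs[[i]])
    expect_equal(re@totalLengthUm, sim$truth@metrics[[i]]@totalLengthUm,
                 tolerance = 1e-9)
    expect_identical(re@shollProfile, sim$truth@metrics[[i]]@shollProfile)
    expect_equal(re@hullVolumeUm3, sim$truth@metrics[[i]]@hullVolumeUm3,
                 tolerance = 1e-9)
  }
})

test_that("empty noise-free scenes are flat background", {
  scene <- SceneSpec(fieldXYUm = 20, nSlices = 8, voxelXYUm = 0.5,
                     nCells = 0, noiseGaussianSd = 0, noisePoissonScale = 0,
                     seed = 1)
  sim <- rasterizeScene(scene, list())
  bg <- round(0.02 * 65535)
  expect_true(all(getChannel(sim$stack, "iba1") == bg))
  expect_true(all(getChannel(sim$stack, "dapi") == bg))
})

test_that("rasterization is byte-identical under a fixed seed", {
  scene <- SceneSpec(fieldXYUm = 30, nSlices = 10, voxelXYUm = 0.5,
                     nCells = 1, nDebris = 5, seed = 9)
  s1 <- rasterizeScene(scene, list(morphologyPreset("ameboid")))
  s2 <- rasterizeScene(scene, list(morphologyPreset("ameboid")))
  expect_identical(s1$stack@channels, s2$stack@channels)
  expect_identical(s1$truth@debrisCenters, s2$truth@debrisCenters)
})

test_that("a single cell renders as one connected supra-half-max component", {
  sim <- unitCellScene(seed = 4)
  iba <- getChannel(sim$stack, "iba1")
  vs <- voxelSize(sim$stack)
  mask <- iba > max(iba) / 2
  labels <- MicrogliaMorph:::cpp_label26(as.vector(mask),
                                         as.integer(dim(iba)))
  dim(labels) <- dim(iba)
  somaVox <- MicrogliaMorph:::.voxelOf(c(31, 31, 10.4), dim(iba), vs)
  expect_gt(labels[somaVox], 0)
})

test_that("soma placement failure is reported with the achieved count", {
  scene <- SceneSpec(fieldXYUm = 25, nSlices = 10, voxelXYUm = 0.5,
                     nCells = 3, minSomaSeparationUm = 100, seed = 1)
  specs <- replicate(3, morphologyPreset("ameboid"), simplify = FALSE)
  expect_error(rasterizeScene(scene, specs), "placed 1 of 3")
})

test_that("above-background mass stays near the true capsule set", {
  scene <- SceneSpec(fieldXYUm = 40, nSlices = 16, voxelXYUm = 0.4,
                     nCells = 1, noiseGaussianSd = 0, noisePoissonScale = 0,
                     seed = 6)
  sim <- rasterizeScene(scene, list(morphologyPreset("ameboid")))
  iba <- getChannel(sim$stack, "iba1")
  vs <- voxelSize(sim$stack)
  bg <- round(0.02 * 65535)
  g <- sim$truth@graphs[[1]]
  spec <- morphologyPreset("ameboid")
  # capsule union dilated by 2 psf sigma, rasterized as a binary mask
  nd <- g@nodes; ed <- g@edges
  segs <- rbind(
    c(nd$x[1], nd$y[1], nd$z[1], nd$x[1], nd$y[1], nd$z[1],
      spec@somaRadiusUm + 1, spec@somaRadiusUm + 1, 1),
    t(vapply(seq_len(nrow(ed)), function(r) {
      a <- ed[r, 1]; b <- ed[r, 2]
      c(nd$x[a], nd$y[a], nd$z[a], nd$x[b], nd$y[b], nd$z[b],
        nd$radius[a] + 1, nd$radius[b] + 1, 1)
    }, numeric(9))))
  near <- MicrogliaMorph:::cpp_rasterize_capsules(
    as.integer(dim(iba)), as.numeric(vs), segs, 0, 0)
  dim(near) <- dim(iba)
  excess <- pmax(iba - bg, 0)
  expect_gte(sum(excess[near > 0.5]) / sum(excess), 0.99)
})
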