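# Debris surface detection, shape statistics and stacked selection.

test_that("blank or out-of-range thresholds yield empty results", {
  flat <- array(1, c(4, 10, 10))
  expect_equal(nrow(labelSurfaces(flat, 1, c(0.8, 0.5, 0.5))), 0)
  expect_warning(out <- labelSurfaces(flat, 5, c(0.8, 0.5, 0.5)),
                 "outside channel range")
  expect_equal(nrow(out), 0)
})

test_that("a rasterized sphere is one object with accurate volume and shape", {
  dims <- c(48, 48, 48); vs <- c(0.1, 0.1, 0.1)
  ball <- rasterizeBall(dims, vs, c(2.4, 2.4, 2.4), 2, 1)
  dim(ball) <- dims
  objs <- labelSurfaces(ball, 0.5, vs)
  expect_equal(nrow(objs), 1)
  expect_equal(objs$volume_um3, 4 / 3 * pi * 8, tolerance = 0.03)
  expect_gte(objs$sphericity, 0.97)
  expect_lte(objs$sphericity, 1.02)
  expect_lt(objs$ellipticity_oblate, 0.05)
  expect_lt(objs$ellipticity_prolate, 0.05)
})

test_that("separated spheres stay separate objects in deterministic order", {
  dims <- c(20, 60, 60); vs <- c(0.4, 0.2, 0.2)
  ch <- pmax(rasterizeBall(dims, vs, c(3, 3, 3), 1.2, 1),
             rasterizeBall(dims, vs, c(9, 9, 5), 1.2, 1))
  dim(ch) <- dims
  objs <- labelSurfaces(ch, 0.5, vs)
  expect_equal(nrow(objs), 2)
  # label 1 is the component whose first voxel comes first in (z,y,x) order
  expect_lt(objs$centroid_z[1], objs$centroid_z[2])
})

test_that("moment ellipticities recover analytic spheroids", {
  # oblate spheroid a = b = 3, c = 1 (c along z), 0.1 um voxels
  grid <- expand.grid(k = 1:30, j = 1:70, i = 1:70)
  x <- (grid$i - 0.5) * 0.1 - 3.5
  y <- (grid$j - 0.5) * 0.1 - 3.5
  z <- (grid$k - 0.5) * 0.1 - 1.5
  vox <- as.matrix(grid[(x / 3)^2 + (y / 3)^2 + z^2 <= 1, ])
  st <- shapeStats(vox, c(0.1, 0.1, 0.1))
  expect_equal(unname(st["ellipticity_oblate"]), 2 / 3, tolerance = 0.02)
  expect_lt(unname(st["ellipticity_prolate"]), 0.02)
  # single voxel: ellipticities 0 by convention
  st1 <- shapeStats(matrix(c(1L, 1L, 1L), 1), c(0.1, 0.1, 0.1))
  expect_equal(unname(st1["ellipticity_oblate"]), 0)
  expect_equal(unname(st1["ellipticity_prolate"]), 0)
})

test_that("selection is a conjunction of the supplied criteria", {
  objs <- data.frame(label = 1:4, volume_um3 = c(1, 5, 1, 1),
                     mean_intensity = c(0.9, 0.9, 0.5, 0.9),
                     sphericity = c(0.9, 0.9, 0.9, 0.4),
                     ellipticity_oblate = 0.1)
  all_c <- DebrisCriteria()
  expect_equal(selectDebris(objs, all_c), 1:4)  # vacuous conjunction
  expect_equal(selectDebris(objs, DebrisCriteria(maxVolumeUm3 = 2,
                                                 minIntensity = 0.8,
                                                 minSphericity = 0.8)), 1L)
  expect_length(selectDebris(objs, DebrisCriteria(maxVolumeUm3 = 0.1)), 0)
})

test_that("tightening any criterion never adds a label", {
  set.seed(31)
  objs <- data.frame(label = 1:40, volume_um3 = runif(40, 0, 10),
                     mean_intensity = runif(40), sphericity = runif(40),
                     ellipticity_oblate = runif(40))
  base <- DebrisCriteria(maxVolumeUm3 = 5, minIntensity = 0.3,
                         minSphericity = 0.3)
  s0 <- selectDebris(objs, base)
  for (tweak in list(DebrisCriteria(maxVolumeUm3 = 3, minIntensity = 0.3,
                                    minSphericity = 0.3),
                     DebrisCriteria(maxVolumeUm3 = 5, minIntensity = 0.6,
                                    minSphericity = 0.3),
                     DebrisCriteria(maxVolumeUm3 = 5, minIntensity = 0.3,
                                    minSphericity = 0.6,
                                    minOblateEllipticity = 0.5))) {
    expect_true(all(selectDebris(objs, tweak) %in% s0))
  }
})

test_that("exactly the planted debris are selected in a rendered scene", {
  scene <- SceneSpec(fieldXYUm = 60, nSlices = 20, voxelXYUm = 0.4,
                     nCells = 3, minSomaSeparationUm = 18, nDebris = 5,
                     noiseGaussianSd = 0, noisePoissonScale = 0, seed = 21)
  sim <- rasterizeScene(scene, replicate(3, morphologyPreset("ameboid"),
                                         simplify = FALSE))
  iba <- normalizeChannel(getChannel(sim$stack, "iba1"))
  vs <- voxelSize(sim$stack)
  objs <- labelSurfaces(iba, 0.9, vs)
  sel <- selectDebris(objs, DebrisCriteria(maxVolumeUm3 = 3,
                                           minIntensity = 0.95,
                                           minSphericity = 0.7,
                                           threshold = 0.9))
  expect_equal(length(sel), 5)
  dc <- sim$truth@debrisCenters
  hit <- vapply(sel, function(l) {
    r <- objs[objs$label == l, ]
    min(sqrt(rowSums((dc - matrix(c(r$centroid_x, r$centroid_y,
                                    r$centroid_z), nrow(dc), 3,
                                  byrow = TRUE))^2))) < 1
  }, TRUE)
  expect_true(all(hit))
})

test_that("masking selected debris reduces false seed points", {
  sim <- unitCellScene(seed = 5, noise = TRUE, nDebris = 30)
  iba <- getChannel(sim$stack, "iba1")
  dapi <- getChannel(sim$stack, "dapi")
  vs <- voxelSize(sim$stack)
  params <- unitCellParams()
  coloc <- colocalizationChannel(dapi, iba)
  starts <- filterByNucleus(detectStartingPoints(coloc, params, vs),
                            dapi, 0.3, vs)
  seedsRaw <- detectSeedPoints(iba, params, starts, vs)
  ib <- normalizeChannel(iba)
  objs <- labelSurfaces(ib, 0.9, vs)
  sel <- selectDebris(objs, DebrisCriteria(maxVolumeUm3 = 3,
                                           minIntensity = 0.95,
                                           minSphericity = 0.7,
                                           threshold = 0.9))
  lab <- attr(objs, "labels")
  lab[!(lab %in% sel)] <- 0L
  masked <- maskVoxels(iba, dilateMask(lab, c(2L, 3L, 3L)) * 1L, 0)
  seedsMasked <- detectSeedPoints(masked, params, starts, vs)
  expect_lt(nrow(seedsMasked), nrow(seedsRaw))
})
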