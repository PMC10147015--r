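# Stack IO and channel arithmetic.

test_that("write/read round trip is exact for integer stacks", {
  scene <- SceneSpec(fieldXYUm = 20, nSlices = 6, voxelXYUm = 0.5,
                     nCells = 1, seed = 2)
  sim <- rasterizeScene(scene, list(morphologyPreset("ameboid")))
  path <- tempfile(fileext = ".tif")
  writeStack(sim$stack, path)
  back <- readStack(path, channelNames(sim$stack))
  expect_identical(dim(back), dim(sim$stack))
  expect_equal(back@channels$iba1, sim$stack@channels$iba1)
  expect_equal(back@channels$dapi, sim$stack@channels$dapi)
  expect_equal(voxelSize(back), voxelSize(sim$stack))
  unlink(c(path, paste0(path, ".json")))
})

test_that("channel-count mismatch and missing files raise distinct errors", {
  expect_error(readStack(tempfile(), "iba1"), "not found")
  st <- ImageStack(list(only = array(0, c(2, 4, 4))), c(0.8, 0.5, 0.5))
  path <- tempfile(fileext = ".tif")
  writeStack(st, path)
  expect_error(readStack(path, c("a", "b")), "channel count mismatch")
  unlink(c(path, paste0(path, ".json")))
})

test_that("voxel size is never silently defaulted", {
  # a bare TIFF without sidecar metadata
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.25, 4, 4)), path,
                  bits.per.sample = 16L, compression = "none")
  expect_error(readStack(path, "ch"), "voxelSize")
  st <- readStack(path, "ch", voxelSize = c(0.8, 0.0705, 0.0705))
  expect_equal(voxelSize(st), c(0.8, 0.0705, 0.0705))
  unlink(path)
})

test_that("colocalization is the geometric mean of normalized channels", {
  a <- array(0, c(2, 3, 3)); b <- array(0, c(2, 3, 3))
  a[1, 1, 1] <- 4; b[1, 1, 1] <- 8           # both at their maxima -> 1
  a[2, 2, 2] <- 1; b[2, 2, 2] <- 8           # a = 0.25, b = 1 -> 0.5
  cl <- colocalizationChannel(a, b)
  expect_equal(cl[1, 1, 1], 1)
  expect_equal(cl[2, 2, 2], 0.5)
  expect_equal(cl[1, 3, 3], 0)               # annihilator where a = 0
  expect_error(colocalizationChannel(a, array(0, c(2, 3, 4))), "shape")
})

test_that("background subtraction flattens background, keeps small dots", {
  vs <- c(0.8, 0.25, 0.25)
  flat <- array(7, c(3, 40, 40))
  out <- subtractBackground(flat, 5, vs)
  expect_true(all(abs(out) < 1e-9))
  expect_true(all(out >= 0))

  dotted <- flat
  dotted[2, 20:21, 20:21] <- 27              # ~0.5 um bright dot, contrast 20
  out2 <- subtractBackground(dotted, 5, vs)
  expect_gt(max(out2[2, , ]), 20 * 0.95)
  expect_true(all(out2 >= 0))
  expect_error(subtractBackground(flat, -1, vs), "positive")
})

test_that("masking is exact and leaves the input untouched", {
  ch <- array(runif(60), c(3, 4, 5))
  mask <- array(0L, dim(ch))
  expect_identical(maskVoxels(ch, mask), ch)
  mask[] <- 1L
  expect_true(all(maskVoxels(ch, mask, 3) == 3))
  mask[] <- 0L; mask[2, 2, 2] <- 1L
  orig <- ch
  out <- maskVoxels(ch, mask, 0)
  expect_identical(ch, orig)
  expect_equal(sum(orig) - sum(out), orig[2, 2, 2])
  expect_error(maskVoxels(ch, array(0L, c(3, 4, 4))), "shape")
})

test_that("mask dilation grows by the requested voxel radius", {
  m <- array(0L, c(5, 9, 9)); m[3, 5, 5] <- 1L
  d <- dilateMask(m, c(1L, 2L, 2L))
  expect_true(d[2, 5, 5] && d[4, 5, 5])
  expect_true(d[3, 3, 5] && d[3, 7, 5])
  expect_false(d[1, 5, 5])
  expect_false(d[3, 2, 5])
  expect_equal(sum(d), 3 * 5 * 5)
})
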