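# Per-cell morphometry: length, volume, Sholl, hull, sphericity.

test_that("total length sums edge lengths in physical um", {
  g <- makeGraph(rbind(c(0, 0, 0), c(3, 4, 0)), c(1L, 2L))
  expect_equal(totalLength(g), 5)
  soma <- makeGraph(c(1, 2, 3), matrix(integer(0), ncol = 2))
  expect_equal(totalLength(soma), 0)
  chain <- makeGraph(cbind(0, 0, (0:5) * 0.8), cbind(1:5, 2:6))
  expect_equal(totalLength(chain), 4)
})

test_that("filament volume is frusta plus the soma body", {
  g <- makeGraph(rbind(c(0, 0, 0), c(0, 0, 1)), c(1L, 2L), radius = 1)
  g@somaVolumeUm3 <- 10
  expect_equal(filamentVolume(g), pi + 10)          # unit cylinder
  cone <- makeGraph(rbind(c(0, 0, 0), c(0, 0, 3)), c(1L, 2L),
                    radius = c(1, 0))
  cone@somaVolumeUm3 <- 0
  expect_equal(filamentVolume(cone), pi)            # cone r 1 -> 0, h 3
  degen <- makeGraph(rbind(c(0, 0, 0), c(0, 0, 2)), c(1L, 2L),
                     radius = c(0, 0))
  degen@somaVolumeUm3 <- 0
  expect_equal(filamentVolume(degen), 0)
  expect_error(filamentVolume({
    gna <- g; gna@nodes$radius[2] <- NA; gna
  }), "radii")
})

test_that("Sholl counts crossings with the half-open shell rule", {
  g <- straightProcessGraph(10)
  p <- shollProfile(g, 1)
  expect_equal(unname(p), rep(1, 10))
  expect_equal(as.numeric(names(p)), 1:10)
  expect_identical(shollProfile(g, 1, "projected2d"), p)

  # symmetric bifurcation: 1 trunk to 3.5 um, two daughters past 7 um
  # radial (7.2, float-safe: a daughter ending at machine-epsilon below a
  # shell would legitimately not cross it)
  bif <- makeGraph(rbind(c(0, 0, 0), c(3.5, 0, 0),
                         c(7.2 * cos(0.35), 7.2 * sin(0.35), 0),
                         c(7.2 * cos(-0.35), 7.2 * sin(-0.35), 0)),
                   rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)))
  pb <- shollProfile(bif, 1)
  expect_equal(unname(pb), c(1, 1, 1, 2, 2, 2, 2))
  expect_equal(sum(pb), 11)
  expect_error(shollProfile(g, 0), "resolutionUm")
})

test_that("planar cells give identical 2D and 3D Sholl modes", {
  set.seed(41)
  spec <- CellSpec(nPrimary = 4, branchProb = 0.5, maxOrder = 3)
  g <- sampleTree(spec, c(0, 0, 0))
  g@nodes$z <- 0
  expect_identical(shollProfile(g, 1, "sphere3d"),
                   shollProfile(g, 1, "projected2d"))
})

test_that("hulls of exact polyhedra are exact", {
  cube <- convexHull(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(cube$volume, 1, tolerance = 1e-12)
  expect_equal(cube$area, 6, tolerance = 1e-12)
  tetra <- convexHull(rbind(c(0, 0, 0), c(1, 0, 0),
                            c(0.5, sqrt(3) / 2, 0),
                            c(0.5, sqrt(3) / 6, sqrt(2 / 3))))
  expect_equal(tetra$volume, sqrt(2) / 12, tolerance = 1e-12)
  expect_equal(tetra$area, sqrt(3), tolerance = 1e-12)
  flat <- convexHull(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(0, 1, 0)))
  expect_true(flat$degenerate)
  expect_equal(flat$volume, 0)
  expect_equal(flat$area, 2, tolerance = 1e-12)
})

test_that("tips-only hull never exceeds the all-nodes hull", {
  set.seed(51)
  for (i in 1:5) {
    g <- sampleTree(morphologyPreset("surveillance"), c(0, 0, 0))
    a <- convexHullMetrics(g, "all_nodes")
    t <- convexHullMetrics(g, "tips_only")
    expect_lte(t$volume, a$volume + 1e-9)
  }
})

test_that("sphericity follows the closed form", {
  expect_equal(sphericity(pi / 6, pi), 1)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_equal(sphericity(0, 5), 0)
  expect_error(sphericity(1, 0), "area")
})

test_that("measureCell flags soma-only cells and composes all metrics", {
  soma <- makeGraph(c(0, 0, 0), matrix(integer(0), ncol = 2),
                    somaRadius = 3)
  m <- measureCell(soma)
  expect_equal(m@totalLengthUm, 0)
  expect_length(m@shollProfile, 0)
  expect_true(m@degenerateHull)
  set.seed(61)
  g <- sampleTree(morphologyPreset("transitional"), c(0, 0, 0))
  m2 <- measureCell(g)
  expect_false(m2@degenerateHull)
  expect_equal(m2@shollSum, sum(m2@shollProfile))
  expect_equal(m2@totalLengthUm, totalLength(g))
})

test_that("metrics respect similarity transforms", {
  set.seed(71)
  g <- sampleTree(morphologyPreset("transitional"), c(0, 0, 0))
  m <- measureCell(g)
  # rigid motion: translate + rotate about z
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  gr <- g
  xyz <- as.matrix(g@nodes[, c("x", "y", "z")]) %*% t(R)
  gr@nodes$x <- xyz[, 1] + 5; gr@nodes$y <- xyz[, 2] - 2
  gr@nodes$z <- xyz[, 3] + 1
  mr <- measureCell(gr)
  expect_equal(mr@totalLengthUm, m@totalLengthUm, tolerance = 1e-9)
  # hull invariance holds to the resolution of the soma-sphere sample,
  # whose polytope does not co-rotate with the cell
  expect_equal(mr@hullVolumeUm3, m@hullVolumeUm3, tolerance = 0.01)
  expect_equal(mr@sphericity, m@sphericity, tolerance = 0.01)
  expect_identical(mr@shollProfile, m@shollProfile)
  # uniform scaling x2 (radii included)
  gs <- g
  gs@nodes$x <- g@nodes$x * 2; gs@nodes$y <- g@nodes$y * 2
  gs@nodes$z <- g@nodes$z * 2; gs@nodes$radius <- g@nodes$radius * 2
  ms <- measureCell(gs)
  expect_equal(ms@totalLengthUm, 2 * m@totalLengthUm, tolerance = 1e-9)
  expect_equal(ms@hullVolumeUm3, 8 * m@hullVolumeUm3, tolerance = 1e-6)
  expect_equal(ms@sphericity, m@sphericity, tolerance = 1e-6)
})

test_that("Sholl profiles vanish beyond the cell's maximal extent", {
  set.seed(81)
  g <- sampleTree(morphologyPreset("ameboid"), c(0, 0, 0))
  p <- shollProfile(g, 1)
  center <- as.numeric(g@nodes[g@somaNode, c("x", "y", "z")])
  dmax <- max(sqrt(rowSums((as.matrix(g@nodes[, c("x", "y", "z")]) -
                              matrix(center, nNodes(g), 3,
                                     byrow = TRUE))^2)))
  expect_lte(max(as.numeric(names(p))), dmax)
  expect_true(all(p[length(p)] >= 1))
})
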