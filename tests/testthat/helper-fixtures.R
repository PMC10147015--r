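# Shared fixtures and independent oracles (test-local implementations that
# never call the code paths they check).

# hand-built filament graph from a node table
makeGraph <- function(xyz, edges, radius = 0.5, soma = 1L,
                      somaRadius = radius[1]) {
  xyz <- matrix(xyz, ncol = 3)
  r <- rep(radius, length.out = nrow(xyz))
  r[soma] <- somaRadius
  FilamentGraph(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           radius = r),
                matrix(as.integer(edges), ncol = 2), somaNode = soma)
}

# a straight radial process: soma at origin, nodes every `step` um along +x
straightProcessGraph <- function(lengthUm = 10, step = 1, radius = 0.5) {
  xs <- seq(0, lengthUm, by = step)
  n <- length(xs)
  makeGraph(cbind(xs, 0, 0), cbind(seq_len(n - 1), 2:n),
            radius = radius, somaRadius = radius)
}

# brute-force 3D convex hull by facet enumeration: every triple of points
# whose plane has all other points on one side is a facet; volume from
# signed tetrahedra against the centroid
bruteHull <- function(p) {
  n <- nrow(p)
  vol <- 0; area <- 0
  cen <- colMeans(p)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- p[i, ]; b <- p[j, ]; cc <- p[k, ]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sum(nrm^2) == 0) next
    s <- vapply(seq_len(n), function(m) sum(nrm * (p[m, ] - a)), 0)
    if (all(s <= 1e-12) || all(s >= -1e-12)) {
      area <- area + sqrt(sum(nrm^2)) / 2
      vol <- vol + abs(sum(nrm * (cen - a))) / 6
    }
  }
  list(volume = vol, area = area)
}

# independent Dunn z for one pair, straight from the rank-sum formula
dunnOracleZ <- function(groups, a, b) {
  allv <- unlist(groups)
  N <- length(allv)
  rk <- rank(allv)
  grp <- rep(names(groups), vapply(groups, length, 1L))
  Ra <- mean(rk[grp == a]); Rb <- mean(rk[grp == b])
  na <- sum(grp == a); nb <- sum(grp == b)
  ties <- table(allv)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (Ra - Rb) / sqrt(s2 * (1 / na + 1 / nb))
}

# a small default scene for reconstruction tests (single centered cell)
unitCellScene <- function(seed = 11, noise = FALSE, nDebris = 0,
                          preset = "transitional") {
  scene <- SceneSpec(fieldXYUm = 62, nSlices = 26, voxelXYUm = 0.25,
                     voxelZUm = 0.8, nCells = 1,
                     noiseGaussianSd = if (noise) 0.01 else 0,
                     noisePoissonScale = if (noise) 200 else 0,
                     nDebris = nDebris, seed = seed)
  rasterizeScene(scene, list(morphologyPreset(preset)),
                 centers = matrix(c(31, 31, 10.4), 1))
}

unitCellParams <- function() {
  TraceParams(startingDiameterUm = 10, seedDiameterUm = 1.2)
}
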