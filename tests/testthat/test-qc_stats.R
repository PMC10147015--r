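# Cell-inclusion QC and nonparametric statistics.

makeCellTable <- function(metricValues, metric = "total_length_um") {
  n <- length(metricValues)
  df <- data.frame(cell_id = sprintf("c%02d", seq_len(n)),
                   animal_id = "a1", group = "g", age = "P18",
                   total_length_um = 50, filament_volume_um3 = 100,
                   sholl_sum = 30, hull_volume_um3 = 500,
                   hull_area_um2 = 300, sphericity = 0.8,
                   nucleus_ok = TRUE, degenerate_hull = FALSE)
  df[[metric]] <- metricValues
  df
}

test_that("the interpolated 10th percentile excludes exactly the tail", {
  tab <- makeCellTable(1:20)
  out <- percentileFilter(tab)
  # P10 of 1..20 by linear interpolation of order statistics is 2.9
  expect_equal(unname(quantile(1:20, 0.1, type = 7)), 2.9)
  expect_equal(nrow(out), 18)
  expect_false(any(out$total_length_um %in% c(1, 2)))
})

test_that("constant metrics exclude nobody; bad nuclei exclude always", {
  tab <- makeCellTable(rep(5, 12))
  expect_equal(nrow(percentileFilter(tab)), 12)
  tab$nucleus_ok[3] <- FALSE
  tab$total_length_um <- 100 + seq_len(12)   # cell 3 is NOT in the tail
  out <- percentileFilter(tab)
  expect_false("c03" %in% out$cell_id)
  tab2 <- makeCellTable(rep(5, 12))
  tab2$degenerate_hull[1] <- TRUE
  expect_false("c01" %in% percentileFilter(tab2)$cell_id)
  expect_error(percentileFilter(makeCellTable(1:5), metrics = "nope"),
               "absent")
})

test_that("the union rule removes 10 to 40 percent on continuous data", {
  set.seed(91)
  for (rep in 1:5) {
    tab <- makeCellTable(runif(100))
    tab$sholl_sum <- runif(100)
    tab$sphericity <- runif(100)
    tab$hull_volume_um3 <- runif(100)
    kept <- nrow(percentileFilter(tab))
    expect_gte(100 - kept, 10)
    expect_lte(100 - kept, 40)
  }
  # perfectly rank-correlated metrics: exactly the shared tail goes
  v <- runif(100)
  tab <- makeCellTable(v)
  tab$sholl_sum <- v * 2
  tab$sphericity <- v + 1
  tab$hull_volume_um3 <- v^2
  expect_equal(nrow(percentileFilter(tab)), 90)
})

test_that("percentile scope pools treatment groups within a cohort", {
  tab <- rbind(makeCellTable(1:20), makeCellTable(101:120))
  tab$age <- rep(c("P10", "P18"), each = 20)
  tab$cell_id <- sprintf("c%02d", 1:40)
  out <- percentileFilter(tab, scope = "age")
  expect_equal(nrow(out), 36)            # 2 removed per cohort
  out2 <- percentileFilter(tab, scope = character(0))
  # pooled: cutoff ~ 4.9, only the low cohort loses cells
  expect_equal(nrow(out2), 36)
  expect_true(all(101:120 %in% out2$total_length_um))
})

test_that("per-animal summaries are means with cell counts", {
  tab <- makeCellTable(c(10, 20, 30))
  tab$animal_id <- c("a1", "a1", "a2")
  out <- perAnimalSummary(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$total_length_um[out$animal_id == "a1"], 15)
  expect_equal(out$n_cells, c(2, 1))
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)           # 2 / C(6,3) * 2-sided
  ident <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$statistic, 8)       # n^2 / 2
  expect_gte(ident$p_value, 0.99)
  a <- c(0.3, 1.7, 2.2, 5.1); b <- c(0.9, 3.3, 4.4)
  r1 <- mannWhitneyU(a, b); r2 <- mannWhitneyU(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r2$statistic, length(a) * length(b) - r1$statistic)
  expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis gives the textbook H and degenerates on ties", {
  r <- kruskalWallisTest(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  perm <- kruskalWallisTest(list(c(7, 8, 9), c(1, 2, 3), c(4, 5, 6)))
  expect_equal(perm$statistic, r$statistic)
  expect_error(kruskalWallisTest(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskalWallisTest(list(1:3)), "two groups")
})

test_that("two-group Kruskal-Wallis agrees with the normal-approx MW p", {
  # samples large enough that the continuity correction is negligible
  set.seed(101)
  x <- rnorm(25); y <- rnorm(25, 0.6)
  kw <- kruskalWallisTest(list(x, y))
  mw <- mannWhitneyU(x, y)
  expect_lt(abs(kw$p_value - mw$p_value), 0.01)
})

test_that("Dunn z agrees with a direct rank computation", {
  grp <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  out <- dunnPosthoc(grp, comparisons = list(c("g1", "g3")))
  expect_equal(out$statistic, dunnOracleZ(grp, "g1", "g3"),
               tolerance = 1e-12)
  same <- dunnPosthoc(list(a = 1:4, b = 1:4),
                      comparisons = list(c("a", "b")))
  expect_equal(same$statistic, 0)
  expect_equal(same$adjusted_p, 1)
  # Bonferroni multiplier is the planned comparison count, capped at 1
  set.seed(5)
  grps <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6), d = rnorm(6))
  cmp <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"))
  out4 <- dunnPosthoc(grps, cmp)
  expect_equal(out4$adjusted_p, pmin(1, 4 * out4$p_value))
  expect_error(dunnPosthoc(grps, list(c("a", "zz"))), "unknown group")
})

test_that("KS on pooled Sholl radii spans identical to disjoint support", {
  profA <- setNames(c(2, 3, 1), c("1", "2", "3"))
  profB <- setNames(c(1, 2), c("6", "7"))
  same <- ksSholl(list(profA), list(profA))
  expect_equal(same$statistic, 0)
  disj <- ksSholl(list(profA), list(profB))
  expect_equal(disj$statistic, 1)
  # worked pair: D equals the maximal ECDF gap computed by hand
  a <- rep(c(1, 2, 3), c(2, 3, 1))
  b <- rep(c(2, 3), c(1, 2))
  gaps <- vapply(sort(unique(c(a, b))), function(t)
    abs(mean(a <= t) - mean(b <= t)), 0)
  got <- ksSholl(list(profA), list(setNames(c(1, 2), c("2", "3"))))
  expect_equal(got$statistic, max(gaps), tolerance = 1e-12)
  expect_error(ksSholl(list(profA), list(setNames(numeric(0), character(0)))),
               "zero total")
})

test_that("group Sholl curves average profiles with SEM conventions", {
  m <- new("CellMetrics", cellId = "c1", animalId = "a", group = "g",
           age = "p", totalLengthUm = 1, filamentVolumeUm3 = 1,
           shollProfile = setNames(c(1, 2), c("1", "2")), shollSum = 3,
           hullVolumeUm3 = 1, hullAreaUm2 = 1, sphericity = 0.5,
           nucleusOk = TRUE, degenerateHull = FALSE)
  one <- shollGroupCurve(list(m))
  expect_equal(one$mean, c(1, 2))
  expect_equal(one$sem, c(0, 0))
  two <- shollGroupCurve(list(m, m))
  expect_equal(two$mean, c(1, 2))
  expect_equal(two$sem, c(0, 0))
})

test_that("rank tests are invariant to strictly increasing transforms", {
  set.seed(111)
  x <- runif(8); y <- runif(8) + 0.3; z <- runif(8)
  f <- function(v) exp(3 * v) + 1
  expect_equal(mannWhitneyU(x, y)$p_value,
               mannWhitneyU(f(x), f(y))$p_value)
  expect_equal(kruskalWallisTest(list(x, y, z))$statistic,
               kruskalWallisTest(list(f(x), f(y), f(z)))$statistic,
               tolerance = 1e-9)
})
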