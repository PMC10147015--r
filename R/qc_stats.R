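# Cell-inclusion QC and nonparametric group statistics.
#
# The inclusion rule mirrors the study design: only cells with a nucleus
# fully inside the z-stack enter, and cells below the 10th percentile on any
# of filament length, Sholl sum, sphericity or hull volume are excluded,
# guarding against cells partially clipped at the stack border. Group
# statistics are nonparametric throughout: Mann-Whitney U for two groups,
# Kruskal-Wallis with a Dunn-Bonferroni post hoc for more, and a
# Kolmogorov-Smirnov test on pooled Sholl intersection radii.

.comparisonRow <- function(test, statistic, df = NA_real_, p = NA_real_,
                           adjusted = NA_real_, comparison = NA_character_) {
  data.frame(test = test, statistic = statistic, df = df, p_value = p,
             adjusted_p = adjusted, comparison = comparison,
             stringsAsFactors = FALSE)
}

#' Percentile-based cell inclusion filter
#'
#' Rows without a nucleus in the stack (\code{nucleus_ok == FALSE}) and
#' degenerate-hull cells are always excluded. For each remaining metric the
#' q-th percentile is computed by linear interpolation of order statistics
#' (\code{quantile type 7}) over the stated scope (default: each
#' model-by-age cohort pooled across treatment groups, so groups share one
#' cutoff); a cell is excluded iff it lies strictly below the percentile on
#' ANY listed metric.
#'
#' @param table per-cell data.frame (see \code{\link{cellTable}}).
#' @param metrics column names entering the union rule.
#' @param q percentile (default 0.10).
#' @param scope character vector of grouping columns defining cohorts;
#'   \code{NULL} uses \code{intersect(c("model", "age"), names(table))}
#'   (the whole table when neither column exists).
#' @return the filtered table.
#' @export
percentileFilter <- function(table,
                             metrics = c("total_length_um", "sholl_sum",
                                         "sphericity", "hull_volume_um3"),
                             q = 0.10, scope = NULL) {
  if (nrow(table) == 0) return(table)
  missing <- setdiff(metrics, names(table))
  if (length(missing) > 0)
    stop("metrics absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if ("nucleus_ok" %in% names(table)) table <- table[table$nucleus_ok, , drop = FALSE]
  if ("degenerate_hull" %in% names(table))
    table <- table[!table$degenerate_hull, , drop = FALSE]
  if (nrow(table) == 0) return(table)
  if (is.null(scope)) scope <- intersect(c("model", "age"), names(table))
  groups <- if (length(scope) > 0)
    interaction(table[scope], drop = TRUE) else factor(rep(1, nrow(table)))
  keep <- logical(nrow(table))
  for (g in levels(groups)) {
    sel <- which(groups == g)
    cuts <- vapply(metrics, function(m)
      quantile(table[[m]][sel], q, type = 7, names = FALSE), 0)
    below <- Reduce(`|`, lapply(seq_along(metrics), function(i)
      table[[metrics[i]]][sel] < cuts[i]))
    keep[sel] <- !below
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-animal summary of cell metrics
#'
#' Mean of each numeric metric per animal, plus the Iba1-positive cell
#' count per animal (cells per imaged field when each animal contributes
#' one field).
#'
#' @param table per-cell data.frame with an \code{animal_id} column.
#' @return data.frame, one row per animal.
#' @export
perAnimalSummary <- function(table) {
  if (!"animal_id" %in% names(table)) stop("animal_id column required")
  nums <- names(table)[vapply(table, is.numeric, TRUE)]
  split_idx <- split(seq_len(nrow(table)), table$animal_id)
  rows <- lapply(names(split_idx), function(a) {
    sel <- split_idx[[a]]
    row <- data.frame(animal_id = a, n_cells = length(sel),
                      stringsAsFactors = FALSE)
    for (lbl in intersect(c("group", "age", "model"), names(table)))
      row[[lbl]] <- table[[lbl]][sel[1]]
    for (m in nums) row[[m]] <- mean(table[[m]][sel])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test for two groups
#'
#' Exact two-sided p by enumeration when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections (both via \code{stats::wilcox.test},
#' whose W statistic is the U of the first sample).
#'
#' @param x,y numeric samples.
#' @return one-row data.frame: test, statistic (U), df (NA), p_value.
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  .comparisonRow("mann_whitney_u", unname(wt$statistic), NA_real_,
                 wt$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with k - 1 degrees of freedom and a chi-square upper
#' tail p (via \code{stats::kruskal.test}). Rejects degenerate input where
#' every observation is identical.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return one-row data.frame: test, statistic (H), df, p_value.
#' @export
kruskalWallisTest <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group", call. = FALSE)
  allv <- unlist(groups)
  if (length(unique(allv)) == 1)
    stop("all observations identical; tie correction degenerates",
         call. = FALSE)
  kt <- kruskal.test(groups)
  .comparisonRow("kruskal_wallis", unname(kt$statistic),
                 unname(kt$parameter), kt$p.value)
}

#' Dunn's post hoc test with Bonferroni correction for planned comparisons
#'
#' For each requested pair (i, j), the Dunn z statistic
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N - 1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' uses mean pooled ranks and the pooled tie-corrected rank variance. The
#' Bonferroni multiplier is the number of requested (planned) comparisons,
#' not the full pairwise count; adjusted p = min(1, m * p).
#'
#' @param groups named list of numeric vectors.
#' @param comparisons list of length-2 character vectors of group names;
#'   \code{NULL} requests all pairs.
#' @param method only \code{"bonferroni"}.
#' @return data.frame with one row per comparison: z, p, adjusted p.
#' @export
dunnPosthoc <- function(groups, comparisons = NULL, method = "bonferroni") {
  method <- match.arg(method, "bonferroni")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named", call. = FALSE)
  if (is.null(comparisons)) {
    nms <- names(groups)
    comparisons <- list()
    for (i in seq_along(nms)) for (j in seq_along(nms))
      if (i < j) comparisons[[length(comparisons) + 1]] <- c(nms[i], nms[j])
  }
  for (cp in comparisons)
    if (!all(cp %in% names(groups)))
      stop("unknown group label in comparison: ",
           paste(cp, collapse = " vs "), call. = FALSE)
  allv <- unlist(groups)
  N <- length(allv)
  rk <- rank(allv)
  grp <- rep(names(groups), vapply(groups, length, 1L))
  meanRank <- tapply(rk, grp, mean)
  nPer <- tapply(rk, grp, length)
  tieTab <- table(allv)
  tieSum <- sum(tieTab^3 - tieTab)
  varTerm <- N * (N + 1) / 12 - tieSum / (12 * (N - 1))
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    a <- cp[1]; b <- cp[2]
    se <- sqrt(varTerm * (1 / nPer[[a]] + 1 / nPer[[b]]))
    z <- if (se > 0) (meanRank[[a]] - meanRank[[b]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    .comparisonRow("dunn", z, NA_real_, p, min(1, m * p),
                   paste(a, "vs", b))
  })
  do.call(rbind, rows)
}

#' Kolmogorov-Smirnov test on pooled Sholl intersection radii
#'
#' Each cell's Sholl profile is expanded into a multiset of radii (each
#' radius repeated by its intersection count), the multisets are pooled
#' within each group, and the two pooled radius samples are compared with
#' the asymptotic two-sample KS test. D = 0 for identical pooled profiles,
#' 1 for disjoint radial supports.
#'
#' @param cellsA,cellsB lists of \code{\link{CellMetrics}} (or named numeric
#'   Sholl profiles).
#' @return one-row data.frame: test, statistic (D), p_value.
#' @export
ksSholl <- function(cellsA, cellsB) {
  expand <- function(cells) {
    if (is(cells, "CellMetrics")) cells <- list(cells)
    unlist(lapply(cells, function(cm) {
      prof <- if (is(cm, "CellMetrics")) cm@shollProfile else cm
      if (length(prof) == 0) return(numeric(0))
      rep(as.numeric(names(prof)), as.integer(prof))
    }))
  }
  a <- expand(cellsA); b <- expand(cellsB)
  if (length(a) == 0 || length(b) == 0)
    stop("a group has zero total Sholl intersections", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  .comparisonRow("ks_sholl", unname(kt$statistic), NA_real_, kt$p.value)
}

#' Group-mean Sholl curve
#'
#' Per-radius mean and SEM over cells, treating radii absent from a cell's
#' profile as zero intersections; a single cell yields SEM 0 by convention.
#'
#' @param cells list of \code{\link{CellMetrics}}.
#' @return data.frame: radius_um, mean, sem, n.
#' @export
shollGroupCurve <- function(cells) {
  if (is(cells, "CellMetrics")) cells <- list(cells)
  radii <- sort(unique(unlist(lapply(cells, function(cm)
    as.numeric(names(cm@shollProfile))))))
  if (length(radii) == 0)
    return(data.frame(radius_um = numeric(0), mean = numeric(0),
                      sem = numeric(0), n = integer(0)))
  mat <- vapply(cells, function(cm) {
    prof <- cm@shollProfile
    v <- setNames(numeric(length(radii)), radii)
    if (length(prof) > 0) v[names(prof)] <- prof
    v
  }, numeric(length(radii)))
  mat <- matrix(mat, nrow = length(radii))
  n <- length(cells)
  mu <- rowMeans(mat)
  sem <- if (n > 1) apply(mat, 1, sd) / sqrt(n) else rep(0, length(radii))
  data.frame(radius_um = radii, mean = mu, sem = sem, n = n)
}
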