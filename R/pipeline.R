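# End-to-end pipeline orchestration: simulate or read stacks, clean, trace,
# measure, QC-filter and test, persisting every intermediate artifact so any
# stage can be re-run from disk. All randomness flows from the single
# config seed (per-scene seeds are derived as seed + scene index), making
# runs bit-reproducible.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable stated once;
#' fields supplied in \code{overrides} replace defaults recursively.
#'
#' @param overrides named list (possibly nested) of overrides.
#' @return configuration list.
#' @export
defaultConfig <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    output_dir = "mgmorph_out",
    channels = list(iba1 = "iba1", dapi = "dapi"),
    simulate = list(
      enabled = TRUE,
      scene = list(field_xy_um = 60, n_slices = 26, voxel_xy_um = 0.3,
                   voxel_z_um = 0.8, min_soma_separation_um = 20,
                   psf_sigma_um = c(0.5, 0.15, 0.15),
                   noise_gaussian_sd = 0.01, noise_poisson_scale = 200,
                   n_debris = 0, debris_radius_um = 0.5,
                   debris_intensity = 2.5),
      groups = list(
        list(name = "ameboid", preset = "ameboid", n_animals = 3,
             fields_per_animal = 4, cells_per_field = 4),
        list(name = "surveillance", preset = "surveillance", n_animals = 3,
             fields_per_animal = 4, cells_per_field = 4)),
      age = "P18"),
    inputs = list(),
    background = list(enabled = FALSE, radius_um = 5),
    debris = list(enabled = FALSE, threshold = 0.9, max_volume_um3 = 3,
                  min_intensity = 0.95, min_sphericity = 0.7,
                  detail_um = 0.2, dilate_vox = c(2L, 3L, 3L)),
    trace = list(starting_diameter_um = 10, seed_diameter_um = 1.2,
                 start_threshold = 0.05, seed_threshold = 0.04,
                 remove_seed_radius_factor = 1.0, max_gap_um = 4,
                 intensity_floor = 0.12, cost_exponent = 2,
                 prune_spur_um = 1.5),
    nucleus_threshold = 0.3,
    soma_import_threshold = 0.35,
    sholl = list(resolution_um = 1.0, mode = "sphere3d"),
    hull = list(points_mode = "all_nodes"),
    qc = list(q = 0.10,
              metrics = c("total_length_um", "sholl_sum", "sphericity",
                          "hull_volume_um3"),
              scope = c("age")),
    comparisons = NULL)
  .mergeConfig(cfg, overrides)
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

.tracePar <- function(tc) {
  TraceParams(startingDiameterUm = tc$starting_diameter_um,
              seedDiameterUm = tc$seed_diameter_um,
              startThreshold = tc$start_threshold,
              seedThreshold = tc$seed_threshold,
              removeSeedRadiusFactor = tc$remove_seed_radius_factor,
              maxGapUm = tc$max_gap_um,
              intensityFloor = tc$intensity_floor,
              costExponent = tc$cost_exponent,
              pruneSpurUm = tc$prune_spur_um)
}

#' Process one two-channel stack into per-cell metrics
#'
#' The per-stack stage chain: optional background subtraction, optional
#' debris masking, colocalization channel, starting-point detection,
#' nucleus QC, seed detection, tracing, disconnected-segment pruning,
#' diameter fitting, soma import, and morphometry.
#'
#' @param stack an \code{\link{ImageStack}} with iba1 and dapi channels.
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param labels named list: animal_id, group, age attached to each cell.
#' @param log function accepting a message string.
#' @return list: \code{metrics} (list of \code{CellMetrics}),
#'   \code{graphs}, \code{counts} (per-stage tallies), \code{iba1} (the
#'   cleaned working channel).
#' @export
processStack <- function(stack, config = defaultConfig(), labels = list(),
                         log = message) {
  vs <- voxelSize(stack)
  iba <- getChannel(stack, config$channels$iba1)
  dapi <- getChannel(stack, config$channels$dapi)
  counts <- list()

  if (isTRUE(config$background$enabled)) {
    iba <- subtractBackground(iba, config$background$radius_um, vs)
    log(sprintf("background subtracted (radius %g um)",
                config$background$radius_um))
  }
  if (isTRUE(config$debris$enabled)) {
    dc <- config$debris
    ib <- .normalize01(iba); dim(ib) <- dim(iba)
    objs <- labelSurfaces(ib, dc$threshold, vs, dc$detail_um)
    crit <- DebrisCriteria(maxVolumeUm3 = dc$max_volume_um3,
                           minIntensity = dc$min_intensity,
                           minSphericity = dc$min_sphericity,
                           threshold = dc$threshold, detailUm = dc$detail_um)
    sel <- selectDebris(objs, crit)
    labArr <- attr(objs, "labels")
    labArr[!(labArr %in% sel)] <- 0L
    # grow the selected surfaces over their PSF halo before masking
    labArr <- dilateMask(labArr, dc$dilate_vox %||% c(2L, 3L, 3L)) * 1L
    iba <- maskVoxels(iba, labArr, 0)
    counts$debris_masked <- length(sel)
    log(sprintf("debris masking: %d of %d surfaces masked", length(sel),
                nrow(objs)))
  }

  params <- .tracePar(config$trace)
  coloc <- colocalizationChannel(dapi, iba)
  starts <- detectStartingPoints(coloc, params, vs)
  counts$starting_points <- nrow(starts)
  startsOk <- filterByNucleus(starts, dapi, config$nucleus_threshold, vs)
  counts$nucleus_pass <- nrow(startsOk)
  log(sprintf("starting points: %d detected, %d with nucleus in stack",
              nrow(starts), nrow(startsOk)))
  if (nrow(startsOk) == 0)
    return(list(metrics = list(), graphs = list(), counts = counts,
                iba1 = iba))

  seeds <- detectSeedPoints(iba, params, startsOk, vs)
  counts$seed_points <- nrow(seeds)
  graphs <- traceFilaments(iba, startsOk, seeds, params, vs)
  graphs <- lapply(graphs, removeDisconnectedSegments, iba1 = iba,
                   voxelSize = vs)
  graphs <- lapply(graphs, fitDiameters, iba1 = iba, voxelSize = vs)
  graphs <- importSomas(graphs, coloc, config$soma_import_threshold, vs)
  counts$cells_traced <- length(graphs)
  log(sprintf("traced %d cell(s) from %d seeds", length(graphs),
              nrow(seeds)))

  for (i in seq_along(graphs)) {
    graphs[[i]]@animalId <- as.character(labels$animal_id %||% NA)
    graphs[[i]]@group <- as.character(labels$group %||% NA)
    graphs[[i]]@age <- as.character(labels$age %||% NA)
    if (!is.null(labels$prefix))
      graphs[[i]]@cellId <- paste0(labels$prefix, "_", graphs[[i]]@cellId)
  }
  metrics <- lapply(graphs, measureCell,
                    shollResolutionUm = config$sholl$resolution_um,
                    shollMode = config$sholl$mode,
                    hullPointsMode = config$hull$points_mode)
  list(metrics = metrics, graphs = graphs, counts = counts, iba1 = iba)
}

#' Run the full pipeline
#'
#' Simulates (or reads) every stack, processes each through
#' \code{\link{processStack}}, pools the per-cell table, applies the
#' percentile QC filter, summarizes per animal, and runs the group
#' statistics: per-metric Mann-Whitney (two groups) or Kruskal-Wallis plus
#' Dunn-Bonferroni (more), and the KS test on pooled Sholl radii. Every
#' artifact is persisted under \code{config$output_dir}: scene TIFFs, SWC
#' skeletons, tidy CSV tables, a JSON statistics report, the effective
#' config, and a log with per-stage counts.
#'
#' @param config configuration list or path to a YAML file
#'   (see \code{\link{defaultConfig}}).
#' @return (invisibly) list with the output directory, tables and stats.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- defaultConfig(yaml::read_yaml(config))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "swc"), showWarnings = FALSE)
  logFile <- file.path(out, "log.txt")
  cat("", file = logFile)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    cat(line, "\n", file = logFile, append = TRUE)
    message(line)
  }
  yaml::write_yaml(config, file.path(out, "config_effective.yaml"))

  stacks <- list()   # list of list(stack, labels, name)
  if (isTRUE(config$simulate$enabled)) {
    sc <- config$simulate$scene
    sceneIdx <- 0
    for (grp in config$simulate$groups) {
      spec <- morphologyPreset(grp$preset)
      for (a in seq_len(grp$n_animals)) {
        animal <- sprintf("%s_a%d", grp$name, a)
        for (f in seq_len(grp$fields_per_animal)) {
          sceneIdx <- sceneIdx + 1
          scene <- SceneSpec(fieldXYUm = sc$field_xy_um,
                             nSlices = sc$n_slices,
                             voxelXYUm = sc$voxel_xy_um,
                             voxelZUm = sc$voxel_z_um,
                             nCells = grp$cells_per_field,
                             minSomaSeparationUm = sc$min_soma_separation_um,
                             psfSigmaUm = unlist(sc$psf_sigma_um),
                             noiseGaussianSd = sc$noise_gaussian_sd,
                             noisePoissonScale = sc$noise_poisson_scale,
                             nDebris = sc$n_debris,
                             debrisRadiusUm = sc$debris_radius_um,
                             debrisIntensity = sc$debris_intensity,
                             seed = config$seed + sceneIdx)
          sim <- rasterizeScene(scene,
                                replicate(grp$cells_per_field, spec,
                                          simplify = FALSE))
          name <- sprintf("%s_f%d", animal, f)
          writeStack(sim$stack, file.path(out, paste0(name, ".tif")))
          stacks[[length(stacks) + 1]] <-
            list(stack = sim$stack,
                 labels = list(animal_id = animal, group = grp$name,
                               age = config$simulate$age, prefix = name),
                 name = name)
          log(sprintf("simulated %s (%d cells)", name, grp$cells_per_field))
        }
      }
    }
  } else {
    for (inp in config$inputs) {
      st <- readStack(inp$path, unlist(config$channels),
                      voxelSize = inp$voxel_size_um %||% NULL)
      nm <- sub("\\.[^.]+$", "", basename(inp$path))
      stacks[[length(stacks) + 1]] <-
        list(stack = st, labels = list(animal_id = inp$animal_id,
                                       group = inp$group, age = inp$age,
                                       prefix = nm), name = nm)
      log(sprintf("read %s", inp$path))
    }
  }
  if (length(stacks) == 0) stop("no input stacks", call. = FALSE)

  allMetrics <- list(); allGraphs <- list()
  for (item in stacks) {
    res <- tryCatch(
      processStack(item$stack, config, item$labels, log = log),
      error = function(e) stop(sprintf("stage failure in stack '%s': %s",
                                       item$name, conditionMessage(e)),
                               call. = FALSE))
    for (g in res$graphs)
      writeSWC(g, file.path(out, "swc", paste0(g@cellId, ".swc")))
    allMetrics <- c(allMetrics, res$metrics)
    allGraphs <- c(allGraphs, res$graphs)
  }
  if (length(allMetrics) == 0) stop("no cells traced", call. = FALSE)

  cells <- cellTable(allMetrics)
  write.csv(cells, file.path(out, "cells_raw.csv"), row.names = FALSE)
  shollLong <- shollLongTable(allMetrics)
  write.csv(shollLong, file.path(out, "sholl_long.csv"), row.names = FALSE)

  qcScope <- intersect(unlist(config$qc$scope), names(cells))
  filtered <- percentileFilter(cells, metrics = unlist(config$qc$metrics),
                               q = config$qc$q, scope = qcScope)
  log(sprintf("QC: %d of %d cells retained", nrow(filtered), nrow(cells)))
  if (nrow(filtered) == 0)
    stop("no cells after QC; nothing to analyze", call. = FALSE)
  write.csv(filtered, file.path(out, "cells_filtered.csv"), row.names = FALSE)

  perAnimal <- perAnimalSummary(filtered)
  write.csv(perAnimal, file.path(out, "per_animal.csv"), row.names = FALSE)

  keptIds <- filtered$cell_id
  keptMetrics <- Filter(function(m) m@cellId %in% keptIds, allMetrics)
  grpOf <- vapply(keptMetrics, function(m) m@group, "")
  groupsPresent <- sort(unique(grpOf))

  statRows <- list()
  metricCols <- c("total_length_um", "sholl_sum", "sphericity",
                  "hull_volume_um3")
  if (length(groupsPresent) >= 2) {
    for (mcol in metricCols) {
      vals <- split(filtered[[mcol]], filtered$group)
      if (length(groupsPresent) == 2) {
        row <- mannWhitneyU(vals[[groupsPresent[1]]],
                            vals[[groupsPresent[2]]])
        row$comparison <- paste(groupsPresent, collapse = " vs ")
      } else {
        row <- kruskalWallisTest(vals)
        dunn <- dunnPosthoc(vals, config$comparisons)
        dunn$metric <- mcol
        statRows[[length(statRows) + 1]] <- dunn
      }
      row$metric <- mcol
      statRows[[length(statRows) + 1]] <- row
    }
    if (length(groupsPresent) == 2) {
      ks <- ksSholl(keptMetrics[grpOf == groupsPresent[1]],
                    keptMetrics[grpOf == groupsPresent[2]])
      ks$comparison <- paste(groupsPresent, collapse = " vs ")
      ks$metric <- "sholl_distribution"
      statRows[[length(statRows) + 1]] <- ks
    }
  }
  stats <- if (length(statRows)) do.call(rbind, statRows) else
    .comparisonRow(character(0), numeric(0))[0, ]
  write.csv(stats, file.path(out, "stats.csv"), row.names = FALSE)
  jsonlite::write_json(stats, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  curves <- lapply(groupsPresent, function(g) {
    cv <- shollGroupCurve(keptMetrics[grpOf == g])
    if (nrow(cv) > 0) cv$group <- g
    cv
  })
  curves <- do.call(rbind, Filter(function(x) nrow(x) > 0, curves))
  if (!is.null(curves))
    write.csv(curves, file.path(out, "sholl_curves.csv"), row.names = FALSE)

  log("pipeline complete")
  invisible(list(output_dir = out, cells = cells, filtered = filtered,
                 per_animal = perAnimal, stats = stats,
                 metrics = keptMetrics))
}
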