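# SWC skeleton interchange: one file per cell, coordinates and radii in um,
# type code 1 for the soma node and 3 for process nodes, parent -1 at the
# root. Cell labels travel in a JSON sidecar when written by the pipeline.

#' Write a filament graph as SWC
#'
#' @param graph a \code{\link{FilamentGraph}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSWC <- function(graph, path) {
  validObject(graph)
  dirE <- .orientEdges(graph)
  n <- nrow(graph@nodes)
  parent <- rep(-1L, n)
  if (nrow(dirE) > 0) parent[dirE[, 2]] <- dirE[, 1]
  type <- rep(3L, n)
  type[graph@somaNode] <- 1L
  df <- data.frame(id = seq_len(n), type = type,
                   x = graph@nodes$x, y = graph@nodes$y, z = graph@nodes$z,
                   radius = graph@nodes$radius, parent = parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC skeleton for cell '%s' (um)", graph@cellId), con)
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d", df$id, df$type, df$x,
                     df$y, df$z, df$radius, df$parent), con)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' @param path SWC file.
#' @param cellId label for the graph (defaults to the file stem).
#' @return a \code{\link{FilamentGraph}}.
#' @export
readSWC <- function(path, cellId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (!identical(as.integer(m[, 1]), seq_len(nrow(m))))
    stop("SWC ids must be 1..n", call. = FALSE)
  soma <- which(m[, 2] == 1)
  if (length(soma) != 1) stop("SWC must contain exactly one soma node (type 1)")
  nodes <- data.frame(x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6])
  edges <- cbind(m[m[, 7] > 0, 7], m[m[, 7] > 0, 1])
  FilamentGraph(nodes, edges, somaNode = as.integer(soma),
                cellId = cellId %||% sub("\\.swc$", "", basename(path)))
}
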