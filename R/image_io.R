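# Stack IO and channel arithmetic.
#
# Stacks are written as plain multi-page 16-bit TIFF (pages z-major with
# channels interleaved within each slice: z1/c1, z1/c2, z2/c1, ...) plus a
# JSON sidecar `<file>.json` carrying channel names, voxel sizes (z, y, x in
# um) and bit depth. On read the sidecar is honoured; a bare TIFF without
# sidecar requires an explicit voxel-size override - physical calibration is
# never silently defaulted.

#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param path output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  validObject(stack)
  d <- dim(stack)
  full <- 2^stack@bitDepth - 1
  pages <- list()
  for (k in seq_len(d[1]))
    for (ch in stack@channels)
      pages[[length(pages) + 1]] <- matrix(ch[k, , ] / full, d[2], d[3])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = channelNames(stack),
               voxel_size_um = as.numeric(stack@voxelSize),
               bit_depth = stack@bitDepth,
               page_order = "z-major, channels interleaved",
               provenance = stack@provenance)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel z-stack from TIFF
#'
#' @param path TIFF path.
#' @param channelNames names to assign to the channels, in page-interleave
#'   order. When a sidecar is present its channel count must be at least
#'   \code{length(channelNames)}.
#' @param voxelSize optional (z, y, x) voxel size override in um. Mandatory
#'   when neither the sidecar nor the TIFF carries physical calibration.
#' @return an \code{\link{ImageStack}}.
#' @export
readStack <- function(path, channelNames, voxelSize = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channelNames)

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  bitDepth <- 16
  if (!is.null(meta)) {
    metaCh <- unlist(meta$channels)
    if (length(metaCh) < nc)
      stop(sprintf("channel count mismatch: file has %d channel(s), %d requested",
                   length(metaCh), nc), call. = FALSE)
    ncFile <- length(metaCh)
    bitDepth <- meta$bit_depth %||% 16
    if (is.null(voxelSize)) voxelSize <- unlist(meta$voxel_size_um)
  } else {
    ncFile <- nc
    if (length(pages) %% nc != 0)
      stop(sprintf("channel count mismatch: %d pages do not divide into %d channel(s)",
                   length(pages), nc), call. = FALSE)
  }
  if (is.null(voxelSize))
    stop("no voxel size in metadata; pass voxelSize = c(z, y, x) in um explicitly",
         call. = FALSE)
  voxelSize <- as.numeric(voxelSize)
  if (length(voxelSize) != 3 || any(voxelSize <= 0))
    stop("voxelSize must be three positive values (z, y, x) in um", call. = FALSE)

  nz <- length(pages) %/% ncFile
  d2 <- dim(pages[[1]])
  full <- 2^bitDepth - 1
  channels <- setNames(vector("list", nc), channelNames)
  for (c in seq_len(nc)) {
    arr <- array(0, c(nz, d2[1], d2[2]))
    for (k in seq_len(nz))
      arr[k, , ] <- round(pages[[(k - 1) * ncFile + c]] * full)
    channels[[c]] <- arr
  }
  ImageStack(channels, voxelSize = voxelSize, bitDepth = bitDepth,
             provenance = path)
}

#' Build a soma colocalization channel from nuclear and membrane channels
#'
#' The voxelwise geometric mean of the min-max normalized inputs: high only
#' where both signals are high, which is exactly the soma body (the nuclear
#' stain fills the dim center that the membrane marker leaves hollow,
#' yielding confluent intensity throughout the soma). Zero anywhere either
#' input is zero; 1 where both inputs reach their maxima.
#'
#' @param a,b 3D channels of identical shape.
#' @return a channel in [0, 1].
#' @export
colocalizationChannel <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("channel shapes differ", call. = FALSE)
  out <- sqrt(.normalize01(a) * .normalize01(b))
  dim(out) <- dim(a)
  out
}

#' Subtract slowly-varying background from a channel
#'
#' Per-slice morphological opening (the rolling-ball equivalent) with a disc
#' of the given physical radius is subtracted from each z slice and the
#' result clipped at zero: flat background maps to ~0 while structures
#' smaller than the disc are preserved. Opening is done in 2D because the
#' coarse axial pitch of optical sectioning makes a 3D structuring-element
#' radius ill-posed.
#'
#' @param ch 3D channel array.
#' @param radiusUm disc radius in um (should exceed the largest structure of
#'   interest).
#' @param voxelSize (z, y, x) voxel size in um.
#' @return background-subtracted channel, same shape, nonnegative.
#' @export
subtractBackground <- function(ch, radiusUm, voxelSize) {
  if (!is.numeric(radiusUm) || radiusUm <= 0)
    stop("radiusUm must be positive", call. = FALSE)
  rpx <- max(1L, round(radiusUm / voxelSize[3]))
  size <- 2L * rpx + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  d <- dim(ch)
  out <- ch
  scale <- max(ch)
  if (scale <= 0) scale <- 1
  for (k in seq_len(d[1])) {
    sl <- ch[k, , ]
    # replicate-pad by the brush radius so the opening has no border bias;
    # scale into [0, 1] because greyscale morphology clips at 1
    pj <- c(rep(1L, rpx), seq_len(d[2]), rep(d[2], rpx))
    pi_ <- c(rep(1L, rpx), seq_len(d[3]), rep(d[3], rpx))
    padded <- sl[pj, pi_] / scale
    op <- EBImage::opening(padded, brush) * scale
    core <- op[rpx + seq_len(d[2]), rpx + seq_len(d[3])]
    out[k, , ] <- pmax(sl - core, 0)
  }
  out
}

#' Dilate a binary/label mask by a voxel box radius
#'
#' Separable binary dilation (per-axis running maximum), used to grow
#' debris surfaces over their PSF halo before masking: a masked deposit
#' core would otherwise leave a bright annulus that seeds false filaments.
#'
#' @param mask 3D array (nonzero = labelled).
#' @param radiusVox integer (z, y, x) dilation radii in voxels.
#' @return logical array of the dilated mask.
#' @export
dilateMask <- function(mask, radiusVox = c(1L, 3L, 3L)) {
  m <- mask != 0
  d <- dim(m)
  shiftOr <- function(m, axis, r) {
    if (r <= 0) return(m)
    out <- m
    for (s in seq_len(r)) {
      idx1 <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx2 <- idx1
      idx1[[axis]] <- seq_len(d[axis] - s)
      idx2[[axis]] <- seq_len(d[axis] - s) + s
      out[idx1[[1]], idx1[[2]], idx1[[3]]] <-
        out[idx1[[1]], idx1[[2]], idx1[[3]]] |
        m[idx2[[1]], idx2[[2]], idx2[[3]]]
      out[idx2[[1]], idx2[[2]], idx2[[3]]] <-
        out[idx2[[1]], idx2[[2]], idx2[[3]]] |
        m[idx1[[1]], idx1[[2]], idx1[[3]]]
    }
    out
  }
  for (ax in 1:3) m <- shiftOr(m, ax, as.integer(radiusVox[ax]))
  m
}

#' Mask labelled voxels to a constant
#'
#' Returns a new channel in which every voxel under a nonzero label is set
#' to \code{value}; the input is untouched.
#'
#' @param ch 3D channel array.
#' @param mask integer label array of the same shape (0 = keep).
#' @param value replacement value.
#' @return masked copy of \code{ch}.
#' @export
maskVoxels <- function(ch, mask, value = 0) {
  if (!identical(dim(ch), dim(mask)))
    stop("channel and mask shapes differ", call. = FALSE)
  out <- ch
  out[mask != 0] <- value
  out
}
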