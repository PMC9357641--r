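#' Tile grid constructor
#'
#' The cropping convention: 128 x 128-pixel tiles (64 um at 0.50 um/pixel)
#' on an 8 x 8 grid, partitioning a 1024 x 1024 frame into 64 tiles.
#'
#' @param tileSidePx tile side in pixels.
#' @param tilesPerSide tiles along each image side.
#' @return a [TileGrid-class].
#' @examples
#' g <- tileGrid()
#' tilesPerImage(g)   # 64
#' @export
tileGrid <- function(tileSidePx = 128L, tilesPerSide = 8L) {
  new("TileGrid", tileSidePx = as.integer(tileSidePx),
      tilesPerSide = as.integer(tilesPerSide))
}

#' @rdname tileGrid
#' @param grid a [TileGrid-class].
#' @export
tilesPerImage <- function(grid) grid@tilesPerSide * grid@tilesPerSide

#' @rdname tileGrid
#' @param pixelSizeUm lateral pixel size in um.
#' @return \code{tileSideUm}: physical tile side in um (64 for the
#'   reference configuration).
#' @export
tileSideUm <- function(grid, pixelSizeUm = 0.50) grid@tileSidePx * pixelSizeUm

#' Calibrate the z-coordinate of a stack
#'
#' Defines z = 0 as the first plane at which fluorescent signal is detected
#' in almost the entire image area: the first plane where the fraction of
#' pixels (channel-mean intensity) above a noise floor of
#' \code{backgroundLevel + 2 * noiseSd} reaches \code{coverageThreshold}.
#' Planes with calibrated depth \code{<= maxDepthUm} are retained (at most
#' 11 planes at 3 um steps over 30 um).
#'
#' When \code{backgroundLevel}/\code{noiseSd} are not given they are
#' estimated robustly (median and MAD of the dimmest plane).
#'
#' @param stack an [MPMStack-class].
#' @param coverageThreshold fraction of the frame that must carry signal
#'   (default 0.90, an explicit reading of "almost the entire image area").
#' @param backgroundLevel,noiseSd optional noise model in gray levels.
#' @return a list: \code{z0} (1-based index of the calibrated surface
#'   plane), \code{planes} (1-based indices of retained planes) and
#'   \code{depthsUm} (calibrated depth of each retained plane).
#' @export
calibrateZ <- function(stack, coverageThreshold = 0.90,
                       backgroundLevel = NULL, noiseSd = NULL) {
  stopifnot(is(stack, "MPMStack"))
  g <- stack@geometry
  nP <- g@nPlanes
  ## channel-mean image per plane
  planeMean <- function(p) {
    m <- stack@voxels[, , 1, p]
    if (g@nChannels > 1)
      for (k in 2:g@nChannels) m <- m + stack@voxels[, , k, p]
    m / g@nChannels
  }
  means <- lapply(seq_len(nP), planeMean)
  if (is.null(backgroundLevel) || is.null(noiseSd)) {
    dimmest <- means[[which.min(vapply(means, mean, numeric(1)))]]
    if (is.null(backgroundLevel)) backgroundLevel <- stats::median(dimmest)
    if (is.null(noiseSd)) noiseSd <- stats::mad(dimmest)
  }
  floorLevel <- backgroundLevel + 2 * noiseSd
  frac <- vapply(means, function(m) mean(m > floorLevel), numeric(1))
  z0 <- which(frac >= coverageThreshold)[1]
  if (is.na(z0))
    stop("z-calibration failure: no plane reaches coverage threshold ",
         coverageThreshold)
  depths <- (seq_len(nP) - z0) * g@zStepUm
  keep <- which(depths >= 0 & depths <= g@maxDepthUm)
  list(z0 = z0, planes = keep, depthsUm = depths[keep])
}

#' Standardize an image to zero mean and unit variance
#'
#' Per-channel standardization of one image: each channel is shifted and
#' scaled so its mean is 0 and its standard deviation is 1. Standardization
#' per channel (rather than jointly) keeps the sparse SHG channel from
#' being dominated by the broad autofluorescence channels.
#'
#' @param image numeric array \code{[y, x, channel]} (a matrix is treated
#'   as a single channel).
#' @return a numeric array of the same shape, per-channel mean 0 and SD 1.
#' @examples
#' x <- array(rnorm(32 * 32 * 3, 5, 2), c(32, 32, 3))
#' s <- standardizeImage(x)
#' round(apply(s, 3, mean), 6)   # 0 0 0
#' @export
standardizeImage <- function(image) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 3L)
  out <- image
  for (k in seq_len(dim(image)[3])) {
    v <- image[, , k]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("degenerate channel ", k,
           ": constant intensity cannot be standardized")
    out[, , k] <- (v - mean(v)) / s
  }
  out
}

#' Crop an image into its grid of tiles
#'
#' Partitions the image into non-overlapping \code{tileSidePx} squares in
#' row-major order (origin top-left, 0-based grid coordinates); each pixel
#' lands in exactly one tile.
#'
#' @param image numeric array \code{[y, x, channel]}.
#' @param grid a [TileGrid-class]; \code{tilesPerSide} is inferred from the
#'   image when it differs from the grid's default.
#' @param imageId identifier recorded in the tile manifest.
#' @return a [TileSet-class] with \code{tilesPerSide^2} tiles.
#' @examples
#' img <- array(runif(256 * 256 * 3), c(256, 256, 3))
#' ts <- cropTiles(img)          # 4 tiles of 128 x 128
#' nrow(tileInfo(ts))            # 4
#' @export
cropTiles <- function(image, grid = tileGrid(), imageId = "img") {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  s <- grid@tileSidePx
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    stop("geometry error: image sides (", d[1], " x ", d[2],
         ") are not divisible by the tile side ", s)
  if (d[1] != d[2])
    stop("geometry error: image must be square")
  n <- d[1] %/% s
  nt <- n * n
  px <- array(0, c(s, s, d[3], nt))
  gr <- integer(nt); gc <- integer(nt)
  t <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {   # row-major
    t <- t + 1L
    px[, , , t] <- image[((i - 1L) * s + 1L):(i * s),
                         ((j - 1L) * s + 1L):(j * s), , drop = FALSE]
    gr[t] <- i - 1L; gc[t] <- j - 1L
  }
  new("TileSet", pixels = px,
      info = data.frame(image_id = imageId, grid_row = gr, grid_col = gc,
                        stringsAsFactors = FALSE))
}

#' Accessors for TileSet
#'
#' @param tiles a [TileSet-class].
#' @return \code{tileInfo}: the manifest data.frame; \code{tilePixels}: the
#'   pixel array \code{[y, x, channel, tile]}; \code{nTiles}: tile count.
#' @export
tileInfo <- function(tiles) tiles@info

#' @rdname tileInfo
#' @export
tilePixels <- function(tiles) tiles@pixels

#' @rdname tileInfo
#' @export
nTiles <- function(tiles) dim(tiles@pixels)[4]

#' Random training/validation split of tiles
#'
#' Tile-level (not patient-level) random split: \code{round(fraction * n)}
#' tiles go to validation and the rest to training; the two sets are
#' disjoint and exhaustive, and the split is deterministic given the seed.
#'
#' @param x a [TileSet-class], a manifest data.frame, or a tile count.
#' @param fraction validation fraction in (0, 1); default 0.20.
#' @param seed RNG seed.
#' @return a list with integer index vectors \code{training} and
#'   \code{validation}.
#' @examples
#' sp <- splitTrainValidation(112960L, 0.20, seed = 1L)
#' length(sp$validation)   # 22592
#' length(sp$training)     # 90368
#' @export
splitTrainValidation <- function(x, fraction = 0.20, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  n <- if (is(x, "TileSet")) nTiles(x)
       else if (is.data.frame(x)) nrow(x)
       else as.integer(x)
  nVal <- round(fraction * n)
  val <- withSeed(seed, sort(sample.int(n, nVal)))
  list(training = setdiff(seq_len(n), val), validation = val)
}
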