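#' Blank-tile rule constructor
#'
#' A tile is blank iff its signal-to-noise ratio against the median-filtered
#' pseudo-noiseless tile is below \code{snrThreshold} AND its mean
#' brightness on the [0, 1] full-scale axis is below
#' \code{brightnessThreshold} (conjunction). The SNR threshold 20 is
#' interpreted in decibels by default (\code{snrMode = "ratio"} is
#' available); both readings are explicit package interpretations, as is
#' the 3 x 3 median window.
#'
#' @param snrThreshold SNR threshold (20).
#' @param brightnessThreshold mean-brightness threshold (0.10).
#' @param medianWindow odd median-filter window side (3).
#' @param snrMode \code{"db"} or \code{"ratio"}.
#' @return a [BlankRule-class].
#' @export
blankRule <- function(snrThreshold = 20, brightnessThreshold = 0.10,
                      medianWindow = 3L, snrMode = c("db", "ratio")) {
  new("BlankRule", snrThreshold = as.numeric(snrThreshold),
      brightnessThreshold = as.numeric(brightnessThreshold),
      medianWindow = as.integer(medianWindow),
      snrMode = match.arg(snrMode))
}

## 2-D median filter of a matrix with reflecting edges. The 3 x 3 case uses
## a vectorized median-of-9 selection network; other odd windows fall back
## to an explicit neighborhood median.
medianFilter2D <- function(m, window = 3L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  if (window == 1L) return(m)
  h <- (window - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  ## reflect-pad
  ridx <- c(rev(seq_len(h) + 1L), seq_len(H), H - seq_len(h))
  cidx <- c(rev(seq_len(h) + 1L), seq_len(W), W - seq_len(h))
  P <- m[ridx, cidx]
  if (window == 3L) {
    a <- vector("list", 9L)
    t <- 0L
    for (dy in 0:2) for (dx in 0:2) {
      t <- t + 1L
      a[[t]] <- P[(1L + dy):(H + dy), (1L + dx):(W + dx)]
    }
    .median9(a)
  } else {
    out <- matrix(0, H, W)
    nb <- matrix(0, H * W, window * window)
    t <- 0L
    for (dy in 0:(window - 1L)) for (dx in 0:(window - 1L)) {
      t <- t + 1L
      nb[, t] <- P[(1L + dy):(H + dy), (1L + dx):(W + dx)]
    }
    out[] <- apply(nb, 1L, stats::median)
    out
  }
}

## median of 9 equally-shaped matrices via the 19-exchange selection
## network (element-wise pmin/pmax); the median lands in a[[5]]
.median9 <- function(a) {
  s2 <- function(i, j) { lo <- pmin(a[[i]], a[[j]]); hi <- pmax(a[[i]], a[[j]])
                         a[[i]] <<- lo; a[[j]] <<- hi }
  s2(2,3); s2(5,6); s2(8,9)
  s2(1,2); s2(4,5); s2(7,8)
  s2(2,3); s2(5,6); s2(8,9)
  s2(1,4); s2(6,9); s2(5,8)
  s2(4,7); s2(2,5); s2(3,6)
  s2(5,8); s2(5,3); s2(7,5); s2(5,3)
  a[[5]]
}

#' Pseudo-noiseless tile by median filtering
#'
#' Per-channel 2-D median filter with the configured window and reflecting
#' edge handling; the result estimates the noise-free tile against which
#' the SNR is computed. Operates on raw-intensity tiles (pre-standardization).
#'
#' @param pixels numeric array \code{[y, x, channel]} (or a matrix).
#' @param rule a [BlankRule-class].
#' @return an array of the same shape.
#' @export
pseudoNoiseless <- function(pixels, rule = blankRule()) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  out <- pixels
  for (k in seq_len(dim(pixels)[3]))
    out[, , k] <- medianFilter2D(pixels[, , k], rule@medianWindow)
  out
}

#' Tile signal-to-noise ratio
#'
#' SNR of a raw-intensity tile against its median-filtered pseudo-noiseless
#' estimate: in \code{"db"} mode,
#' \code{20 * log10(RMS(denoised) / RMS(residual))}; in \code{"ratio"} mode
#' the plain RMS ratio. Degenerate cases: zero residual with nonzero signal
#' gives \code{+Inf}; an all-zero tile gives 0.
#'
#' @param pixels numeric array \code{[y, x, channel]} on the raw intensity
#'   scale.
#' @param rule a [BlankRule-class].
#' @return a dimensionless SNR.
#' @export
tileSNR <- function(pixels, rule = blankRule()) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  den <- pseudoNoiseless(pixels, rule)
  rms <- function(x) sqrt(mean(x^2))
  sRMS <- rms(den)
  nRMS <- rms(pixels - den)
  if (nRMS == 0) {
    if (sRMS > 0) return(Inf)
    return(0)
  }
  r <- sRMS / nRMS
  if (rule@snrMode == "db") 20 * log10(r) else r
}

#' Mean tile brightness on the [0, 1] scale
#'
#' Mean over all channels and pixels of \code{intensity / fullScale}
#' (full scale 4095 for 12-bit data). Computed on raw intensities, not
#' standardized values: a mean-zero standardized tile would make a 0.10
#' brightness threshold meaningless.
#'
#' @param pixels numeric array of raw gray levels.
#' @param fullScale gray level mapped to brightness 1.0.
#' @return mean brightness in [0, 1].
#' @export
meanBrightness <- function(pixels, fullScale = 4095) {
  mean(pixels) / fullScale
}

#' Blank-tile decision
#'
#' TRUE iff \code{tileSNR < snrThreshold} AND
#' \code{meanBrightness < brightnessThreshold}.
#'
#' @param pixels numeric array of raw gray levels \code{[y, x, channel]}.
#' @param rule a [BlankRule-class].
#' @param fullScale gray level mapped to brightness 1.0.
#' @return logical.
#' @examples
#' dark <- array(rnorm(128 * 128 * 3, 80, 12), c(128, 128, 3))
#' isBlank(dark)   # TRUE: low SNR and brightness ~0.02
#' @export
isBlank <- function(pixels, rule = blankRule(), fullScale = 4095) {
  if (meanBrightness(pixels, fullScale) >= rule@brightnessThreshold)
    return(FALSE)
  tileSNR(pixels, rule) < rule@snrThreshold
}
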