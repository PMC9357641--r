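## Shared fixtures, built in code at test time.

## fine-grid numerical oracle for the channel response of a Gaussian
## emission line: integrate the line shape over each filter pass-band on a
## 0.01 nm grid, independent of the package's binned-spectrum path
gaussChannelOracle <- function(peak, fwhm, amplitude = 1,
                               centers = c(390, 480, 629),
                               widths = c(18, 40, 56),
                               lo = 380, hi = 630) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(seq_along(centers), function(k) {
    a <- max(lo, centers[k] - widths[k] / 2)
    b <- min(hi, centers[k] + widths[k] / 2)
    if (b <= a) return(0)
    grid <- seq(a, b, by = 0.01)
    sum(amplitude * exp(-(grid - peak)^2 / (2 * sigma^2))) * 0.01
  }, numeric(1))
}

## brute-force 2-D median filter with reflecting edges (oracle for the
## selection-network and C++ implementations)
bruteMedianFilter <- function(m, window = 3L) {
  h <- (window - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  refl <- function(i, n) ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ys <- refl(i + (-h:h), H)
    xs <- refl(j + (-h:h), W)
    out[i, j] <- stats::median(m[ys, xs])
  }
  out
}

## a linearly separable two-class tile fixture: class 1 carries vertical
## stripes, class 0 horizontal stripes, plus mild noise; standardized scale
separableTiles <- function(n, side = 32L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- array(stats::rnorm(side * side * 3L * n, 0, 0.3),
             c(side, side, 3L, n))
  stripesV <- sin(2 * pi * seq_len(side) / 8)
  for (i in seq_len(n)) {
    pat <- if (y[i] == 1) matrix(stripesV, side, side, byrow = TRUE)
           else matrix(stripesV, side, side)
    for (k in 1:3) x[, , k, i] <- x[, , k, i] + pat
  }
  list(x = x, y = y)
}

## small cancer/normal phantom specs used across tests
tinyCancerSpec <- function(seed = 11L, side = 512L, noiseSd = 12)
  phantomSpec(stackGeometry(side, side), tissueClass = "cancer",
              ducts = 1L, adipose = 1L, collagen = 2L, dcis = 1L,
              invasive = 1L, immune = 1L, noiseSd = noiseSd, seed = seed)

tinyNormalSpec <- function(seed = 21L, side = 512L, noiseSd = 12)
  phantomSpec(stackGeometry(side, side), tissueClass = "normal",
              ducts = 2L, adipose = 1L, collagen = 2L, immune = 1L,
              noiseSd = noiseSd, seed = seed)

## per-tile structure coverage of a mask on a tile grid
tileCoverage <- function(mask, tileSide = 128L) {
  n <- nrow(mask) %/% tileSide
  out <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ys <- ((i - 1L) * tileSide + 1L):(i * tileSide)
    xs <- ((j - 1L) * tileSide + 1L):(j * tileSide)
    out <- c(out, mean(mask[ys, xs]))
  }
  out
}
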