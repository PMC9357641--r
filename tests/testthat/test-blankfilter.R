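test_that("median filtering matches a brute-force neighborhood oracle", {
  set.seed(4)
  m <- matrix(as.numeric(sample(0:50, 40 * 33, TRUE)), 40, 33)
  expect_equal(medianFilter2D(m, 3L), bruteMedianFilter(m, 3L))
  ## checkerboard: interior becomes the local majority
  cb <- matrix((outer(1:12, 1:12, "+") %% 2) + 0, 12, 12)
  expect_equal(medianFilter2D(cb, 3L), bruteMedianFilter(cb, 3L))
  ## 5x5 window path
  expect_equal(medianFilter2D(m, 5L), bruteMedianFilter(m, 5L))
})

test_that("C++ stack median agrees with the R selection network", {
  set.seed(5)
  x <- array(rnorm(24 * 24 * 3 * 4), c(24, 24, 3, 4))
  fast <- mpmtiles:::.medianStack(x, 3L)
  for (t in 1:4) for (k in 1:3)
    expect_equal(fast[, , k, t], medianFilter2D(x[, , k, t], 3L))
})

test_that("pseudo-noiseless image removes impulses, keeps constants", {
  const <- array(7, c(16, 16, 2))
  expect_identical(pseudoNoiseless(const), const)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 100
  expect_true(all(pseudoNoiseless(imp) == 0))
})

test_that("tile SNR handles degenerate cases and matches a ramp oracle", {
  expect_identical(tileSNR(array(5, c(8, 8, 1))), Inf)
  expect_identical(tileSNR(array(0, c(8, 8, 1))), 0)
  ## smooth ramp + seeded noise: SNR within 1 dB of the oracle that knows
  ## the true noise-free ramp
  set.seed(6)
  ramp <- outer(seq(100, 900, length.out = 64),
                seq(0, 400, length.out = 64), "+") / 2
  noise <- matrix(rnorm(64 * 64, 0, 15), 64, 64)
  tile <- ramp + noise
  oracle <- 20 * log10(sqrt(mean(ramp^2)) / sqrt(mean(noise^2)))
  expect_lt(abs(tileSNR(tile) - oracle), 1)
})

test_that("ratio mode reports the linear RMS ratio", {
  set.seed(7)
  tile <- matrix(500 + rnorm(32 * 32, 0, 10), 32, 32)
  db <- tileSNR(tile, blankRule(snrMode = "db"))
  ratio <- tileSNR(tile, blankRule(snrMode = "ratio"))
  expect_equal(db, 20 * log10(ratio))
})

test_that("mean brightness is the full-scale-normalized mean", {
  expect_equal(meanBrightness(array(0, c(4, 4, 3))), 0)
  expect_equal(meanBrightness(array(4095, c(4, 4, 3))), 1)
  half <- array(c(0, 4095), c(4, 4, 2))
  expect_equal(meanBrightness(half), 0.5)
})

test_that("blankness is the conjunction of low SNR and low brightness", {
  set.seed(8)
  ## dark noise-only tile: both conditions hold
  dark <- array(pmax(0, rnorm(128 * 128 * 3, 80, 12)), c(128, 128, 3))
  expect_true(isBlank(dark))
  ## bright tissue tile: brightness alone rescues it
  bright <- dark + 1600
  expect_false(isBlank(bright))
  ## dark but smooth tile: SNR alone rescues it
  smooth <- array(rep(outer(seq(60, 250, length.out = 128),
                            seq(0, 60, length.out = 128), "+"), 3),
                  c(128, 128, 3))
  expect_gte(tileSNR(smooth), 20)
  expect_lt(meanBrightness(smooth), 0.10)
  expect_false(isBlank(smooth))
})

test_that("vectorized blank flags agree with per-tile decisions", {
  ph <- generatePhantom(tinyCancerSpec(seed = 12L))
  ts <- cropTiles(ph$stack@voxels[, , , 1], imageId = "x")
  flags <- mpmtiles:::blankFlags(tilePixels(ts))
  for (t in seq_len(nTiles(ts))) {
    px <- tilePixels(ts)[, , , t]
    expect_identical(flags$is_blank[t], isBlank(px))
    expect_equal(flags$snr[t], tileSNR(px))
    expect_equal(flags$brightness[t], meanBrightness(px))
  }
})
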