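makeStack <- function(planeLevels, side = 64L, noise = 0, seed = 1L) {
  nP <- length(planeLevels)
  set.seed(seed)
  vox <- array(0L, c(side, side, 3L, nP))
  for (p in seq_len(nP))
    vox[, , , p] <- as.integer(pmax(0, round(
      planeLevels[p] + rnorm(side * side * 3L, 0, noise))))
  new("MPMStack",
      voxels = vox,
      geometry = stackGeometry(side, side, nPlanes = nP),
      imageId = "s", patientId = "P01", group = "A", tissueLabel = "normal")
}

test_that("z-calibration finds the first full-coverage plane", {
  ## two background planes, then bright tissue from plane 3 on
  st <- makeStack(c(80, 80, 900, 900, 900), noise = 10)
  cal <- calibrateZ(st, backgroundLevel = 80, noiseSd = 10)
  expect_identical(cal$z0, 3L)
  expect_equal(cal$depthsUm[1], 0)
})

test_that("retained planes stop at 30 um: at most 11 planes at 3 um steps", {
  st <- makeStack(rep(900, 20), noise = 5)
  cal <- calibrateZ(st, backgroundLevel = 80, noiseSd = 5)
  expect_identical(cal$z0, 1L)
  expect_length(cal$planes, 11L)
  expect_equal(max(cal$depthsUm), 30)
})

test_that("all-background stacks fail calibration", {
  st <- makeStack(rep(80, 4), noise = 10)
  expect_error(calibrateZ(st, backgroundLevel = 80, noiseSd = 10),
               "calibration failure")
})

test_that("standardization yields per-channel mean 0 and SD 1", {
  set.seed(2)
  img <- array(rnorm(64 * 64 * 3, 500, 120), c(64, 64, 3))
  s <- standardizeImage(img)
  for (k in 1:3) {
    expect_lt(abs(mean(s[, , k])), 1e-6)
    expect_lt(abs(sd(s[, , k]) - 1), 1e-6)
  }
  ## idempotence and affine invariance
  expect_equal(standardizeImage(s), s, tolerance = 1e-9)
  expect_equal(standardizeImage(3.7 * img + 11), s, tolerance = 1e-9)
})

test_that("a balanced two-level channel standardizes to -1 / +1", {
  img <- matrix(rep(c(0, 2), each = 32), 8, 8)
  s <- standardizeImage(img)
  vals <- sort(unique(round(as.vector(s), 6)))
  ## sample SD of a balanced {0,2} sample is slightly above 1; population
  ## values are -1/+1 up to that factor
  expect_equal(vals[1], -vals[2])
  expect_lt(abs(abs(vals[1]) - 1), 0.02)
  expect_equal(mean(s), 0)
})

test_that("constant channels are rejected as degenerate", {
  img <- array(1, c(16, 16, 3))
  expect_error(standardizeImage(img), "degenerate channel")
})

test_that("cropping partitions the image without overlap", {
  set.seed(3)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  ts <- cropTiles(img, imageId = "img1")
  expect_identical(nTiles(ts), 4L)
  info <- tileInfo(ts)
  expect_identical(info$grid_row, c(0L, 0L, 1L, 1L))
  expect_identical(info$grid_col, c(0L, 1L, 0L, 1L))
  ## reassemble
  rec <- array(0, dim(img))
  for (t in seq_len(4)) {
    i <- info$grid_row[t]; j <- info$grid_col[t]
    rec[(i * 128 + 1):(i * 128 + 128),
        (j * 128 + 1):(j * 128 + 128), ] <- tilePixels(ts)[, , , t]
  }
  expect_identical(rec, img)
})

test_that("single-tile and full-frame crops behave", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  ts <- cropTiles(img)
  expect_identical(nTiles(ts), 1L)
  expect_identical(tilePixels(ts)[, , , 1], img)
  big <- array(0, c(1024, 64, 3))
  expect_error(cropTiles(big), "geometry error")
  odd <- array(0, c(100, 100, 3))
  expect_error(cropTiles(odd), "geometry error")
})

test_that("train/validation split reproduces the clinical tile arithmetic", {
  sp <- splitTrainValidation(112960L, 0.20, seed = 1L)
  expect_length(sp$validation, 22592L)
  expect_length(sp$training, 90368L)
  expect_length(intersect(sp$training, sp$validation), 0L)
  expect_setequal(c(sp$training, sp$validation), seq_len(112960L))
})

test_that("splits are deterministic and validated", {
  a <- splitTrainValidation(100L, 0.20, seed = 7L)
  b <- splitTrainValidation(100L, 0.20, seed = 7L)
  expect_identical(a, b)
  expect_length(a$validation, 20L)
  expect_error(splitTrainValidation(100L, 1.2), "fraction")
  expect_error(splitTrainValidation(100L, 0), "fraction")
})
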