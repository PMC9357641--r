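test_that("network gradients match finite differences", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- c(1, 0, 1)
  w <- c(2, 1, 2)
  p <- mpmtiles:::.cnnInit(2L)
  p$w4 <- rnorm(64, 0, 0.3)   # output layer initializes at zero; randomize
  p$b4 <- 0.1                 # so every layer's gradient path is exercised
  fwd <- mpmtiles:::.cnnForward(p, x, keep = TRUE)
  gr <- mpmtiles:::.cnnBackward(p, fwd, mpmtiles:::.bceGrad(fwd$z, y, w))
  lossAt <- function(q) mpmtiles:::.bceLoss(mpmtiles:::.cnnForward(q, x)$z, y, w)
  eps <- 1e-6
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      up <- p; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- p; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][k]) / max(1e-6, abs(num) + abs(gr[[nm]][k])),
                1e-4)
    }
  }
})

test_that("separable classes are learned to perfect validation accuracy", {
  tr <- separableTiles(160, seed = 1L)
  va <- separableTiles(48, seed = 2L)
  cfg <- trainConfig(epochs = 10L, learningRate = 0.01, batchSize = 32L,
                     seed = 3L)
  model <- trainTileClassifier(tr$x, tr$y, va$x, va$y, cfg)
  expect_equal(model@validationScore, 1.0)
  ## tile-level decision: cancer-class tiles score > 0.5
  p <- predictTiles(model, va$x)
  expect_true(all((p >= 0.5) == (va$y == 1)))
})

test_that("permuted labels stay at chance accuracy", {
  tr <- separableTiles(160, seed = 4L)
  va <- separableTiles(60, seed = 5L)
  set.seed(6)
  ## break the label-feature association everywhere: no signal to learn
  yPermTr <- sample(tr$y)
  yPermVa <- sample(va$y)
  cfg <- trainConfig(epochs = 4L, learningRate = 0.01, batchSize = 32L,
                     seed = 7L)
  model <- trainTileClassifier(tr$x, yPermTr, va$x, yPermVa, cfg)
  ## chance 0.5 within binomial noise at n = 60
  expect_gt(model@validationScore, 0.30)
  expect_lt(model@validationScore, 0.70)
})

test_that("an untrained model scores a balanced set near one half", {
  va <- separableTiles(200, seed = 8L)
  model <- untrainedTileClassifier(3L, seed = 9L)
  p <- predictTiles(model, va$x)
  expect_gte(mean(p), 0.45)
  expect_lte(mean(p), 0.55)
})

test_that("prediction is deterministic and respects the blank contract", {
  va <- separableTiles(10, seed = 10L)
  model <- untrainedTileClassifier(3L, seed = 1L)
  expect_identical(predictTiles(model, va$x), predictTiles(model, va$x))
  ts <- new("TileSet", pixels = va$x[, , , 1:2, drop = FALSE],
            info = data.frame(image_id = "i", grid_row = 0:1, grid_col = 0L,
                              is_blank = c(FALSE, TRUE)))
  expect_error(predictTiles(model, ts), "contract violation")
})

test_that("training rejects single-class inputs", {
  tr <- separableTiles(20, seed = 11L)
  va <- separableTiles(8, seed = 12L)
  expect_error(
    trainTileClassifier(tr$x, rep(1, 20), va$x, va$y,
                        trainConfig(epochs = 1L)),
    "degenerate training set")
})

test_that("model selection picks the earliest best validation epoch", {
  tr <- separableTiles(120, seed = 13L)
  va <- separableTiles(40, seed = 14L)
  cfg <- trainConfig(epochs = 8L, learningRate = 0.01, batchSize = 32L,
                     seed = 15L)
  model <- trainTileClassifier(tr$x, tr$y, va$x, va$y, cfg)
  h <- model@history
  expect_identical(which(h$selected), min(which(h$val_accuracy ==
                                                  max(h$val_accuracy))))
  expect_equal(model@validationScore, max(h$val_accuracy))
})

test_that("training is deterministic given the seed", {
  tr <- separableTiles(64, seed = 16L)
  va <- separableTiles(16, seed = 17L)
  cfg <- trainConfig(epochs = 2L, learningRate = 0.01, batchSize = 32L,
                     seed = 18L)
  m1 <- trainTileClassifier(tr$x, tr$y, va$x, va$y, cfg)
  m2 <- trainTileClassifier(tr$x, tr$y, va$x, va$y, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
})

test_that("checkpoints round-trip through the text format", {
  tr <- separableTiles(64, seed = 19L)
  va <- separableTiles(16, seed = 20L)
  model <- trainTileClassifier(tr$x, tr$y, va$x, va$y,
                               trainConfig(epochs = 2L, learningRate = 0.01,
                                           batchSize = 32L, seed = 21L))
  base <- tempfile()
  saveTileClassifier(model, base)
  back <- loadTileClassifier(base)
  expect_equal(predictTiles(back, va$x), predictTiles(model, va$x),
               tolerance = 1e-12)
  unlink(paste0(base, c(".params.txt", ".json")))
})
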