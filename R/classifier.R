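#' Training configuration constructor
#'
#' Defaults follow the reference protocol: Adam, 100 epochs, learning rate
#' 0.020, batch size 128. The architecture is the package's small
#' convolutional network; see the methods vignette for the desk-scale
#' settings used in the bundled pipeline configuration.
#'
#' @param architecture currently \code{"small_cnn"}.
#' @param epochs training epochs (>= 1).
#' @param learningRate Adam learning rate.
#' @param batchSize mini-batch size.
#' @param optimizer currently \code{"adam"}.
#' @param classWeighting \code{"none"} or \code{"balanced"} (positives
#'   up-weighted by the negative/positive count ratio).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(architecture = "small_cnn", epochs = 100L,
                        learningRate = 0.020, batchSize = 128L,
                        optimizer = "adam", classWeighting = "none",
                        seed = 1L) {
  new("TrainConfig", architecture = architecture,
      epochs = as.integer(epochs), learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), optimizer = optimizer,
      classWeighting = classWeighting, seed = as.integer(seed))
}

.asTileArray <- function(x) {
  if (is(x, "TileSet")) x <- tilePixels(x)
  stopifnot(is.array(x), length(dim(x)) == 4L)
  x
}

.asLabels01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("cancer", "no_cancer"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    as.numeric(labels == "cancer")
  } else as.numeric(labels)
}

#' Train the tile classifier
#'
#' Trains the small convolutional network on standardized, nonblank tiles
#' with binary labels, evaluating validation accuracy after every epoch and
#' returning the parameter state of the best epoch (model selection on the
#' validation set; ties resolved toward the earliest epoch). Deterministic
#' given \code{config@seed}.
#'
#' @param trainTiles,valTiles [TileSet-class] objects or arrays
#'   \code{[y, x, channel, tile]} of standardized nonblank tiles.
#' @param trainLabels,valLabels labels: \code{"cancer"}/\code{"no_cancer"}
#'   or 0/1 numeric.
#' @param config a [TrainConfig-class].
#' @param verbose print per-epoch progress.
#' @return a [TileClassifierModel-class]; \code{model@history} holds the
#'   per-epoch training loss and validation accuracy.
#' @export
trainTileClassifier <- function(trainTiles, trainLabels, valTiles, valLabels,
                                config = trainConfig(), verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"))
  x <- .cnnPrep(.asTileArray(trainTiles))
  xv <- .cnnPrep(.asTileArray(valTiles))
  y <- .asLabels01(trainLabels)
  yv <- .asLabels01(valLabels)
  n <- dim(x)[4]
  stopifnot(length(y) == n, length(yv) == dim(xv)[4])
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only one class present")
  wpos <- if (config@classWeighting == "balanced")
    sum(y == 0) / sum(y == 1) else 1
  wAll <- ifelse(y == 1, wpos, 1)

  withSeed(config@seed, {
    state <- list(params = .cnnInit(dim(x)[3]))
    state$m <- lapply(state$params, function(p) p * 0)
    state$v <- state$m
    best <- list(acc = -Inf, params = state$params, epoch = 0L)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_accuracy = numeric())
    t <- 0L
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0L
      for (s in seq(1L, n, config@batchSize)) {
        idx <- ord[s:min(n, s + config@batchSize - 1L)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]; wb <- wAll[idx]
        fwd <- .cnnForward(state$params, xb, keep = TRUE)
        epLoss <- epLoss + .bceLoss(fwd$z, yb, wb); nb <- nb + 1L
        grads <- .cnnBackward(state$params, fwd, .bceGrad(fwd$z, yb, wb))
        t <- t + 1L
        state <- .adamStep(state, grads, config@learningRate, t)
      }
      pv <- .cnnPredictProb(state$params, xv)
      acc <- mean((pv >= 0.5) == (yv == 1))
      hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / nb,
                                     val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, params = state$params,
                                       epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val acc %.4f", ep,
                        epLoss / nb, acc))
    }
    hist$selected <- hist$epoch == best$epoch
    new("TileClassifierModel", architecture = config@architecture,
        params = best$params, config = config, history = hist,
        validationScore = best$acc, inputSide = dim(x)[1],
        dataFingerprint = paste(dim(.asTileArray(trainTiles)),
                                collapse = "x"))
  })
}

#' Predict cancer probabilities for tiles
#'
#' Deterministic forward pass of a trained (or freshly initialized) model;
#' returns the probability of cancer per tile. Tiles flagged blank must not
#' be scored: passing a [TileSet-class] containing blank tiles is a
#' contract violation.
#'
#' @param model a [TileClassifierModel-class].
#' @param tiles a [TileSet-class] or array \code{[y, x, channel, tile]} of
#'   standardized nonblank tiles.
#' @return numeric vector of probabilities in [0, 1].
#' @seealso [trainTileClassifier()], [untrainedTileClassifier()]
#' @export
predictTiles <- function(model, tiles) {
  stopifnot(is(model, "TileClassifierModel"))
  if (is(tiles, "TileSet") && "is_blank" %in% names(tileInfo(tiles)) &&
      any(tileInfo(tiles)$is_blank))
    stop("contract violation: blank tiles must not be passed to the classifier")
  x <- .cnnPrep(.asTileArray(tiles))
  .cnnPredictProb(model@params, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Untrained (randomly initialized) classifier
#'
#' Useful as a no-signal control: over a balanced test set the mean
#' predicted probability of a random-init model sits near 0.5.
#'
#' @param nChannels input channels.
#' @param seed RNG seed for the initialization.
#' @return a [TileClassifierModel-class] with random parameters.
#' @export
untrainedTileClassifier <- function(nChannels = 3L, seed = 1L) {
  params <- withSeed(seed, .cnnInit(as.integer(nChannels)))
  new("TileClassifierModel", architecture = "small_cnn", params = params,
      config = trainConfig(seed = as.integer(seed)),
      history = data.frame(), validationScore = NA_real_,
      inputSide = 32L, dataFingerprint = "untrained")
}

#' Save / load a classifier checkpoint
#'
#' Parameters go to a flat CSV-like text matrix; metadata (config,
#' validation score, history) to a JSON sidecar.
#'
#' @param model a [TileClassifierModel-class].
#' @param path base path (files \code{<path>.params.txt} and
#'   \code{<path>.json} are written).
#' @return \code{saveTileClassifier}: the path invisibly;
#'   \code{loadTileClassifier}: the restored model.
#' @export
saveTileClassifier <- function(model, path) {
  p <- model@params
  flat <- unlist(p)
  writeLines(format(flat, digits = 17), paste0(path, ".params.txt"))
  meta <- list(architecture = model@architecture,
               shapes = lapply(p, function(x) dim(x) %||% length(x)),
               config = list(epochs = model@config@epochs,
                             learningRate = model@config@learningRate,
                             batchSize = model@config@batchSize,
                             classWeighting = model@config@classWeighting,
                             seed = model@config@seed),
               validationScore = model@validationScore,
               inputSide = model@inputSide,
               dataFingerprint = model@dataFingerprint,
               history = model@history)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveTileClassifier
#' @export
loadTileClassifier <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.numeric(readLines(paste0(path, ".params.txt")))
  params <- list(); off <- 0L
  for (nm in names(meta$shapes)) {
    sh <- unlist(meta$shapes[[nm]])
    len <- prod(sh)
    v <- flat[(off + 1L):(off + len)]
    params[[nm]] <- if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
    off <- off + len
  }
  cfg <- trainConfig(epochs = meta$config$epochs,
                     learningRate = meta$config$learningRate,
                     batchSize = meta$config$batchSize,
                     classWeighting = meta$config$classWeighting,
                     seed = meta$config$seed)
  new("TileClassifierModel", architecture = meta$architecture,
      params = params, config = cfg,
      history = as.data.frame(meta$history),
      validationScore = meta$validationScore,
      inputSide = as.integer(meta$inputSide),
      dataFingerprint = meta$dataFingerprint)
}
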