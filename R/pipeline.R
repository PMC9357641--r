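#' Pipeline configuration constructor
#'
#' One object fixing every stage of an end-to-end run. The training
#' defaults here are the desk-scale settings (fewer epochs than the
#' reference protocol, balanced class weighting against the natural
#' scarcity of cancer tiles); see the methods vignette.
#'
#' @param phantomGeometry a [StackGeometry-class] for the simulated cohort.
#' @param spectral a [SpectralConfig-class].
#' @param blankRule a [BlankRule-class].
#' @param trainConfig a [TrainConfig-class].
#' @param verdictConfig a [VerdictConfig-class].
#' @param nPatients,imagesPerPatient cohort layout.
#' @param cancerFraction fraction of patients providing cancerous tissue.
#' @param seed global seed; stage seeds are derived from it.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(phantomGeometry = stackGeometry(),
                           spectral = spectralConfig(),
                           blankRule = NULL, trainConfig = NULL,
                           verdictConfig = NULL,
                           nPatients = 12L, imagesPerPatient = 8L,
                           cancerFraction = 0.5, seed = 1L) {
  if (is.null(blankRule)) blankRule <- mpmtiles::blankRule()
  if (is.null(trainConfig))
    trainConfig <- mpmtiles::trainConfig(epochs = 40L,
                                         classWeighting = "balanced")
  if (is.null(verdictConfig)) verdictConfig <- mpmtiles::verdictConfig()
  new("PipelineConfig", phantomGeometry = phantomGeometry,
      spectral = spectral, blankRule = blankRule,
      trainConfig = trainConfig, verdictConfig = verdictConfig,
      nPatients = as.integer(nPatients),
      imagesPerPatient = as.integer(imagesPerPatient),
      cancerFraction = as.numeric(cancerFraction), seed = as.integer(seed))
}

## vectorized blank decision for a raw tile stack [y, x, channel, tile]
blankFlags <- function(tilesRaw, rule = blankRule(), fullScale = 4095) {
  d <- dim(tilesRaw)
  den <- .medianStack(tilesRaw, rule@medianWindow)
  per <- d[1] * d[2] * d[3]
  sRMS <- sqrt(colMeans(matrix(den^2, per)))
  nRMS <- sqrt(colMeans(matrix((tilesRaw - den)^2, per)))
  bright <- colMeans(matrix(tilesRaw, per)) / fullScale
  ratio <- ifelse(nRMS == 0, ifelse(sRMS > 0, Inf, NA), sRMS / nRMS)
  snr <- if (rule@snrMode == "db") 20 * log10(ratio) else ratio
  snr[is.na(snr)] <- 0          # all-zero tiles
  data.frame(snr = snr, brightness = bright,
             is_blank = snr < rule@snrThreshold &
               bright < rule@brightnessThreshold)
}

## median filter every channel of every tile in one pass (3x3 network over
## the first two dims of a [y, x, slice] stack, reflecting edges)
.medianStack <- function(x4, window = 3L) {
  d <- dim(x4)
  if (window == 1L) return(x4)
  if (window != 3L) {
    out <- x4
    for (t in seq_len(d[4])) for (k in seq_len(d[3]))
      out[, , k, t] <- medianFilter2D(x4[, , k, t], window)
    return(out)
  }
  out <- .median3StackCpp(as.numeric(x4), d[1], d[2], d[3] * d[4])
  dim(out) <- d
  out
}

#' Simulate a cohort to disk
#'
#' Writes every cohort image as a multi-page TIFF with a JSON sidecar, the
#' truth masks as TIFF label images, and the cohort manifest as CSV.
#' Deterministic per seed.
#'
#' @param config a [PipelineConfig-class].
#' @param outDir writable output directory.
#' @param verbose log per-stage counts to stderr.
#' @return the manifest data.frame (with a \code{path} column), invisibly.
#' @export
runSimulate <- function(config, outDir, verbose = FALSE) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  cohort <- generateCohort(config@nPatients, config@imagesPerPatient,
                           config@cancerFraction, config@seed,
                           geometry = config@phantomGeometry)
  man <- cohort$manifest
  man$path <- file.path(outDir, paste0(man$image_id, ".tif"))
  for (i in seq_len(nrow(man))) {
    ph <- cohortImage(cohort, i, config@spectral)
    writeStackTIFF(ph$stack, man$path[i])
    tiff::writeTIFF(ph$truth@cancerMask * 1,
                    file.path(outDir, paste0(man$image_id[i], "_cancer.tif")),
                    bits.per.sample = 8L)
    if (verbose) message("simulated ", man$image_id[i])
  }
  utils::write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes the whole flow: simulate (in memory) -> blank-filter on raw
#' intensities -> standardize -> crop -> train on group A (with a
#' tile-level 20\% validation split) -> predict group B -> evaluate.
#' Returns the evaluation report: tile-level confusion matrix and metrics,
#' per-image verdicts, sensitivity/specificity, ROC points and AUC, and
#' stage-by-stage tile accounting. Deterministic given \code{config@seed}.
#'
#' @param config a [PipelineConfig-class].
#' @param verbose log stage progress to stderr.
#' @return a list of class \code{"mpmPipelineReport"}; see Details.
#' @details Report elements: \code{tileManifest} (per-tile CSV-ready data
#'   frame), \code{confusion} ([ConfusionMatrix-class]), \code{tileMetrics},
#'   \code{verdicts}, \code{imageRates}, \code{roc}, \code{counts} (tile
#'   accounting), \code{model} (the trained classifier) and \code{config}.
#' @export
runFull <- function(config, verbose = FALSE) {
  stopifnot(is(config, "PipelineConfig"))
  g <- config@phantomGeometry
  if (g@nPlanes != 1L)
    stop("runFull expects single-plane cohort images ",
         "(each retained plane is an independent image file)")
  cohort <- generateCohort(config@nPatients, config@imagesPerPatient,
                           config@cancerFraction, config@seed, geometry = g)
  man <- cohort$manifest
  nImg <- nrow(man)
  grid <- tileGrid(tileSidePx = 128L,
                   tilesPerSide = as.integer(g@widthPx %/% 128L))
  tpi <- tilesPerImage(grid)
  full <- config@spectral@fullScale

  pooled <- vector("list", nImg)
  rows <- vector("list", nImg)
  for (i in seq_len(nImg)) {
    ph <- cohortImage(cohort, i, config@spectral)
    raw <- ph$stack@voxels[, , , 1]
    rawTiles <- cropTiles(raw, grid, imageId = man$image_id[i])
    bf <- blankFlags(tilePixels(rawTiles), config@blankRule, full)
    std <- standardizeImage(raw)
    stdTiles <- cropTiles(std, grid, imageId = man$image_id[i])
    pooled[[i]] <- .cnnPrep(tilePixels(stdTiles))
    info <- tileInfo(stdTiles)
    info$patient_id <- man$patient_id[i]
    info$group <- man$group[i]
    info$tissue_label <- man$tissue_label[i]
    info$is_blank <- bf$is_blank
    info$truth_label <- as.vector(t(ph$truth@tileLabels))
    info$score <- NA_real_
    info$split <- NA_character_
    rows[[i]] <- info
    if (verbose && i %% 10 == 0)
      message("prepared ", i, "/", nImg, " images")
  }
  manifest <- do.call(rbind, rows)
  tiles <- array(unlist(pooled),
                 c(dim(pooled[[1]])[1:3], nImg * tpi))
  rm(pooled)

  idxA <- which(manifest$group == "A")
  idxB <- which(manifest$group == "B")
  if (!length(idxA) || !length(idxB))
    stop("stage error [split]: both groups must be nonempty")
  sp <- splitTrainValidation(length(idxA), 0.20,
                             seed = deriveSeed(config@seed, 101L))
  manifest$split[idxA[sp$training]] <- "training"
  manifest$split[idxA[sp$validation]] <- "validation"

  selTrain <- idxA[sp$training][!manifest$is_blank[idxA[sp$training]]]
  selVal <- idxA[sp$validation][!manifest$is_blank[idxA[sp$validation]]]
  if (verbose)
    message("training on ", length(selTrain), " tiles, validating on ",
            length(selVal))
  model <- trainTileClassifier(
    tiles[, , , selTrain, drop = FALSE],
    manifest$truth_label[selTrain],
    tiles[, , , selVal, drop = FALSE],
    manifest$truth_label[selVal],
    config@trainConfig, verbose = verbose)

  selB <- idxB[!manifest$is_blank[idxB]]
  manifest$score[selB] <- .cnnPredictProb(model@params,
                                          tiles[, , , selB, drop = FALSE])

  manB <- manifest[idxB, ]
  cm <- tileOutcomes(manB)
  verdicts <- imageVerdicts(manB, config@verdictConfig,
                            nTilesPerImage = tpi)
  roc <- rocCurve(verdicts, nTilesPerImage = tpi)
  counts <- list(
    images = nImg, tilesPerImage = tpi, tilesTotal = nImg * tpi,
    groupA = length(idxA), groupB = length(idxB),
    blankA = sum(manifest$is_blank[idxA]),
    blankB = sum(manifest$is_blank[idxB]),
    trainingNonblank = length(selTrain), validationNonblank = length(selVal),
    testedNonblankB = length(selB),
    confusionTotal = totalCount(cm))
  if (counts$confusionTotal != counts$groupB)
    stop("stage error [evaluate]: confusion total does not conserve tiles")
  structure(list(tileManifest = manifest, confusion = cm,
                 tileMetrics = matrixMetrics(cm), verdicts = verdicts,
                 imageRates = imageLevelRates(verdicts), roc = roc,
                 counts = counts, model = model, config = config),
            class = "mpmPipelineReport")
}

#' Write a pipeline report to disk
#'
#' JSON report (confusion matrix, metrics, rates, ROC, counts) plus CSVs of
#' the tile manifest and per-image verdicts.
#'
#' @param report an \code{mpmPipelineReport} from [runFull()].
#' @param outDir writable output directory.
#' @return the JSON path, invisibly.
#' @export
writeReport <- function(report, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  cm <- report$confusion
  out <- list(
    confusion = list(tp = cm@tp, fp = cm@fp, fn = cm@fn, tn = cm@tn),
    tileMetrics = as.list(report$tileMetrics),
    imageRates = as.list(report$imageRates),
    auc = report$roc$auc,
    rocPoints = report$roc$points,
    counts = report$counts,
    seed = report$config@seed)
  path <- file.path(outDir, "report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$tileManifest,
                   file.path(outDir, "tile_manifest.csv"), row.names = FALSE)
  utils::write.csv(report$verdicts,
                   file.path(outDir, "image_verdicts.csv"), row.names = FALSE)
  invisible(path)
}

#' @export
print.mpmPipelineReport <- function(x, ...) {
  cat("MPM tile-classification pipeline report\n")
  cat(sprintf("  images: %d (A: %d tiles, B: %d tiles)\n",
              x$counts$images, x$counts$groupA, x$counts$groupB))
  cat(sprintf("  blanks: A %d, B %d\n", x$counts$blankA, x$counts$blankB))
  m <- x$tileMetrics
  cat(sprintf("  tile metrics: acc %.3f prec %.3f rec %.3f F %.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["f_measure"]))
  r <- x$imageRates
  cat(sprintf("  image rates: sens %.3f spec %.3f AUC %.3f\n",
              r["sensitivity"], r["specificity"], x$roc$auc))
  invisible(x)
}
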