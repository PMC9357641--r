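#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib mpmtiles, .registration = TRUE
NULL

#' Spectral acquisition configuration
#'
#' Describes the spectral-detector side of the acquisition: near-infrared
#' excitation wavelength, the detector window and its binning, and the
#' intensity quantization depth. The reference configuration is 780 nm
#' excitation, a 380--630 nm detector window split into 25 bins of 10 nm,
#' and 12-bit (4096-level) quantization.
#'
#' @slot excitationWavelength numeric, excitation wavelength in nm.
#' @slot detectorRangeLow,detectorRangeHigh numeric, detector window in nm.
#' @slot nBins integer, number of detector bins.
#' @slot quantizationLevels integer, number of gray levels (a power of two).
#' @slot fullScale numeric, intensity mapped to the top gray level.
#'
#' @seealso [spectralConfig()]
#' @export
setClass("SpectralConfig",
  representation(
    excitationWavelength = "numeric",
    detectorRangeLow     = "numeric",
    detectorRangeHigh    = "numeric",
    nBins                = "integer",
    quantizationLevels   = "integer",
    fullScale            = "numeric"
  )
)

setValidity("SpectralConfig", function(object) {
  msg <- NULL
  if (object@excitationWavelength <= 0)
    msg <- c(msg, "excitationWavelength must be positive")
  if (object@detectorRangeHigh <= object@detectorRangeLow)
    msg <- c(msg, "detectorRangeHigh must exceed detectorRangeLow")
  if (object@excitationWavelength <= object@detectorRangeHigh)
    msg <- c(msg, "excitation must lie above the detector window (red-shifted)")
  if (object@nBins < 1L)
    msg <- c(msg, "nBins must be >= 1")
  q <- object@quantizationLevels
  if (q < 2L || bitwAnd(q, q - 1L) != 0L)
    msg <- c(msg, "quantizationLevels must be a power of two >= 2")
  if (object@fullScale <= 0)
    msg <- c(msg, "fullScale must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Binned emission spectrum
#'
#' A fluorophore emission spectrum discretized onto the detector bins:
#' bin centers in nm (equally spaced, strictly increasing) and non-negative
#' relative intensities.
#'
#' @slot binCenters numeric vector of bin-center wavelengths (nm).
#' @slot intensities numeric vector of non-negative relative intensities.
#'
#' @seealso [emissionSpectrum()]
#' @export
setClass("EmissionSpectrum",
  representation(binCenters = "numeric", intensities = "numeric")
)

setValidity("EmissionSpectrum", function(object) {
  msg <- NULL
  if (length(object@binCenters) != length(object@intensities))
    msg <- c(msg, "binCenters and intensities must have equal length")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  d <- diff(object@binCenters)
  if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-9))
    msg <- c(msg, "binCenters must be strictly increasing and equally spaced")
  if (is.null(msg)) TRUE else msg
})

#' Tissue fluorophore
#'
#' A single emitting species of the tissue model: a named autofluorescent
#' component (or the SHG line of fibrillar collagen) with a Gaussian emission
#' line shape parameterized by peak wavelength, FWHM and relative amplitude.
#'
#' @slot name character, one of the recognised fluorophore labels.
#' @slot peakWavelength numeric, emission peak (nm).
#' @slot bandwidthFWHM numeric, full width at half maximum (nm).
#' @slot relativeAmplitude numeric, dimensionless amplitude (>= 0).
#'
#' @seealso [fluorophore()], [fluorophorePanel()]
#' @export
setClass("Fluorophore",
  representation(
    name              = "character",
    peakWavelength    = "numeric",
    bandwidthFWHM     = "numeric",
    relativeAmplitude = "numeric"
  )
)

setValidity("Fluorophore", function(object) {
  msg <- NULL
  if (object@bandwidthFWHM <= 0) msg <- c(msg, "bandwidthFWHM must be positive")
  if (object@relativeAmplitude < 0) msg <- c(msg, "relativeAmplitude must be >= 0")
  if (object@peakWavelength <= 0) msg <- c(msg, "peakWavelength must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Band-pass channel filter set
#'
#' The emission filters in front of the detection channels, each given as
#' (center, full width) in nm; the pass-band is
#' \eqn{[center - width/2, center + width/2]}. The reference set is
#' 390/18, 480/40 and 629/56 nm.
#'
#' @slot filters numeric matrix with columns \code{center} and \code{width},
#'   one row per channel.
#'
#' @seealso [channelFilters()]
#' @export
setClass("ChannelFilterSet", representation(filters = "matrix"))

setValidity("ChannelFilterSet", function(object) {
  f <- object@filters
  msg <- NULL
  if (!is.numeric(f) || ncol(f) != 2L)
    msg <- c(msg, "filters must be a numeric matrix with columns center, width")
  else if (any(f <= 0))
    msg <- c(msg, "filter centers and widths must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Physical geometry of an image stack
#'
#' Lateral and axial sampling of an acquisition: 1024 x 1024 pixels at
#' 0.50 um/pixel, z-stacks at 3 um steps retained down to 30 um below the
#' calibrated surface, three detection channels.
#'
#' @slot widthPx,heightPx integer, frame size in pixels.
#' @slot pixelSizeUm numeric, lateral pixel size (um).
#' @slot zStepUm numeric, axial step (um).
#' @slot maxDepthUm numeric, deepest retained calibrated depth (um).
#' @slot nChannels integer, number of detection channels.
#' @slot nPlanes integer, number of acquired z-planes.
#'
#' @seealso [stackGeometry()]
#' @export
setClass("StackGeometry",
  representation(
    widthPx = "integer", heightPx = "integer",
    pixelSizeUm = "numeric", zStepUm = "numeric", maxDepthUm = "numeric",
    nChannels = "integer", nPlanes = "integer"
  )
)

setValidity("StackGeometry", function(object) {
  msg <- NULL
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "frame size must be positive")
  if (object@pixelSizeUm <= 0 || object@zStepUm <= 0)
    msg <- c(msg, "pixel and z-step sizes must be positive")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@nPlanes < 1L) msg <- c(msg, "nPlanes must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Phantom specification
#'
#' Everything needed to render one synthetic MPM frame (or z-stack) of
#' breast tissue: geometry, tissue class, per-structure counts, acquisition
#' noise, and the seed making the rendering reproducible.
#'
#' @slot geometry a [StackGeometry-class].
#' @slot tissueClass character; \code{"normal"}, \code{"cancer"} or
#'   \code{"cancer_with_normal_regions"}.
#' @slot structureCounts named integer vector with entries \code{ducts},
#'   \code{adipose}, \code{collagen}, \code{dcis}, \code{invasive},
#'   \code{immune}.
#' @slot noiseSd numeric, additive Gaussian read-noise SD in gray levels.
#' @slot backgroundLevel numeric, background offset in gray levels.
#' @slot coverageFraction numeric, fraction of cancer-mask pixels above which
#'   a tile is labeled \code{cancer}.
#' @slot surfacePlanes integer, number of background-only planes above the
#'   tissue surface (z-stacks only).
#' @slot seed integer RNG seed.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    geometry = "StackGeometry",
    tissueClass = "character",
    structureCounts = "integer",
    noiseSd = "numeric",
    backgroundLevel = "numeric",
    coverageFraction = "numeric",
    surfacePlanes = "integer",
    seed = "integer"
  )
)

.structureNames <- c("ducts", "adipose", "collagen", "dcis", "invasive", "immune")

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  sc <- object@structureCounts
  if (!all(.structureNames %in% names(sc)))
    msg <- c(msg, paste("structureCounts must name:",
                        paste(.structureNames, collapse = ", ")))
  if (any(sc < 0L)) msg <- c(msg, "structure counts must be >= 0")
  if (!object@tissueClass %in% c("normal", "cancer", "cancer_with_normal_regions"))
    msg <- c(msg, "unknown tissueClass")
  if (object@tissueClass == "normal" &&
      any(sc[c("dcis", "invasive")] > 0L))
    msg <- c(msg, "normal phantoms must contain zero DCIS/invasive structures")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  if (object@coverageFraction <= 0 || object@coverageFraction >= 1)
    msg <- c(msg, "coverageFraction must be in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Multi-channel MPM image stack
#'
#' A quantized 12-bit intensity stack with its physical geometry and
#' case-level metadata. Voxels are stored as an integer array indexed
#' \code{[y, x, channel, z]}; channels follow the filter order
#' 390/18, 480/40, 629/56 nm.
#'
#' @slot voxels integer array \code{[y, x, channel, z]} in
#'   \code{[0, quantizationLevels - 1]}.
#' @slot geometry a [StackGeometry-class].
#' @slot imageId,patientId character identifiers.
#' @slot group character, case-level split group (\code{"A"} or \code{"B"}).
#' @slot tissueLabel character, \code{"normal"} or \code{"cancerous"}
#'   (tissue of origin, not the per-image finding).
#'
#' @seealso [generatePhantom()], [calibrateZ()]
#' @export
setClass("MPMStack",
  representation(
    voxels = "array", geometry = "StackGeometry",
    imageId = "character", patientId = "character",
    group = "character", tissueLabel = "character"
  )
)

setValidity("MPMStack", function(object) {
  g <- object@geometry
  d <- dim(object@voxels)
  msg <- NULL
  if (length(d) != 4L)
    msg <- c(msg, "voxels must be a 4-d array [y, x, channel, z]")
  else if (!identical(as.integer(d),
                      c(g@heightPx, g@widthPx, g@nChannels, g@nPlanes)))
    msg <- c(msg, "voxel dimensions do not match geometry")
  v <- range(object@voxels)
  if (v[1] < 0) msg <- c(msg, "voxels must be non-negative")
  if (!object@group %in% c("A", "B")) msg <- c(msg, "group must be 'A' or 'B'")
  if (!object@tissueLabel %in% c("normal", "cancerous"))
    msg <- c(msg, "tissueLabel must be 'normal' or 'cancerous'")
  if (is.null(msg)) TRUE else msg
})

#' Per-pixel and per-tile ground truth for a phantom
#'
#' @slot cancerMask logical matrix \code{[y, x]}; TRUE on malignant pixels.
#' @slot structureMask integer matrix \code{[y, x]} of structure codes
#'   (0 = background; see \code{attr(, "levels")}).
#' @slot tileLabels character matrix (tiles-per-side square) with entries
#'   \code{"cancer"} / \code{"no_cancer"}.
#' @slot placements data.frame of the circular structure placements
#'   (structure, cy, cx, r) used for rendering; diagnostic metadata.
#'
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomTruth",
  representation(
    cancerMask = "matrix", structureMask = "matrix", tileLabels = "matrix",
    placements = "data.frame"
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- NULL
  if (!is.logical(object@cancerMask)) msg <- c(msg, "cancerMask must be logical")
  if (!identical(dim(object@cancerMask), dim(object@structureMask)))
    msg <- c(msg, "cancerMask and structureMask dimensions differ")
  tl <- object@tileLabels
  if (nrow(tl) != ncol(tl)) msg <- c(msg, "tileLabels must be square")
  if (!all(tl %in% c("cancer", "no_cancer")))
    msg <- c(msg, "tileLabels entries must be 'cancer' or 'no_cancer'")
  if (is.null(msg)) TRUE else msg
})

#' Tile grid convention
#'
#' Cropping convention: 128 x 128-pixel tiles on an 8 x 8 grid (64 tiles
#' per 1024 x 1024 frame), row-major, origin top-left, 0-based coordinates.
#'
#' @slot tileSidePx integer, tile side in pixels.
#' @slot tilesPerSide integer, tiles along each image side.
#'
#' @seealso [tileGrid()], [cropTiles()]
#' @export
setClass("TileGrid",
  representation(tileSidePx = "integer", tilesPerSide = "integer")
)

setValidity("TileGrid", function(object) {
  if (object@tileSidePx < 1L || object@tilesPerSide < 1L)
    "tile side and grid size must be positive" else TRUE
})

#' A set of image tiles with their manifest
#'
#' Tiles cropped from one or more images: a pixel array plus a manifest
#' data frame (one row per tile) carrying grid coordinates, blank flags,
#' truth labels and classifier scores.
#'
#' @slot pixels numeric array \code{[y, x, channel, tile]}.
#' @slot info data.frame with columns \code{image_id}, \code{grid_row},
#'   \code{grid_col}, and optionally \code{is_blank}, \code{truth_label},
#'   \code{score}, \code{split}.
#'
#' @seealso [cropTiles()]
#' @export
setClass("TileSet",
  representation(pixels = "array", info = "data.frame")
)

setValidity("TileSet", function(object) {
  d <- dim(object@pixels)
  msg <- NULL
  if (length(d) != 4L) msg <- c(msg, "pixels must be [y, x, channel, tile]")
  else if (d[4] != nrow(object@info))
    msg <- c(msg, "info must have one row per tile")
  need <- c("image_id", "grid_row", "grid_col")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have image_id, grid_row, grid_col")
  if (is.null(msg)) TRUE else msg
})

#' Blank-tile exclusion rule
#'
#' A tile is blank iff its signal-to-noise ratio against a median-filtered
#' pseudo-noiseless version falls below \code{snrThreshold} AND its mean
#' brightness (on the [0, 1] full-scale axis) falls below
#' \code{brightnessThreshold}.
#'
#' @slot snrThreshold numeric; threshold on the SNR (dB by default).
#' @slot brightnessThreshold numeric in (0, 1).
#' @slot medianWindow integer, odd median-filter window side.
#' @slot snrMode character, \code{"db"} or \code{"ratio"}.
#'
#' @seealso [blankRule()], [isBlank()]
#' @export
setClass("BlankRule",
  representation(
    snrThreshold = "numeric", brightnessThreshold = "numeric",
    medianWindow = "integer", snrMode = "character"
  )
)

setValidity("BlankRule", function(object) {
  msg <- NULL
  if (object@snrThreshold <= 0) msg <- c(msg, "snrThreshold must be positive")
  if (object@brightnessThreshold <= 0)
    msg <- c(msg, "brightnessThreshold must be positive")
  if (object@medianWindow %% 2L != 1L || object@medianWindow < 1L)
    msg <- c(msg, "medianWindow must be odd and positive")
  if (!object@snrMode %in% c("db", "ratio"))
    msg <- c(msg, "snrMode must be 'db' or 'ratio'")
  if (is.null(msg)) TRUE else msg
})

#' Training configuration for the tile classifier
#'
#' The reference protocol is Adam with 100 epochs, learning rate 0.020 and
#' batch size 128; the architecture is a small convolutional network.
#'
#' @slot architecture character, currently \code{"small_cnn"}.
#' @slot epochs,batchSize integer.
#' @slot learningRate numeric.
#' @slot optimizer character, currently \code{"adam"}.
#' @slot classWeighting character, \code{"none"} or \code{"balanced"}.
#' @slot seed integer RNG seed for initialization and batching.
#'
#' @seealso [trainConfig()], [trainTileClassifier()]
#' @export
setClass("TrainConfig",
  representation(
    architecture = "character", epochs = "integer", learningRate = "numeric",
    batchSize = "integer", optimizer = "character",
    classWeighting = "character", seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- NULL
  if (!object@architecture %in% c("small_cnn"))
    msg <- c(msg, "architecture must be 'small_cnn'")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@optimizer %in% "adam") msg <- c(msg, "optimizer must be 'adam'")
  if (!object@classWeighting %in% c("none", "balanced"))
    msg <- c(msg, "classWeighting must be 'none' or 'balanced'")
  if (is.null(msg)) TRUE else msg
})

#' Trained tile classifier
#'
#' @slot architecture character architecture id.
#' @slot params list of trained parameter matrices.
#' @slot config the [TrainConfig-class] used for training.
#' @slot history data.frame of per-epoch training loss and validation metric.
#' @slot validationScore numeric, metric of the selected epoch.
#' @slot inputSide integer, spatial side of the network input.
#' @slot dataFingerprint character, digest of the training data shape.
#'
#' @seealso [trainTileClassifier()], [predictTiles()]
#' @export
setClass("TileClassifierModel",
  representation(
    architecture = "character", params = "list", config = "TrainConfig",
    history = "data.frame", validationScore = "numeric",
    inputSide = "integer", dataFingerprint = "character"
  )
)

#' Tile-level confusion matrix
#'
#' TP/FP/FN/TN tile counts; the source of accuracy, precision, recall and
#' F-measure.
#'
#' @slot tp,fp,fn,tn numeric counts.
#'
#' @seealso [confusionMatrix()], [matrixMetrics()], [tileOutcomes()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric")
)

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
    "counts must be non-negative" else TRUE
})

#' Image-level verdict configuration
#'
#' An image is called malignant iff its malignant probability (positive
#' tiles / 64) reaches the threshold; the operating point of the clinical
#' ROC analysis is 0.0625 (4 of 64 tiles).
#'
#' @slot threshold numeric in (0, 1).
#' @slot strict logical; if TRUE the decision uses a strict \code{>}.
#'
#' @seealso [verdictConfig()], [imageVerdicts()]
#' @export
setClass("VerdictConfig",
  representation(threshold = "numeric", strict = "logical")
)

setValidity("VerdictConfig", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    "threshold must be in (0, 1)" else TRUE
})

#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations with a single global seed so a full run
#' (simulate, preprocess, blank-filter, train, predict, evaluate) is
#' reproducible from one object.
#'
#' @slot phantomGeometry a [StackGeometry-class] for generated cohorts.
#' @slot spectral a [SpectralConfig-class].
#' @slot blankRule a [BlankRule-class].
#' @slot trainConfig a [TrainConfig-class].
#' @slot verdictConfig a [VerdictConfig-class].
#' @slot nPatients,imagesPerPatient integer cohort layout.
#' @slot cancerFraction numeric, fraction of patients providing cancer tissue.
#' @slot seed integer global seed.
#'
#' @seealso [pipelineConfig()], [runFull()]
#' @export
setClass("PipelineConfig",
  representation(
    phantomGeometry = "StackGeometry", spectral = "SpectralConfig",
    blankRule = "BlankRule", trainConfig = "TrainConfig",
    verdictConfig = "VerdictConfig",
    nPatients = "integer", imagesPerPatient = "integer",
    cancerFraction = "numeric", seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- NULL
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  if (object@imagesPerPatient < 1L)
    msg <- c(msg, "imagesPerPatient must be >= 1")
  if (object@cancerFraction < 0 || object@cancerFraction > 1)
    msg <- c(msg, "cancerFraction must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
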