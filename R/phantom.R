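#' Stack geometry constructor
#'
#' Defaults reproduce the reference acquisition: 1024 x 1024 pixels at
#' 0.50 um/pixel, 3 um z-steps, retained depth <= 30 um (so at most 11
#' calibrated planes), three channels. Cohort phantoms are generated as
#' single-plane stacks by default, each plane standing for one image file.
#'
#' @param widthPx,heightPx frame size in pixels.
#' @param pixelSizeUm lateral pixel size (um).
#' @param zStepUm axial step (um).
#' @param maxDepthUm deepest retained calibrated depth (um).
#' @param nChannels number of detection channels.
#' @param nPlanes number of acquired planes.
#' @return a [StackGeometry-class].
#' @export
stackGeometry <- function(widthPx = 1024L, heightPx = 1024L,
                          pixelSizeUm = 0.50, zStepUm = 3.0,
                          maxDepthUm = 30.0, nChannels = 3L,
                          nPlanes = 1L) {
  new("StackGeometry",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      pixelSizeUm = as.numeric(pixelSizeUm), zStepUm = as.numeric(zStepUm),
      maxDepthUm = as.numeric(maxDepthUm), nChannels = as.integer(nChannels),
      nPlanes = as.integer(nPlanes))
}

#' Phantom specification constructor
#'
#' @param geometry a [StackGeometry-class].
#' @param tissueClass \code{"normal"}, \code{"cancer"} or
#'   \code{"cancer_with_normal_regions"}.
#' @param ducts,adipose,collagen,dcis,invasive,immune structure counts.
#' @param noiseSd Gaussian read-noise SD in gray levels.
#' @param backgroundLevel background offset in gray levels.
#' @param coverageFraction cancer-mask coverage above which a tile is
#'   labeled \code{cancer} (default 5\%).
#' @param surfacePlanes background-only planes above the tissue surface.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(geometry = stackGeometry(),
                        tissueClass = c("normal", "cancer",
                                        "cancer_with_normal_regions"),
                        ducts = 3L, adipose = 3L, collagen = 5L,
                        dcis = 0L, invasive = 0L, immune = 1L,
                        noiseSd = 12, backgroundLevel = 80,
                        coverageFraction = 0.05, surfacePlanes = 0L,
                        seed = 1L) {
  tissueClass <- match.arg(tissueClass)
  counts <- c(ducts = as.integer(ducts), adipose = as.integer(adipose),
              collagen = as.integer(collagen), dcis = as.integer(dcis),
              invasive = as.integer(invasive), immune = as.integer(immune))
  new("PhantomSpec", geometry = geometry, tissueClass = tissueClass,
      structureCounts = counts, noiseSd = as.numeric(noiseSd),
      backgroundLevel = as.numeric(backgroundLevel),
      coverageFraction = as.numeric(coverageFraction),
      surfacePlanes = as.integer(surfacePlanes), seed = as.integer(seed))
}

#' Generate one synthetic MPM stack with ground truth
#'
#' Renders the requested structures as geometric primitives (ducts as
#' epithelial annuli with signal-void nuclei and, for normal ducts, bright
#' edge puncta; DCIS as ducts filled with enlarged-nucleus cancer texture
#' and no puncta; invasive nests as irregular blobs; adipose cells as large
#' circles; collagen as curvilinear SHG-emitting fibers; immune infiltrates
#' as scattered small bright cells), maps each structure's emission spectrum
#' through the band-pass channels, adds Gaussian read noise, and quantizes
#' to the 12-bit gray scale. Deterministic given \code{spec@seed}.
#'
#' @param spec a [PhantomSpec-class].
#' @param config a [SpectralConfig-class].
#' @param filters a [ChannelFilterSet-class].
#' @param imageId,patientId,group,tissueLabel stack metadata.
#' @return a list with elements \code{stack} ([MPMStack-class]) and
#'   \code{truth} ([PhantomTruth-class]).
#' @examples
#' spec <- phantomSpec(stackGeometry(256L, 256L), ducts = 1L, adipose = 1L,
#'                     collagen = 1L, immune = 0L, seed = 7L)
#' ph <- generatePhantom(spec)
#' dim(ph$stack@voxels)   # 256 256 3 1
#' @export
generatePhantom <- function(spec, config = spectralConfig(),
                            filters = channelFilters(),
                            imageId = "img001", patientId = "P01",
                            group = "A",
                            tissueLabel = if (spec@tissueClass == "normal")
                              "normal" else "cancerous") {
  stopifnot(is(spec, "PhantomSpec"))
  g <- spec@geometry
  withSeed(spec@seed, {
    env <- newScene(g@heightPx, g@widthPx, g@nChannels,
                    rscale = min(1, g@heightPx / 1024))
    sigs <- sceneSignatures(config, filters)
    sc <- spec@structureCounts
    ## larger structures first so placement has room
    for (i in seq_len(sc[["adipose"]]))  renderAdipose(env, sigs)
    for (i in seq_len(sc[["dcis"]]))     renderDuct(env, sigs, cancerous = TRUE)
    for (i in seq_len(sc[["invasive"]])) renderInvasiveNest(env, sigs)
    for (i in seq_len(sc[["ducts"]]))    renderDuct(env, sigs, cancerous = FALSE)
    for (i in seq_len(sc[["collagen"]])) renderCollagenFiber(env, sigs)
    for (i in seq_len(sc[["immune"]]))   renderImmuneInfiltrate(env, sigs)
    scene <- sceneCompose(env)
    scene$ch <- .blurPSF(scene$ch)

    nP <- g@nPlanes
    vox <- array(0L, c(g@heightPx, g@widthPx, g@nChannels, nP))
    for (p in seq_len(nP)) {
      pz <- p - 1L
      if (pz < spec@surfacePlanes) {
        plane <- array(spec@backgroundLevel,
                       c(g@heightPx, g@widthPx, g@nChannels))
      } else {
        depth <- (pz - spec@surfacePlanes) * g@zStepUm
        atten <- exp(-depth / 60)   # mild signal loss with depth
        plane <- spec@backgroundLevel + scene$ch * atten
      }
      if (spec@noiseSd > 0)
        plane <- plane + stats::rnorm(length(plane), 0, spec@noiseSd)
      vox[, , , p] <- quantizeIntensity(pmax(plane, 0), config)
    }

    tileSide <- 128L
    if (g@heightPx %% tileSide != 0L || g@widthPx %% tileSide != 0L)
      tileSide <- as.integer(gcd2(g@heightPx, g@widthPx))
    truth <- new("PhantomTruth",
                 cancerMask = scene$cmask,
                 structureMask = structure(scene$smask,
                                           levels = .structureCodes),
                 tileLabels = tileLabelsFromMask(scene$cmask, tileSide,
                                                 spec@coverageFraction),
                 placements = env$placements)
    stack <- new("MPMStack", voxels = vox, geometry = g,
                 imageId = imageId, patientId = patientId, group = group,
                 tissueLabel = tissueLabel)
    list(stack = stack, truth = truth)
  })
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Lay out a synthetic patient cohort
#'
#' Plans a reproducible cohort: patients are assigned a tissue type
#' (\code{cancerFraction} of them provide cancerous tissue), images per
#' patient get deterministic per-image seeds derived from the cohort seed,
#' and patients are split case-disjointly into groups A and B. Mirroring
#' the clinical data, a fraction of cancer-tissue images carries no
#' malignant findings (zero cancer structures).
#'
#' Images are rendered lazily by [cohortImage()] so arbitrarily large
#' cohorts never need to reside in memory at once.
#'
#' @param nPatients number of patients (>= 2).
#' @param imagesPerPatient image files per patient.
#' @param cancerFraction fraction of patients providing cancerous tissue.
#' @param seed cohort seed.
#' @param geometry a [StackGeometry-class] for every image.
#' @param fracNoMalignant fraction of cancer-tissue images rendered without
#'   malignant findings.
#' @param noiseSd,backgroundLevel acquisition noise model (gray levels).
#' @return a list of class \code{"PhantomCohort"} with elements
#'   \code{manifest} (data.frame: image_id, patient_id, group, tissue_label,
#'   has_malignant, seed), \code{geometry} and \code{params}.
#' @examples
#' coh <- generateCohort(4L, 2L, 0.5, seed = 1L,
#'                       geometry = stackGeometry(256L, 256L))
#' nrow(coh$manifest)   # 8
#' @export
generateCohort <- function(nPatients, imagesPerPatient,
                           cancerFraction = 0.5, seed = 1L,
                           geometry = stackGeometry(),
                           fracNoMalignant = 0.10,
                           noiseSd = 12, backgroundLevel = 80) {
  if (cancerFraction < 0 || cancerFraction > 1)
    stop("cancerFraction must be in [0, 1]")
  if (nPatients < 2L)
    stop("nPatients must be >= 2 to form patient-disjoint groups")
  nCancer <- round(cancerFraction * nPatients)
  tissue <- c(rep("cancerous", nCancer), rep("normal", nPatients - nCancer))
  ## alternate within tissue type so both groups see both classes
  grp <- character(nPatients)
  grp[tissue == "cancerous"] <- rep_len(c("A", "B"), nCancer)
  grp[tissue == "normal"] <- rep_len(c("A", "B"), nPatients - nCancer)
  pid <- sprintf("P%02d", seq_len(nPatients))

  rows <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nPatients), function(i) {
      nm <- imagesPerPatient
      hasMal <- if (tissue[i] == "cancerous")
        stats::runif(nm) >= fracNoMalignant else rep(FALSE, nm)
      data.frame(
        image_id = sprintf("%s_img%03d", pid[i], seq_len(nm)),
        patient_id = pid[i], group = grp[i], tissue_label = tissue[i],
        has_malignant = hasMal,
        seed = vapply(seq_len(nm), function(j)
          deriveSeed(seed, (i - 1L) * nm + j), integer(1)),
        stringsAsFactors = FALSE)
    }))
  })
  structure(list(manifest = rows, geometry = geometry,
                 params = list(seed = as.integer(seed),
                               noiseSd = noiseSd,
                               backgroundLevel = backgroundLevel,
                               fracNoMalignant = fracNoMalignant)),
            class = "PhantomCohort")
}

#' Render one cohort image
#'
#' @param cohort a cohort from [generateCohort()].
#' @param i row index into \code{cohort$manifest}.
#' @param config,filters spectral model (defaults as in [generatePhantom()]).
#' @return a list with \code{stack} and \code{truth}, as [generatePhantom()].
#' @export
cohortImage <- function(cohort, i, config = spectralConfig(),
                        filters = channelFilters()) {
  row <- cohort$manifest[i, ]
  cancerImage <- isTRUE(row$has_malignant)
  tc <- if (row$tissue_label == "normal") "normal"
        else if (cancerImage) "cancer" else "cancer_with_normal_regions"
  g <- cohort$geometry
  ## structure counts are laid out for the 1024 x 1024 reference frame and
  ## scaled with frame area for smaller geometries
  f <- (as.numeric(g@heightPx) * g@widthPx) / 1024^2
  sc <- function(n) max(1L, as.integer(round(n * f)))
  spec <- phantomSpec(
    geometry = g, tissueClass = tc,
    ducts = sc(if (cancerImage) 1L else 3L),
    adipose = sc(if (cancerImage) 1L else 3L),
    collagen = sc(if (cancerImage) 4L else 5L),
    dcis = if (cancerImage) sc(2L) else 0L,
    invasive = if (cancerImage) sc(2L) else 0L,
    immune = sc(if (cancerImage) 3L else 1L),
    noiseSd = cohort$params$noiseSd,
    backgroundLevel = cohort$params$backgroundLevel,
    seed = row$seed)
  generatePhantom(spec, config, filters,
                  imageId = row$image_id, patientId = row$patient_id,
                  group = row$group, tissueLabel = row$tissue_label)
}

#' Write / read an MPM stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered plane-major, channel-minor (plane 1 channels
#' 390/480/629, then plane 2, ...). Intensities are stored as 16-bit
#' samples holding the 12-bit gray levels; geometry and labels go to
#' \code{<path>.json}.
#'
#' @param stack an [MPMStack-class].
#' @param path TIFF output path.
#' @return \code{writeStackTIFF}: the path, invisibly.
#'   \code{readStackTIFF}: the reconstructed [MPMStack-class].
#' @export
writeStackTIFF <- function(stack, path) {
  g <- stack@geometry
  pages <- list()
  for (p in seq_len(g@nPlanes))
    for (k in seq_len(g@nChannels))
      pages[[length(pages) + 1L]] <- stack@voxels[, , k, p] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(widthPx = g@widthPx, heightPx = g@heightPx,
               pixelSizeUm = g@pixelSizeUm, zStepUm = g@zStepUm,
               maxDepthUm = g@maxDepthUm, nChannels = g@nChannels,
               nPlanes = g@nPlanes, imageId = stack@imageId,
               patientId = stack@patientId, group = stack@group,
               tissueLabel = stack@tissueLabel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStackTIFF
#' @export
readStackTIFF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  g <- stackGeometry(meta$widthPx, meta$heightPx, meta$pixelSizeUm,
                     meta$zStepUm, meta$maxDepthUm, meta$nChannels,
                     meta$nPlanes)
  vox <- array(0L, c(g@heightPx, g@widthPx, g@nChannels, g@nPlanes))
  i <- 1L
  for (p in seq_len(g@nPlanes))
    for (k in seq_len(g@nChannels)) {
      vox[, , k, p] <- as.integer(round(pages[[i]] * 65535))
      i <- i + 1L
    }
  new("MPMStack", voxels = vox, geometry = g, imageId = meta$imageId,
      patientId = meta$patientId, group = meta$group,
      tissueLabel = meta$tissueLabel)
}
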