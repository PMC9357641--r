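#' Spectral configuration constructor
#'
#' Builds a [SpectralConfig-class]. Defaults reproduce the reference
#' acquisition: 780 nm excitation, a 380--630 nm detector window in 25 bins
#' (10 nm each), 4096 gray levels (12 bits).
#'
#' @param excitationWavelength excitation wavelength in nm.
#' @param detectorRangeLow,detectorRangeHigh detector window bounds in nm.
#' @param nBins number of detector bins.
#' @param quantizationLevels gray levels (power of two).
#' @param fullScale intensity mapped to the top gray level; a free parameter
#'   of the phantom model, since detector gain is instrument-specific.
#'
#' @return a \code{SpectralConfig}.
#' @examples
#' cfg <- spectralConfig()
#' binWidth(cfg)        # 10 nm
#' shgWavelength(cfg)   # 390 nm
#' @export
spectralConfig <- function(excitationWavelength = 780,
                           detectorRangeLow = 380,
                           detectorRangeHigh = 630,
                           nBins = 25L,
                           quantizationLevels = 4096L,
                           fullScale = 4095) {
  new("SpectralConfig",
      excitationWavelength = as.numeric(excitationWavelength),
      detectorRangeLow = as.numeric(detectorRangeLow),
      detectorRangeHigh = as.numeric(detectorRangeHigh),
      nBins = as.integer(nBins),
      quantizationLevels = as.integer(quantizationLevels),
      fullScale = as.numeric(fullScale))
}

#' Detector bin width and bin centers
#'
#' @param config a [SpectralConfig-class].
#' @return \code{binWidth}: the width of one detector bin in nm (10 for the
#'   reference configuration); \code{binCenters}: the nm positions of the
#'   bin centers (385, 395, ..., 625 for the reference configuration).
#' @export
binWidth <- function(config) {
  (config@detectorRangeHigh - config@detectorRangeLow) / config@nBins
}

#' @rdname binWidth
#' @export
binCenters <- function(config) {
  w <- binWidth(config)
  config@detectorRangeLow + w * (seq_len(config@nBins) - 0.5)
}

#' Second-harmonic-generation wavelength
#'
#' SHG from non-centrosymmetric structures (fibrillar collagen) emits at
#' exactly half the excitation wavelength: 390 nm under 780 nm excitation.
#'
#' @param config a [SpectralConfig-class].
#' @return the SHG emission wavelength in nm.
#' @examples
#' shgWavelength(spectralConfig())           # 390
#' shgWavelength(spectralConfig(800, 380, 630))  # undefined here: 800/2 = 400
#' @export
shgWavelength <- function(config) {
  stopifnot(is(config, "SpectralConfig"))
  if (config@excitationWavelength <= 0)
    stop("invalid spectral config: non-positive excitation wavelength")
  config@excitationWavelength / 2
}

## Fixed emission peaks of the tissue components (nm). The three
## autofluorescence peaks (480/510/570) and the SHG line at half the
## excitation wavelength are the observable signatures the channel filters
## were chosen for.
.fluorophorePeaks <- c(
  epithelial_autofluorescence = 480,
  adipose                     = 480,
  stromal_fiber               = 480,
  duct_edge_puncta            = 510,
  immune_cell                 = 570,
  shg_collagen                = 390
)

## FWHM defaults: broad autofluorescence bands vs a narrow SHG line.
.fluorophoreFWHM <- c(
  epithelial_autofluorescence = 80,
  adipose                     = 80,
  stromal_fiber               = 80,
  duct_edge_puncta            = 80,
  immune_cell                 = 80,
  shg_collagen                = 12
)

#' Construct a tissue fluorophore
#'
#' Returns a [Fluorophore-class] for one of the six tissue components, with
#' the emission peak fixed by component identity (480 nm epithelial /
#' adipose / stromal autofluorescence, 510 nm duct-edge puncta, 570 nm
#' immune cells, SHG at half the excitation wavelength) and a default FWHM
#' of 80 nm for autofluorescence bands versus 12 nm for the SHG line.
#'
#' @param name one of \code{"epithelial_autofluorescence"}, \code{"adipose"},
#'   \code{"stromal_fiber"}, \code{"duct_edge_puncta"}, \code{"immune_cell"},
#'   \code{"shg_collagen"}.
#' @param relativeAmplitude dimensionless amplitude.
#' @param bandwidthFWHM FWHM in nm; default per component.
#'
#' @return a \code{Fluorophore}.
#' @export
fluorophore <- function(name, relativeAmplitude = 1,
                        bandwidthFWHM = NULL) {
  name <- match.arg(name, names(.fluorophorePeaks))
  if (is.null(bandwidthFWHM)) bandwidthFWHM <- .fluorophoreFWHM[[name]]
  new("Fluorophore", name = name,
      peakWavelength = .fluorophorePeaks[[name]],
      bandwidthFWHM = as.numeric(bandwidthFWHM),
      relativeAmplitude = as.numeric(relativeAmplitude))
}

#' Fluorophore panel as a data frame
#'
#' The full component table in CSV-friendly form (columns \code{name},
#' \code{peak_nm}, \code{fwhm_nm}, \code{amplitude}).
#'
#' @param amplitudes optional named numeric vector of amplitudes.
#' @return a data.frame, one row per tissue component.
#' @seealso [readFluorophorePanel()], [writeFluorophorePanel()]
#' @export
fluorophorePanel <- function(amplitudes = NULL) {
  nm <- names(.fluorophorePeaks)
  amp <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(amplitudes)) amp[names(amplitudes)] <- amplitudes
  data.frame(name = nm,
             peak_nm = unname(.fluorophorePeaks[nm]),
             fwhm_nm = unname(.fluorophoreFWHM[nm]),
             amplitude = unname(amp[nm]),
             stringsAsFactors = FALSE)
}

#' Read or write a fluorophore panel CSV
#'
#' @param path CSV path.
#' @param panel a data.frame as returned by [fluorophorePanel()].
#' @return \code{readFluorophorePanel} returns the panel data.frame.
#' @export
readFluorophorePanel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "peak_nm", "fwhm_nm", "amplitude")
  if (!all(need %in% names(p)))
    stop("fluorophore panel CSV must have columns: ",
         paste(need, collapse = ", "))
  p
}

#' @rdname readFluorophorePanel
#' @export
writeFluorophorePanel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Binned emission spectrum of a fluorophore
#'
#' Integrates a Gaussian line shape (peak wavelength, FWHM, amplitude) over
#' each detector bin. Peaks outside the detector window yield truncated
#' spectra; zero amplitude yields an all-zero spectrum.
#'
#' @param fluor a [Fluorophore-class].
#' @param config a [SpectralConfig-class].
#' @return an [EmissionSpectrum-class] on the detector bins.
#' @examples
#' sp <- emissionSpectrum(fluorophore("epithelial_autofluorescence"))
#' # the argmax bin covers the 480 nm peak:
#' abs(wavelengths(sp)[which.max(intensities(sp))] - 480) <= 5
#' @export
emissionSpectrum <- function(fluor, config = spectralConfig()) {
  stopifnot(is(fluor, "Fluorophore"), is(config, "SpectralConfig"))
  w <- binWidth(config)
  edges <- config@detectorRangeLow + w * (0:config@nBins)
  sigma <- fluor@bandwidthFWHM / (2 * sqrt(2 * log(2)))
  ## integral of the unit-peak Gaussian over each bin, scaled by amplitude
  cdf <- stats::pnorm(edges, mean = fluor@peakWavelength, sd = sigma)
  intens <- fluor@relativeAmplitude * diff(cdf) * sigma * sqrt(2 * pi)
  new("EmissionSpectrum",
      binCenters = binCenters(config), intensities = intens)
}

#' Accessors for EmissionSpectrum
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @return \code{intensities}: the per-bin relative intensities;
#'   \code{wavelengths}: the bin centers (nm).
#' @export
intensities <- function(spectrum) spectrum@intensities

#' @rdname intensities
#' @export
wavelengths <- function(spectrum) spectrum@binCenters

#' Write a spectrum as CSV
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param path CSV path.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(bin_center_nm = spectrum@binCenters,
               intensity = spectrum@intensities),
    path, row.names = FALSE)
  invisible(path)
}

#' Reference band-pass filter set
#'
#' @param centers,widths filter centers and full widths in nm; defaults are
#'   the 390/18, 480/40 and 629/56 nm filters.
#' @return a [ChannelFilterSet-class].
#' @export
channelFilters <- function(centers = c(390, 480, 629),
                           widths = c(18, 40, 56)) {
  new("ChannelFilterSet",
      filters = cbind(center = as.numeric(centers),
                      width = as.numeric(widths)))
}

#' Channel response of a spectrum through the filter set
#'
#' Each channel receives the spectrum intensity falling inside its
#' pass-band \eqn{[center - width/2, center + width/2]}; detector bins that
#' partially overlap a pass-band contribute in proportion to the overlap
#' fraction.
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param filters a [ChannelFilterSet-class].
#' @return a non-negative numeric vector, one entry per channel.
#' @export
channelResponse <- function(spectrum, filters = channelFilters()) {
  stopifnot(is(spectrum, "EmissionSpectrum"), is(filters, "ChannelFilterSet"))
  ctr <- spectrum@binCenters
  w <- if (length(ctr) > 1) ctr[2] - ctr[1] else
    stop("spectrum must have >= 2 bins")
  lo <- ctr - w / 2
  hi <- ctr + w / 2
  f <- filters@filters
  vapply(seq_len(nrow(f)), function(k) {
    plo <- f[k, "center"] - f[k, "width"] / 2
    phi <- f[k, "center"] + f[k, "width"] / 2
    overlap <- pmax(0, pmin(hi, phi) - pmax(lo, plo)) / w
    sum(spectrum@intensities * overlap)
  }, numeric(1))
}

#' Quantize an intensity to the detector gray scale
#'
#' Maps a non-negative physical intensity to an integer gray level:
#' \code{round(clip(x / fullScale, 0, 1) * (levels - 1))}, i.e. 0--4095 for
#' the 12-bit reference configuration, saturating at full scale.
#'
#' @param intensity non-negative numeric (vector/array allowed).
#' @param config a [SpectralConfig-class]; supplies \code{fullScale} and the
#'   number of levels.
#' @return integer gray levels with the shape of \code{intensity}.
#' @export
quantizeIntensity <- function(intensity, config = spectralConfig()) {
  if (any(intensity < 0))
    stop("intensity must be non-negative")
  q <- config@quantizationLevels - 1L
  out <- as.integer(round(pmin(pmax(intensity / config@fullScale, 0), 1) * q))
  if (!is.null(dim(intensity))) dim(out) <- dim(intensity)
  out
}
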