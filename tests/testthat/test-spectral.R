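test_that("SHG emits at exactly half the excitation wavelength", {
  expect_equal(shgWavelength(spectralConfig()), 390)
  expect_equal(shgWavelength(spectralConfig(excitationWavelength = 800)), 400)
  expect_equal(shgWavelength(spectralConfig(excitationWavelength = 1000)), 500)
  expect_error(spectralConfig(excitationWavelength = -5), "positive")
})

test_that("detector binning matches the 380-630 nm / 25-bin geometry", {
  cfg <- spectralConfig()
  expect_identical(binWidth(cfg), 10)
  ctr <- binCenters(cfg)
  expect_length(ctr, 25L)
  expect_equal(ctr[1], 385)
  expect_equal(unique(diff(ctr)), 10)
})

test_that("emission spectra preserve the configured peak bin", {
  cfg <- spectralConfig()
  panel <- fluorophorePanel()
  for (nm in panel$name) {
    sp <- emissionSpectrum(fluorophore(nm), cfg)
    pk <- wavelengths(sp)[which.max(intensities(sp))]
    expect_lte(abs(pk - panel$peak_nm[panel$name == nm]), binWidth(cfg) / 2)
  }
})

test_that("SHG line is sharp: > 90% of intensity within one bin of the peak", {
  sp <- emissionSpectrum(fluorophore("shg_collagen"))
  i <- which.max(intensities(sp))
  frac <- sum(intensities(sp)[max(1, i - 1):min(25, i + 1)]) /
    sum(intensities(sp))
  expect_gt(frac, 0.90)
})

test_that("zero-amplitude fluorophores give all-zero spectra and responses", {
  sp <- emissionSpectrum(fluorophore("immune_cell", relativeAmplitude = 0))
  expect_true(all(intensities(sp) == 0))
  expect_equal(channelResponse(sp), c(0, 0, 0))
})

test_that("channel responses agree with a fine-grid integration oracle", {
  cfg <- spectralConfig()
  panel <- fluorophorePanel()
  for (nm in panel$name) {
    row <- panel[panel$name == nm, ]
    got <- channelResponse(emissionSpectrum(fluorophore(nm), cfg))
    want <- gaussChannelOracle(row$peak_nm, row$fwhm_nm)
    ## same dominant channel
    expect_identical(which.max(got), which.max(want), label = nm)
    ## proportions agree to a few percent despite 10 nm binning
    expect_lt(max(abs(got / sum(got) - want / sum(want))), 0.05)
  }
  shg <- channelResponse(emissionSpectrum(fluorophore("shg_collagen"), cfg))
  expect_gt(shg[1], 10 * max(shg[2:3]))
  imm <- channelResponse(emissionSpectrum(fluorophore("immune_cell"), cfg))
  expect_gt(imm[3], imm[2])
})

test_that("distinct emission peaks produce distinct channel signatures", {
  cfg <- spectralConfig()
  panel <- fluorophorePanel()
  resp <- lapply(panel$name, function(nm)
    channelResponse(emissionSpectrum(fluorophore(nm), cfg)))
  names(resp) <- panel$name
  for (a in panel$name) for (b in panel$name) {
    if (panel$peak_nm[panel$name == a] == panel$peak_nm[panel$name == b])
      next
    cossim <- sum(resp[[a]] * resp[[b]]) /
      sqrt(sum(resp[[a]]^2) * sum(resp[[b]]^2))
    expect_lt(cossim, 1 - 1e-6)
  }
})

test_that("quantization clips, saturates and is monotone", {
  cfg <- spectralConfig()
  expect_identical(quantizeIntensity(4095, cfg), 4095L)
  expect_identical(quantizeIntensity(0, cfg), 0L)
  expect_identical(quantizeIntensity(2 * 4095, cfg), 4095L)
  expect_error(quantizeIntensity(-1, cfg), "non-negative")
  x <- sort(runif(100, 0, 9000))
  q <- quantizeIntensity(x, cfg)
  expect_true(all(diff(q) >= 0L))
  expect_true(all(q >= 0L & q <= 4095L))
})

test_that("fluorophore panel round-trips through CSV", {
  p <- fluorophorePanel(c(shg_collagen = 2))
  f <- tempfile(fileext = ".csv")
  writeFluorophorePanel(p, f)
  expect_equal(readFluorophorePanel(f), p)
  unlink(f)
})
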