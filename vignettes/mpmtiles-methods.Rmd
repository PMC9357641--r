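---
title: "Tile-based classification of label-free multiphoton breast-tissue images"
author: "mpmtiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based classification of label-free multiphoton breast-tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmtiles)
```

## The problem

Label-free multiphoton excitation microscopy (MPM) images fresh breast
tissue without fixation or staining: under near-infrared femtosecond-pulse
excitation at 780 nm, the tissue's intrinsic fluorophores emit with three
major peaks — broad autofluorescence at 480 nm (epithelium, adipose cells,
stroma) and 510 nm (dot-like puncta along normal duct edges) and 570 nm
(immune cells) — while fibrillar collagen produces second-harmonic
generation (SHG) at exactly half the excitation wavelength, a sharp line at
390 nm. Detected through 390/18, 480/40 and 629/56 nm band-pass filters,
these signals render duct morphology, nuclei (as signal voids), collagen
architecture and cellular infiltrates well enough that malignant lesions
can be recognized.

`mpmtiles` implements the downstream analysis as a reusable, testable
pipeline: each 1024 × 1024-pixel acquisition (0.50 µm/pixel, 12-bit,
3 channels) is standardized, cropped into 64 tiles of 128 px (64 µm),
blank tiles are excluded by a signal-to-noise rule, a trainable
convolutional classifier scores each remaining tile for the presence of
cancer cells, and per-image results are aggregated into a *malignant
probability* — the fraction of an image's 64 tiles called positive — which
is thresholded at 0.0625 (4 tiles) for the image-level malignant /
nonmalignant call. Evaluation covers the tile-level confusion matrix
(accuracy, precision, recall, F-measure), image-level sensitivity and
specificity, the ROC curve and its trapezoid AUC, Mann–Whitney U
comparisons, and Cohen's kappa for rater agreement.

Because the clinical images are not public, the package ships a synthetic
phantom generator that emulates the acquisition geometry and the tissue
structures with per-pixel ground truth, so every stage — and the pipeline
end to end — is exercised by data whose answer is known by construction.

## The spectral model

Emission lines are modeled as Gaussians integrated over the 25 detector
bins spanning 380–630 nm (10 nm each). Peak positions are fixed by
component identity (480/510/570 nm, SHG at `excitation / 2`); line widths
and amplitudes are *free phantom parameters*, not measured facts: the
sources report peak positions and the qualitative contrast between the
"sharp and narrow" SHG line and the broad autofluorescence bands, so the
defaults (FWHM 80 nm for autofluorescence, 12 nm for SHG) were chosen once
to reproduce that contrast. Channel responses are overlap-weighted sums of
bin intensities inside each filter pass-band; a fine-grid numerical
integration serves as the oracle for this computation in the test suite.

```{r spectral}
cfg <- spectralConfig()
shgWavelength(cfg)
round(channelResponse(emissionSpectrum(fluorophore("shg_collagen"), cfg)), 2)
```

Quantization maps non-negative intensities to the 12-bit gray scale by
`round(clip(x / fullScale) * 4095)`; the full-scale reference is a phantom
parameter because detector gain is instrument-specific.

## The phantom generator

`generatePhantom()` renders geometric stand-ins for the structures the
imaging distinguishes:

* **normal ducts** — epithelial annuli (radius 70–110 px) around a dark
  lumen, with small (3–4.5 px) signal-void nuclei and bright 510 nm
  puncta dotted along the outer edge;
* **DCIS** — ducts filled with high-variance "irregular proliferation"
  texture and enlarged (6–10 px) nuclei, without edge puncta;
* **invasive nests** — irregular angularly-modulated blobs of the same
  cancer texture, without luminal formation;
* **adipose cells** — large circles with a bright membrane and a
  moderately autofluorescent interior;
* **collagen** — curvilinear random-walk fibers carrying the SHG
  signature; and
* **immune infiltrates** — scattered small bright 570 nm cells.

Each structure's 3-channel signature is its emission spectrum passed
through the filter model. Textures are Gaussian amplitude fields sampled
on a coarse grid and bilinearly interpolated, boundaries ramp linearly
over ~2 px, and the composed scene receives a light binomial blur — three
choices that emulate the optical point-spread function and matter for the
blank rule (below): median filters preserve smooth ramps, so tissue does
not masquerade as noise. Gaussian read noise (SD 12 gray levels) is added
on a background offset of 80 gray levels before 12-bit quantization.
These acquisition-noise defaults are fixed study conditions of the
synthetic cohorts, not tuning knobs.

Ground truth is constructed, not annotated: the cancer mask is the union
of DCIS/invasive footprints, and a tile is labeled `cancer` when more than
5 % of its pixels are cancer-mask pixels — a small positive fraction,
since the motivating use case is cancer occupying only part of a captured
image. `generateCohort()` plans patient cohorts with case-disjoint A/B
groups, and mirrors the clinical structure in which some images from
cancerous tissue contain no malignant findings (10 % by default); such
files count as *normal* at image level, matching how the published
image-level denominators are composed. Structure radii are specified for
the 1024 px reference frame and scaled down proportionally for smaller
test frames so unit tests can run on 256–512 px images.

What the phantom does **not** emulate: real histological texture,
3-D continuity across z beyond a simple exponential attenuation,
mucinous/micropapillary subtypes, depth-dependent scattering, or
photobleaching. Passing end-to-end tests therefore demonstrates that the
pipeline's machinery is correct and recovers planted signal under the
stated noise model — not that the classifier would reach clinical
performance on patient images.

## Preprocessing

`calibrateZ()` defines z = 0 as the first plane where the fraction of
pixels above a noise floor (`background + 2 × noise SD`, both estimated
robustly from the dimmest plane when not supplied) reaches a coverage
threshold, and retains planes down to 30 µm (11 planes at 3 µm). The
coverage threshold default, 0.90, is one explicit reading of "almost the
entire image area"; it is configurable. Each retained plane is treated as
an independent image file.

`standardizeImage()` centers and scales *per channel* to mean 0, SD 1.
Standardizing jointly would let the two bright autofluorescence channels
swamp the sparse SHG channel; per-channel is an interpretation, flagged as
such. `cropTiles()` partitions the frame into 128 px tiles in row-major
order (origin top-left, 0-based grid coordinates).
`splitTrainValidation()` draws the 20 % validation split at tile level —
not patient level — reproducing the published split arithmetic
(112,960 group-A tiles → 22,592 validation / 90,368 training); plain
(unstratified) sampling is used.

## The blank rule

A tile is blank iff **both** its SNR against a median-filtered
"pseudo-noiseless" estimate falls below 20 **and** its mean brightness
(raw intensity / 4095, averaged over pixels and channels) falls below
0.10. Three decisions here are package interpretations, stated openly:

* the SNR formula — `20·log10(RMS(denoised) / RMS(tile − denoised))`,
  i.e. the threshold is read in decibels (`snrMode = "ratio"` is
  available);
* the median window — 3 × 3, the smallest standard denoising window;
* brightness is computed on raw intensities even though normalization is
  listed before cropping: a mean-zero standardized tile would make a 0.10
  mean threshold meaningless, so the blank rule reads the pre-standardized
  scale.

Degenerate cases are pinned down: zero residual with signal gives +Inf,
an all-zero tile gives 0. The 3 × 3 path runs in C++; the R
selection-network implementation and a brute-force neighborhood median
serve as its oracles in the tests.

## The classifier

The tile classifier is a small convolutional network written in the
package. A fixed moment-pooling front end brings the standardized 128 px
tile to the 32 px working resolution while keeping the first two moments
of the discarded high-frequency content: each input channel contributes a
4 × 4 block-mean channel *and* a block-SD channel (six input maps in
all). The SD maps carry the local texture variance that separates
irregular proliferation from smooth epithelium — a cue plain average
pooling would destroy, and the one that matters most when a lesion
covers only a corner of a tile. Three 3 × 3 same-padded convolution blocks (8, 16,
32 maps) with ReLU and 2 × 2 average pooling follow; the head
concatenates global *average* and global *max* pooling of the last
feature maps before a single logistic unit. The max path matters for the
motivating use case — cancer occupying a small corner of a tile: spatial
averaging alone dilutes a lesion covering a few percent of the tile below
the decision point, while the maximum keeps it decisive. The
output layer initializes at zero, so an untrained model scores exactly
0.5 and training curves start from chance. Gradients are exact
(finite-difference-verified); optimization is Adam on binary
cross-entropy, with optional class weighting (`"balanced"` up-weights the
scarcer cancer tiles). Training evaluates validation accuracy after every
epoch and returns the parameters of the best epoch, ties resolved toward
the earliest — "model selection on the validation set" made precise.

The reference protocol (Adam, 100 epochs, learning rate 0.020, batch
size 128) is the default of `trainConfig()`. The pipeline's desk-scale
default uses 40 epochs with balanced weighting: on cohorts of ~100 images
the loss plateaus well before 100 epochs, and the scarcity of cancer
tiles (roughly 10 % of nonblank tiles) otherwise depresses recall. A
full-scale Inception-style architecture is deliberately out of scope: the
value of the artifact is the pipeline, and 128 px synthetic tiles neither
need nor could justify it. Tiles score positive at probability ≥ 0.5.

## Evaluation conventions

* Predicted-positive = nonblank with score ≥ 0.5; **all** blank tiles are
  predicted-negative. Every tile, blank included, enters the confusion
  matrix, so totals conserve 64 × images.
* Malignant probability keeps denominator 64 (blanks count), and the
  image is called malignant iff the probability is **≥** 0.0625 — the
  inclusive inequality matches the standard ROC operating-point
  convention and makes "4 positive tiles" a malignant call; a strict
  variant is configurable.
* The ROC sweeps thresholds over the probability grid {0, 1/64, …, 1}
  plus a sentinel above 1 and integrates by trapezoid; the suite checks
  its AUC equals the concordant-pair (rank-sum) statistic exactly.
* `mannWhitneyU()` computes U from midranks; p-values come from exact
  enumeration for combined n ≤ 20 (valid under ties) and otherwise from
  the tie-corrected normal approximation. `stats::wilcox.test` is the
  cross-check in the tests, never the implementation, because its exact
  path cannot handle ties.
* `cohensKappa()` handles the degenerate chance-agreement-1 case
  explicitly (kappa 1 if observed agreement is also 1, undefined
  otherwise).
* Reported metrics are compared with published values at 3 decimals.

## Problem sizes and reproducibility

The bundled end-to-end property runs a cohort of 12 patients (6 per
group) × 8 images at the full 1024 px frame — 6,144 tiles — trains the
desk-scale classifier, and requires tile-level recall ≥ 0.9 and
image-level AUC ≥ 0.95; smaller 512 px cohorts exercise determinism and
serialization. These sizes were chosen once as the smallest cohorts that
leave the property comfortably away from its thresholds.

Every stochastic step (cohort layout, rendering, splits, initialization,
batch shuffling) derives from explicit seeds via an RNG-state-preserving
helper, so identical seeds reproduce cohorts, manifests, trained
parameters and reports bit for bit, and generation never perturbs the
caller's RNG state.

## Known limitations

* The blank-rule SNR sits ~3 dB above background and ~1 dB below the
  dimmest legitimate tissue at the default noise settings; substantially
  different background/noise choices would require revisiting the
  phantom's amplitude table (they are one coupled set of conditions).
* The classifier is deliberately small; it learns the phantom's texture
  and morphology cues and is not expected to transfer to real MPM data.
* Image-level truth in the phantom ("any cancer tile") is a construction,
  standing in for per-file pathologist findings.
* The published clinical numbers that depend on the unreleased patient
  images (e.g. the clinical AUC) are reproduced only as *computations on
  the printed tables*, never re-measured.
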