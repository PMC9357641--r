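## Internal scene renderer for the synthetic phantoms.
##
## A "scene" is an environment collecting deferred paint operations
## ("patches": a bounding box, a mask, per-pixel values and a channel
## signature) plus the placement registry used for the overlap budget.
## Patches are composed into the channel images in one pass at the end
## (sceneCompose), which keeps array updates in-place. Geometry is in
## pixels; all randomness comes from the caller's RNG state.

.structureCodes <- c(background = 0L, duct = 1L, adipose = 2L, collagen = 3L,
                     dcis = 4L, invasive = 5L, immune = 6L)

## Render amplitudes in gray levels (free phantom parameters; chosen so
## tissue sits well above the read-noise floor the way real structures do).
.renderAmplitudes <- c(epithelium = 1100, puncta = 1800, cancer = 1300,
                       adipose = 900, collagen = 1900, immune = 1400)

newScene <- function(H, W, nChannels, rscale = 1) {
  env <- new.env(parent = emptyenv())
  env$H <- H; env$W <- W; env$C <- nChannels
  env$rscale <- rscale   # structure-radius scale for sub-reference frames
  env$patches <- vector("list", 0L)
  env$placed <- list()   # circles (cy, cx, r) used for overlap budgeting
  env$placements <- data.frame(structure = character(), cy = numeric(),
                               cx = numeric(), r = numeric())
  env
}

.recordPlacement <- function(env, structure, ctr, r) {
  env$placements <- rbind(env$placements,
                          data.frame(structure = structure,
                                     cy = unname(ctr["cy"]),
                                     cx = unname(ctr["cx"]), r = r))
}

## Per-structure 3-channel signatures: band-pass response of the component's
## emission spectrum, normalized to unit maximum.
sceneSignatures <- function(config, filters) {
  sig <- function(name) {
    r <- channelResponse(emissionSpectrum(fluorophore(name), config), filters)
    r / max(r)
  }
  list(epithelium = sig("epithelial_autofluorescence"),
       puncta     = sig("duct_edge_puncta"),
       cancer     = sig("epithelial_autofluorescence"),  # same 480 nm peak
       adipose    = sig("adipose"),
       collagen   = sig("shg_collagen"),
       immune     = sig("immune_cell"))
}

.box <- function(env, cy, cx, r) {
  ys <- max(1L, floor(cy - r)):min(env$H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(env$W, ceiling(cx + r))
  if (!length(ys) || !length(xs) || ys[1] > ys[length(ys)] ||
      xs[1] > xs[length(xs)]) return(NULL)
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  list(ys = as.integer(ys), xs = as.integer(xs), Y = Y, X = X)
}

## Defer painting of `w * vals * signature[k]` into channel k. `w` is the
## soft coverage weight in [0, 1]; masks for the truth images use w > 0.5.
.paint <- function(env, box, w, vals, signature, code = 0L,
                   cancer = FALSE) {
  if (is.null(box)) return(invisible(NULL))
  mask <- w > 0
  if (!any(mask)) return(invisible(NULL))
  env$patches[[length(env$patches) + 1L]] <-
    list(ys = box$ys, xs = box$xs, mask = mask, hard = w > 0.5,
         vals = w * vals, signature = signature, code = as.integer(code),
         cancer = cancer)
  invisible(NULL)
}

## Compose all patches into channel images and masks. Cancer structure
## codes (dcis/invasive) are never overwritten by later stroma.
sceneCompose <- function(env) {
  H <- env$H; W <- env$W; C <- env$C
  ch <- array(0, c(H, W, C))
  smask <- matrix(0L, H, W)
  cmask <- matrix(FALSE, H, W)
  plane <- H * W
  cancerCodes <- .structureCodes[c("dcis", "invasive")]
  for (p in env$patches) {
    sel <- which(p$mask)
    if (!length(sel)) next
    gidx <- (rep(p$xs - 1L, each = length(p$ys)) * H +
             rep(p$ys, times = length(p$xs)))[sel]
    vals <- p$vals[sel]
    for (k in seq_len(C)) {
      off <- (k - 1L) * plane
      ch[gidx + off] <- ch[gidx + off] + p$signature[k] * vals
    }
    hidx <- (rep(p$xs - 1L, each = length(p$ys)) * H +
             rep(p$ys, times = length(p$xs)))[which(p$hard)]
    if (p$code > 0L && length(hidx)) {
      keep <- if (p$code %in% cancerCodes) hidx else
        hidx[!(smask[hidx] %in% cancerCodes)]
      smask[keep] <- p$code
    }
    if (p$cancer && length(hidx)) cmask[hidx] <- TRUE
  }
  list(ch = ch, smask = smask, cmask = cmask)
}

## Find a center whose circle overlaps already-placed circles by at most
## `overlapBudget` of the center distance (coarse circle-intersection bound).
.placeCircle <- function(env, r, margin, overlapBudget = 0.25,
                         maxTries = 200L) {
  if (env$H - 2 * (margin + r) < 1 || env$W - 2 * (margin + r) < 1)
    stop("phantom placement error: structure of radius ", r,
         " does not fit the frame")
  for (t in seq_len(maxTries)) {
    cy <- stats::runif(1, margin + r, env$H - margin - r)
    cx <- stats::runif(1, margin + r, env$W - margin - r)
    ok <- TRUE
    for (p in env$placed) {
      d <- sqrt((cy - p[1])^2 + (cx - p[2])^2)
      if (d < (r + p[3]) * (1 - overlapBudget)) { ok <- FALSE; break }
    }
    if (ok) {
      env$placed <- c(env$placed, list(c(cy, cx, r)))
      return(c(cy = cy, cx = cx))
    }
  }
  stop("phantom placement error: could not place a structure of radius ", r,
       " within the overlap budget")
}

## Cellular-granularity texture: a Gaussian amplitude field sampled on a
## coarse grid and bilinearly interpolated, so it is correlated over scales
## beyond the median-filter window (unlike read noise) and free of sharp
## discontinuities (optics blur real texture the same way).
.blockField <- function(nr, nc, base, sd, scale = 6L) {
  br <- ceiling(nr / scale) + 1L
  bc <- ceiling(nc / scale) + 1L
  coarse <- matrix(stats::rnorm(br * bc, 0, sd), br, bc)
  fine <- .interpMat(nr, br, scale) %*% coarse %*% t(.interpMat(nc, bc, scale))
  pmin(pmax(base * (1 + fine), 0.05), 2.2)
}

## n x b bilinear interpolation matrix for coarse nodes every `scale` px
.interpMat <- function(n, b, scale) {
  pos <- (seq_len(n) - 1) / scale + 1
  k0 <- pmin(floor(pos), b - 1L)
  f <- pos - k0
  M <- matrix(0, n, b)
  M[cbind(seq_len(n), k0)] <- 1 - f
  M[cbind(seq_len(n), k0 + 1L)] <- f
  M
}

## Separable [1,2,1]/4 binomial blur per channel (replicated edges): a
## light point-spread-function stand-in applied to the composed noiseless
## scene, so no rendered edge is sharper than the optics would allow.
.blurPSF <- function(ch) {
  H <- dim(ch)[1]; W <- dim(ch)[2]
  up <- c(1L, seq_len(H - 1L)); dn <- c(seq_len(H - 1L) + 1L, H)
  lf <- c(1L, seq_len(W - 1L)); rt <- c(seq_len(W - 1L) + 1L, W)
  for (k in seq_len(dim(ch)[3])) {
    m <- ch[, , k]
    for (pass in 1:2) {
      m <- (m[up, ] + 2 * m + m[dn, ]) / 4
      m <- (m[, lf] + 2 * m + m[, rt]) / 4
    }
    ch[, , k] <- m
  }
  ch
}

## Soft (anti-aliased) masks: coverage ramps linearly over `aa` pixels at
## structure boundaries, as the optical point-spread function would render
## them. The median filter preserves such ramps, so structure edges do not
## masquerade as noise in the blank rule's SNR.
.softDisk <- function(d, r, aa = 2) pmin(pmax((r - d) / aa, 0), 1)

.softAnnulus <- function(d, rIn, rOut, aa = 2)
  .softDisk(d, rOut, aa) * pmin(pmax((d - rIn) / aa, 0), 1)

renderDuct <- function(env, sigs, cancerous = FALSE) {
  rOut <- stats::runif(1, 70, 110) * env$rscale
  ctr <- .placeCircle(env, rOut, margin = 8)
  .recordPlacement(env, if (cancerous) "dcis" else "duct", ctr, rOut)
  box <- .box(env, ctr["cy"], ctr["cx"], rOut + 8)
  d <- sqrt((box$Y - ctr["cy"])^2 + (box$X - ctr["cx"])^2)
  if (cancerous) {
    ## DCIS: duct filled with irregularly proliferating cells, enlarged
    ## signal-void nuclei, no edge puncta.
    w <- .softDisk(d, rOut)
    tex <- .blockField(nrow(d), ncol(d), 1, 0.45)
    tex <- .carveNuclei(tex, box, ctr, rIn = 0, rOut = rOut,
                        n = round(rOut^2 / 450), nucR = c(6, 10))
    .paint(env, box, w, tex * .renderAmplitudes["cancer"], sigs$cancer,
           code = .structureCodes["dcis"], cancer = TRUE)
  } else {
    ## Normal duct: epithelial ring around a signal-void lumen with neat,
    ## small nuclei and bright dot-like puncta along the outer edge.
    rIn <- rOut - stats::runif(1, 18, 28) * env$rscale
    w <- .softAnnulus(d, rIn, rOut)
    tex <- .blockField(nrow(d), ncol(d), 1, 0.12)
    tex <- .carveNuclei(tex, box, ctr, rIn = rIn, rOut = rOut,
                        n = round(2 * pi * (rIn + rOut) / 2 / 14),
                        nucR = c(3, 4.5))
    .paint(env, box, w, tex * .renderAmplitudes["epithelium"],
           sigs$epithelium, code = .structureCodes["duct"])
    .renderPuncta(env, ctr, rOut + 3, sigs)
  }
  invisible(NULL)
}

## Carve signal-void elliptical nuclei into a texture matrix (local bbox).
.carveNuclei <- function(tex, box, ctr, rIn, rOut, n, nucR) {
  if (n < 1) return(tex)
  th <- stats::runif(n, 0, 2 * pi)
  rr <- if (rIn > 0) (rIn + rOut) / 2 + stats::runif(n, -3, 3) else
    sqrt(stats::runif(n)) * (rOut - nucR[2] - 1)
  ny <- ctr["cy"] + rr * sin(th)
  nx <- ctr["cx"] + rr * cos(th)
  rad <- stats::runif(n, nucR[1], nucR[2])
  for (i in seq_len(n)) {
    d <- sqrt((box$Y - ny[i])^2 + (box$X - nx[i])^2)
    v <- .softDisk(d, rad[i])          # 1 inside the nucleus, ramp at edge
    tex <- tex * (1 - 0.88 * v)        # signal-void: drop to 12 % of texture
  }
  tex
}

.renderPuncta <- function(env, ctr, radius, sigs) {
  n <- max(8L, round(2 * pi * radius / 13))
  th <- sort(stats::runif(n, 0, 2 * pi))
  py <- ctr["cy"] + (radius + stats::runif(n, -1.5, 1.5)) * sin(th)
  px <- ctr["cx"] + (radius + stats::runif(n, -1.5, 1.5)) * cos(th)
  amp <- .renderAmplitudes["puncta"] * stats::runif(n, 0.7, 1.1)
  for (i in seq_len(n)) {
    box <- .box(env, py[i], px[i], 4)
    if (is.null(box)) next
    w <- .softDisk(sqrt((box$Y - py[i])^2 + (box$X - px[i])^2), 3, aa = 1.8)
    .paint(env, box, w, matrix(amp[i], nrow(box$Y), ncol(box$Y)),
           sigs$puncta, code = .structureCodes["duct"])
  }
}

renderInvasiveNest <- function(env, sigs) {
  r0 <- stats::runif(1, 75, 115) * env$rscale
  ctr <- .placeCircle(env, r0 * 1.3, margin = 8)
  .recordPlacement(env, "invasive", ctr, r0)
  box <- .box(env, ctr["cy"], ctr["cx"], r0 * 1.45)
  dy <- box$Y - ctr["cy"]; dx <- box$X - ctr["cx"]
  th <- atan2(dy, dx)
  ## irregular blob: angularly modulated radius (no luminal formation)
  k <- sample(2:4, 2)
  ph <- stats::runif(2, 0, 2 * pi)
  a <- stats::runif(2, 0.12, 0.22)
  rb <- r0 * (1 + a[1] * sin(k[1] * th + ph[1]) + a[2] * sin(k[2] * th + ph[2]))
  w <- pmin(pmax((rb - sqrt(dy^2 + dx^2)) / 2, 0), 1)
  tex <- .blockField(nrow(th), ncol(th), 1, 0.45)
  tex <- .carveNuclei(tex, box, ctr, rIn = 0, rOut = r0,
                      n = round(r0^2 / 450), nucR = c(6, 10))
  .paint(env, box, w, tex * .renderAmplitudes["cancer"], sigs$cancer,
         code = .structureCodes["invasive"], cancer = TRUE)
  invisible(NULL)
}

renderAdipose <- function(env, sigs) {
  r <- stats::runif(1, 55, 100) * env$rscale
  ctr <- .placeCircle(env, r, margin = 6)
  .recordPlacement(env, "adipose", ctr, r)
  box <- .box(env, ctr["cy"], ctr["cx"], r + 4)
  d <- sqrt((box$Y - ctr["cy"])^2 + (box$X - ctr["cx"])^2)
  ring <- .softAnnulus(d, r - 5, r)
  interior <- .softDisk(d, r - 2)   # overlaps the ring ramp: no dark groove
  .paint(env, box, ring,
         matrix(.renderAmplitudes["adipose"], nrow(d), ncol(d)),
         sigs$adipose, code = .structureCodes["adipose"])
  ## adipocytes autofluoresce much like epithelium: a moderately bright,
  ## gently textured interior rather than a signal void
  .paint(env, box, interior,
         .blockField(nrow(d), ncol(d), 0.55, 0.12, scale = 8L) *
           .renderAmplitudes["adipose"],
         sigs$adipose, code = .structureCodes["adipose"])
  invisible(NULL)
}

renderCollagenFiber <- function(env, sigs) {
  ## curvilinear fiber: a smooth random walk of short thick segments
  y <- stats::runif(1, 1, env$H); x <- stats::runif(1, 1, env$W)
  th <- stats::runif(1, 0, 2 * pi)
  nSeg <- 70L; step <- 11; thick <- stats::runif(1, 3.2, 4.8)
  amp <- .renderAmplitudes["collagen"] * stats::runif(1, 0.8, 1.1)
  for (s in seq_len(nSeg)) {
    th <- th + stats::rnorm(1, 0, 0.17)
    y2 <- y + step * sin(th); x2 <- x + step * cos(th)
    .renderSegment(env, y, x, y2, x2, thick, amp, sigs)
    y <- y2; x <- x2
    if (y < -50 || y > env$H + 50 || x < -50 || x > env$W + 50) break
  }
  invisible(NULL)
}

.renderSegment <- function(env, y1, x1, y2, x2, thick, amp, sigs) {
  box <- .box(env, (y1 + y2) / 2, (x1 + x2) / 2,
              sqrt((y2 - y1)^2 + (x2 - x1)^2) / 2 + thick + 1)
  if (is.null(box)) return(invisible(NULL))
  vy <- y2 - y1; vx <- x2 - x1
  L2 <- vy^2 + vx^2
  if (L2 == 0) return(invisible(NULL))
  t <- pmin(pmax(((box$Y - y1) * vy + (box$X - x1) * vx) / L2, 0), 1)
  d <- sqrt((box$Y - (y1 + t * vy))^2 + (box$X - (x1 + t * vx))^2)
  w <- .softDisk(d, thick, aa = 2.2)
  .paint(env, box, w, matrix(amp, nrow(d), ncol(d)), sigs$collagen,
         code = .structureCodes["collagen"])
}

renderImmuneInfiltrate <- function(env, sigs) {
  m <- min(60, env$H / 4)
  cy <- stats::runif(1, m, env$H - m)
  cx <- stats::runif(1, m, env$W - m)
  n <- 35L
  py <- cy + stats::rnorm(n, 0, 38)
  px <- cx + stats::rnorm(n, 0, 38)
  rad <- stats::runif(n, 2.6, 4)
  amp <- .renderAmplitudes["immune"] * stats::runif(n, 0.7, 1.1)
  for (i in seq_len(n)) {
    box <- .box(env, py[i], px[i], rad[i] + 2)
    if (is.null(box)) next
    w <- .softDisk(sqrt((box$Y - py[i])^2 + (box$X - px[i])^2), rad[i],
                   aa = 1.8)
    .paint(env, box, w, matrix(amp[i], nrow(box$Y), ncol(box$Y)),
           sigs$immune, code = .structureCodes["immune"])
  }
  invisible(NULL)
}
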