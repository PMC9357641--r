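## Small convolutional network engine (base R, BLAS-backed im2col).
##
## Architecture ("small_cnn"): an optional fixed average-pooling front end
## bringing the tile to a 32 x 32 working resolution, then three 3 x 3
## same-padded convolution blocks (8, 16, 32 feature maps) with ReLU and
## 2 x 2 average pooling (global average pooling after the last block),
## and a single logistic output unit. Trained with Adam on (optionally
## class-weighted) binary cross-entropy. Gradients are exact (verified by
## finite differences in the test suite); all arrays are [y, x, channel,
## sample].

.cnnCache <- new.env(parent = emptyenv())

## index matrix mapping padded-input elements to im2col columns, cached by
## shape; columns ordered (dy, dx, channel)
.im2colIdx <- function(H, W, C, B) {
  key <- paste("i", H, W, C, B, sep = "_")
  got <- .cnnCache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx1 <- matrix(0L, H * W, 9L * C)
  t <- 0L
  for (c in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    t <- t + 1L
    idx1[, t] <- (i + dy) + Hp * (j + dx - 1L) + Hp * Wp * (c - 1L)
  }
  per <- Hp * Wp * C
  full <- idx1[rep(seq_len(H * W), times = B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * per, each = H * W)
  .cnnCache[[key]] <- full
  full
}

.pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

## same-padded 3x3 convolution; returns output array and the column matrix
## needed for the backward pass
.convFwd <- function(x, W, b) {
  d <- dim(x)                       # H W C B
  xp <- .pad1(x)
  idx <- .im2colIdx(d[1], d[2], d[3], d[4])
  M <- matrix(xp[idx], nrow = d[1] * d[2] * d[4])
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  Cout <- length(b)
  ya <- array(Y, c(d[1], d[2], d[4], Cout))
  list(out = aperm(ya, c(1L, 2L, 4L, 3L)), M = M, inDim = d)
}

.convBwd <- function(fwd, W, dOut) {
  d <- fwd$inDim
  Cout <- ncol(W)
  dY <- matrix(aperm(dOut, c(1L, 2L, 4L, 3L)), nrow = d[1] * d[2] * d[4])
  dW <- crossprod(fwd$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  Hp <- d[1] + 2L; Wp <- d[2] + 2L
  dxp <- numeric(Hp * Wp * d[3] * d[4])
  idx <- .im2colIdx(d[1], d[2], d[3], d[4])
  for (k in seq_len(ncol(idx))) {
    ii <- idx[, k]
    dxp[ii] <- dxp[ii] + dM[, k]
  }
  dim(dxp) <- c(Hp, Wp, d[3], d[4])
  list(dx = dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE],
       dW = dW, db = db)
}

.avgpool2Fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); e1 <- seq(2L, d[1], 2L)
  o2 <- seq(1L, d[2], 2L); e2 <- seq(2L, d[2], 2L)
  (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
   x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
}

.avgpool2Bwd <- function(dOut, inDim) {
  dx <- array(0, inDim)
  o1 <- seq(1L, inDim[1], 2L); e1 <- seq(2L, inDim[1], 2L)
  o2 <- seq(1L, inDim[2], 2L); e2 <- seq(2L, inDim[2], 2L)
  q <- dOut / 4
  dx[o1, o2, , ] <- q; dx[e1, o2, , ] <- q
  dx[o1, e2, , ] <- q; dx[e1, e2, , ] <- q
  dx
}

## fixed front-end average pooling by integer factor f
.avgpoolK <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  stopifnot(d[1] %% f == 0L, d[2] %% f == 0L)
  dim(x) <- c(f, d[1] %/% f, f, d[2] %/% f, d[3] * d[4])
  x <- aperm(x, c(1L, 3L, 2L, 4L, 5L))
  y <- colMeans(matrix(x, f * f))
  dim(y) <- c(d[1] %/% f, d[2] %/% f, d[3], d[4])
  y
}

.cnnInit <- function(Cin) {
  he <- function(fanIn, n) stats::rnorm(n, 0, sqrt(2 / fanIn))
  ## output layer reads global average AND global max features (2 x 32):
  ## the max path keeps cancer occupying a small corner of a tile decisive.
  ## Zero-initialized output layer: an untrained model scores exactly 0.5.
  list(W1 = matrix(he(9 * Cin, 9 * Cin * 8), 9 * Cin, 8), b1 = numeric(8),
       W2 = matrix(he(72, 72 * 16), 72, 16),              b2 = numeric(16),
       W3 = matrix(he(144, 144 * 32), 144, 32),           b3 = numeric(32),
       w4 = numeric(64),                                   b4 = 0)
}

## forward pass; keep = TRUE retains intermediates for the backward pass
.cnnForward <- function(params, x, keep = FALSE) {
  f1 <- .convFwd(x, params$W1, params$b1)
  a1 <- pmax(f1$out, 0)
  p1 <- .avgpool2Fwd(a1)
  f2 <- .convFwd(p1, params$W2, params$b2)
  a2 <- pmax(f2$out, 0)
  p2 <- .avgpool2Fwd(a2)
  f3 <- .convFwd(p2, params$W3, params$b3)
  a3 <- pmax(f3$out, 0)
  d3 <- dim(a3)
  flat <- matrix(a3, d3[1] * d3[2])              # HW x (C*B)
  iMax <- max.col(t(flat), ties.method = "first")
  Fm <- rbind(matrix(colMeans(flat), d3[3], d3[4]),
              matrix(flat[cbind(iMax, seq_along(iMax))], d3[3], d3[4]))
  z <- as.vector(crossprod(Fm, params$w4)) + params$b4
  if (!keep) return(list(z = z))
  list(z = z, f1 = f1, a1 = a1, p1 = p1, f2 = f2, a2 = a2, p2 = p2,
       f3 = f3, a3 = a3, Fm = Fm, iMax = iMax)
}

## backward pass from dL/dz; returns gradients named like params
.cnnBackward <- function(params, fwd, dz) {
  d3 <- dim(fwd$a3)
  dw4 <- fwd$Fm %*% dz
  db4 <- sum(dz)
  dF <- outer(params$w4, dz)                      # 2C x B
  C <- d3[3]
  dAvg <- dF[seq_len(C), , drop = FALSE]
  dMax <- dF[C + seq_len(C), , drop = FALSE]
  da3 <- array(rep(dAvg, each = d3[1] * d3[2]) / (d3[1] * d3[2]), d3)
  dMaxFlat <- matrix(0, d3[1] * d3[2], C * d3[4])
  dMaxFlat[cbind(fwd$iMax, seq_along(fwd$iMax))] <- as.vector(dMax)
  da3 <- da3 + array(dMaxFlat, d3)
  da3 <- da3 * (fwd$a3 > 0)
  g3 <- .convBwd(fwd$f3, params$W3, da3)
  dp2 <- g3$dx
  da2 <- .avgpool2Bwd(dp2, dim(fwd$a2)) * (fwd$a2 > 0)
  g2 <- .convBwd(fwd$f2, params$W2, da2)
  da1 <- .avgpool2Bwd(g2$dx, dim(fwd$a1)) * (fwd$a1 > 0)
  g1 <- .convBwd(fwd$f1, params$W1, da1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, w4 = as.vector(dw4), b4 = db4)
}

## stable binary cross-entropy with logits; w are per-sample weights
.bceLoss <- function(z, y, w) {
  sp <- pmax(z, 0) + log1p(exp(-abs(z)))          # softplus(z)
  sum(w * (sp - y * z)) / sum(w)
}

.bceGrad <- function(z, y, w) {
  p <- 1 / (1 + exp(-z))
  w * (p - y) / sum(w)
}

.adamStep <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(state$params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    state$params[[nm]] <- state$params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  state
}

## Network-resolution preprocessing of a tile array: sides > 32 are pooled
## to the 32 x 32 working resolution, keeping the first two moments of the
## discarded high-frequency content — each input channel yields a
## block-mean channel and a block-SD channel. The SD channels carry the
## local texture variance that distinguishes irregular proliferation from
## smooth epithelium even when a lesion covers only a corner of the tile.
.cnnPrep <- function(x) {
  d <- dim(x)
  if (d[1] != d[2]) stop("tiles must be square")
  if (d[1] > 32L) {
    if (d[1] %% 32L != 0L)
      stop("tile side must be 32 or a multiple of 32")
    f <- d[1] %/% 32L
    mu <- .avgpoolK(x, f)
    sd <- sqrt(pmax(.avgpoolK(x^2, f) - mu^2, 0))
    x <- array(0, c(32L, 32L, 2L * d[3], d[4]))
    x[, , seq_len(d[3]), ] <- mu
    x[, , d[3] + seq_len(d[3]), ] <- sd
  }
  if (dim(x)[1] %% 4L != 0L)
    stop("working resolution must be divisible by 4")
  x
}

## batched predicted probabilities for a prepared array
.cnnPredictProb <- function(params, x, batch = 256L) {
  n <- dim(x)[4]
  p <- numeric(n)
  for (s in seq(1L, n, batch)) {
    e <- min(n, s + batch - 1L)
    z <- .cnnForward(params, x[, , , s:e, drop = FALSE])$z
    p[s:e] <- 1 / (1 + exp(-z))
  }
  p
}
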