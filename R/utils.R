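## Internal helpers shared across modules.

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. All stochastic package operations are
## routed through this so a seed argument fully determines the output.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a per-item seed from a master seed, kept inside 32-bit range.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

## A tile is `cancer` when the cancer-mask coverage within it exceeds
## `coverage`. Returns a tilesPerSide x tilesPerSide character matrix.
tileLabelsFromMask <- function(mask, tileSidePx, coverage) {
  H <- nrow(mask); W <- ncol(mask)
  if (H %% tileSidePx != 0L || W %% tileSidePx != 0L)
    stop("mask dimensions must be divisible by the tile side")
  nr <- H %/% tileSidePx; nc <- W %/% tileSidePx
  lab <- matrix("no_cancer", nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ys <- ((i - 1L) * tileSidePx + 1L):(i * tileSidePx)
    xs <- ((j - 1L) * tileSidePx + 1L):(j * tileSidePx)
    if (mean(mask[ys, xs]) > coverage) lab[i, j] <- "cancer"
  }
  lab
}
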