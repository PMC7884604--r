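# Internal helpers: seeding, band-limited noise, masks, Fisher transform.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-stream seed from a base seed and string/int
# tags. Plain 32-bit-safe modular arithmetic; not cryptographic, just
# collision-sparse enough to decorrelate participants and sessions.
deriveSeed <- function(base, ...) {
  h <- as.numeric(base) %% 2147483647
  for (tag in list(...)) {
    v <- if (is.character(tag)) utf8ToInt(tag) else as.numeric(tag)
    for (x in v) h <- (h * 30269 + (x %% 30307) + 17) %% 2147483647
  }
  as.integer(h %% 2147483562) + 1L
}

# T x n matrix of unit-variance noise whose spectral support lies inside
# [lowHz, highHz]: white noise is FFT-filtered and rescaled per column.
bandLimitedNoise <- function(nTime, trS, lowHz, highHz, n = 1L) {
  x <- matrix(stats::rnorm(nTime * n), nTime, n)
  f <- (seq_len(nTime) - 1) / (nTime * trS)
  f <- pmin(f, 1 / trS - f)  # two-sided spectrum folds at Nyquist
  keep <- f >= lowHz & f <= highHz
  if (!any(keep))
    stop("no Fourier frequencies inside the requested band")
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / nTime
  sc <- apply(out, 2, stats::sd)
  sc[sc == 0] <- 1
  sweep(out, 2, sc, "/")
}

# Axis-aligned box mask from fractional coordinates (lo, hi in [0, 1]).
boxMask <- function(gridShape, lo, hi) {
  m <- array(FALSE, gridShape)
  idx <- lapply(1:3, function(a) {
    i1 <- max(1L, ceiling(lo[a] * gridShape[a]))
    i2 <- min(gridShape[a], max(i1, floor(hi[a] * gridShape[a])))
    i1:i2
  })
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

#' Default mask layout for the synthetic grid
#'
#' Places five disjoint axis-aligned boxes on the grid: the seed region,
#' two target ROIs (ventral striatum and dorsolateral prefrontal stand-ins),
#' and white-matter and CSF nuisance regions. Positions are fractional, so
#' the layout scales with `gridShape`.
#'
#' @param gridShape integer vector of 3 voxel counts.
#' @return Named list of logical 3D arrays:
#'   `seed`, `vstr`, `dlpfc`, `wm`, `csf`.
#' @examples
#' m <- defaultMasks(c(20L, 20L, 20L))
#' vapply(m, sum, 0L)
#' @export
defaultMasks <- function(gridShape) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 4L))
  list(
    seed  = boxMask(gridShape, c(0.15, 0.55, 0.20), c(0.28, 0.68, 0.33)),
    vstr  = boxMask(gridShape, c(0.50, 0.50, 0.30), c(0.63, 0.63, 0.43)),
    dlpfc = boxMask(gridShape, c(0.30, 0.50, 0.65), c(0.43, 0.63, 0.78)),
    wm    = boxMask(gridShape, c(0.65, 0.15, 0.45), c(0.90, 0.40, 0.70)),
    csf   = boxMask(gridShape, c(0.08, 0.08, 0.60), c(0.32, 0.32, 0.88))
  )
}

#' Fisher r-to-z transform with clipping
#'
#' `atanh(r)` after clipping `|r|` at `1 - clip` so that degenerate
#' correlations (e.g. a voxel identical to the seed series) stay finite.
#'
#' @param r correlations in `[-1, 1]`.
#' @param clip clipping margin (default `1e-6`).
#' @return Fisher-z values.
#' @examples
#' fisherZ(0.5)        # 0.5493
#' fisherZ(1)          # atanh(1 - 1e-6), finite
#' @export
fisherZ <- function(r, clip = 1e-6) {
  atanh(pmin(1 - clip, pmax(-1 + clip, r)))
}

# Flatten a 4D array to V x T.
toVoxelMatrix <- function(arr4d) {
  d <- dim(arr4d)
  dim(arr4d) <- c(prod(d[1:3]), d[4])
  arr4d
}

# Voxel spacing (mm per voxel along each axis) from a 4x4 affine.
affineSpacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

diagAffine <- function(voxelSizeMm) {
  diag(c(rep(voxelSizeMm, 3), 1))
}
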