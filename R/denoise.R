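#' Framewise displacement from a rigid-body motion trace
#'
#' Sum of absolute backward differences of the three translations (mm)
#' plus 50 mm times the absolute backward differences of the three
#' rotations (rad), i.e. rotations are converted to arc length on a 50 mm
#' sphere. The first volume has no predecessor and gets FD = 0.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (rad).
#' @param headRadiusMm rotation-to-translation conversion radius.
#' @return Length-T non-negative vector in mm.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.2
#' framewiseDisplacement(m)
#' @export
framewiseDisplacement <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("motion trace needs at least 2 volumes")
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Detect outlier volumes (intensity and motion censoring)
#'
#' A volume is flagged when the z-score of the linearly detrended
#' volume-mean intensity exceeds `zThresh` in absolute value, or when its
#' framewise displacement is at least `fdThreshMm`.
#'
#' @param run a [BoldRun-class].
#' @param zThresh global-signal z threshold (default 3).
#' @param fdThreshMm framewise-displacement threshold in mm (default 0.5).
#' @return Length-T logical vector; TRUE = outlier.
#' @export
detectOutlierVolumes <- function(run, zThresh = 3, fdThreshMm = 0.5) {
  stopifnot(is(run, "BoldRun"), zThresh > 0, fdThreshMm > 0)
  d <- dim(run@data)
  if (prod(d) == 0) stop("empty run")
  g <- colMeans(toVoxelMatrix(run@data))
  tt <- seq_along(g)
  res <- stats::residuals(stats::lm(g ~ tt))
  z <- if (stats::sd(res) > 0) res / stats::sd(res) else res * 0
  fd <- framewiseDisplacement(run@motion)
  abs(z) > zThresh | fd >= fdThreshMm
}

#' Build the nuisance regression design
#'
#' Assembles 6 motion parameters, their first and second backward-difference
#' derivatives (first row padded with 0), mean white-matter and CSF series,
#' linear and quadratic trends, and one one-hot indicator column per flagged
#' outlier volume.
#'
#' @param motion T x 6 motion trace.
#' @param wmSeries,csfSeries length-T mean tissue series.
#' @param outlierFlags length-T logical from [detectOutlierVolumes()].
#' @return A [NuisanceDesign-class] with
#'   `18 + 2 + 2 + n_outliers` columns.
#' @export
buildNuisanceDesign <- function(motion, wmSeries, csfSeries, outlierFlags) {
  motion <- as.matrix(motion)
  nT <- nrow(motion)
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  if (length(wmSeries) != nT || length(csfSeries) != nT ||
      length(outlierFlags) != nT)
    stop("motion, tissue series and outlier flags must share length T")
  parNames <- c("tx", "ty", "tz", "rx", "ry", "rz")
  d1 <- rbind(0, diff(motion))
  d2 <- rbind(0, diff(d1))
  X <- cbind(motion, d1, d2, wmSeries, csfSeries,
             seq(-1, 1, length.out = nT),
             seq(-1, 1, length.out = nT)^2)
  labels <- c(paste0("mot_", parNames), paste0("dmot_", parNames),
              paste0("ddmot_", parNames), "wm", "csf",
              "trend_linear", "trend_quadratic")
  flagged <- which(outlierFlags)
  if (length(flagged)) {
    spikes <- matrix(0, nT, length(flagged))
    spikes[cbind(flagged, seq_along(flagged))] <- 1
    X <- cbind(X, spikes)
    labels <- c(labels, paste0("spike_", flagged))
  }
  colnames(X) <- labels
  new("NuisanceDesign", matrix = X, labels = labels,
      censored = as.logical(outlierFlags))
}

#' Binary 3D mask erosion
#'
#' 6-connected binary erosion applied `iterations` times: a voxel survives
#' only if all six face neighbours (treating the boundary as background)
#' are inside the mask. Anti-extensive; 0 iterations is the identity.
#'
#' @param mask logical 3D array.
#' @param iterations number of erosion passes (default 1).
#' @param name mask label used in error messages.
#' @return The eroded logical array; an error if erosion empties the mask.
#' @export
erodeMask <- function(mask, iterations = 1L, name = "mask") {
  stopifnot(length(dim(mask)) == 3L, iterations >= 0)
  if (!any(mask)) stop("mask '", name, "' is empty")
  m <- mask
  d <- dim(m)
  shifted <- function(a, axis, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[axis]] <- seq_len(d[axis] - by) + by
                  src[[axis]] <- seq_len(d[axis] - by) }
    else        { dst[[axis]] <- seq_len(d[axis] + by)
                  src[[axis]] <- seq_len(d[axis] + by) - by }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (i in seq_len(iterations)) {
    m <- m &
      shifted(m, 1, 1) & shifted(m, 1, -1) &
      shifted(m, 2, 1) & shifted(m, 2, -1) &
      shifted(m, 3, 1) & shifted(m, 3, -1)
    if (!any(m))
      stop("erosion emptied mask '", name, "' after ", i, " iteration(s)")
  }
  m
}

# Discrete cosine basis on the full time grid whose frequencies lie
# outside [low, high] Hz; rows can then be subset to retained volumes so
# nuisance regression and band-stop filtering happen in one fit.
outOfBandCosines <- function(nT, trS, band) {
  k <- seq_len(nT - 1)
  f <- k / (2 * nT * trS)
  keep <- f < band[1] | f > band[2]
  k <- k[keep]
  tt <- seq_len(nT) - 0.5
  B <- cos(outer(tt, k) * (pi / nT))
  colnames(B) <- paste0("dct_", k)
  B
}

#' Nuisance regression with simultaneous band-pass filtering
#'
#' Per voxel, a single least-squares fit over the retained (non-censored)
#' volumes against the nuisance design augmented with a discrete cosine
#' basis spanning frequencies outside the pass band (band-stop by
#' regression). Residuals are therefore orthogonal to every nuisance
#' regressor and carry only pass-band signal; censored volumes are zeroed
#' and excluded from all downstream correlations. Zero-variance design
#' columns (e.g. derivatives of a still trace) are dropped with a warning.
#'
#' @param run a [BoldRun-class].
#' @param design a [NuisanceDesign-class] with T rows.
#' @param band pass band in Hz (default 0.01-0.1).
#' @return A [CleanRun-class].
#' @export
denoiseRun <- function(run, design, band = c(0.01, 0.1)) {
  stopifnot(is(run, "BoldRun"), is(design, "NuisanceDesign"))
  d <- dim(run@data)
  nT <- d[4]
  if (nrow(design@matrix) != nT)
    stop("design rows must equal the number of volumes")
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be (low, high) Hz with 0 < low < high")
  keep <- !design@censored
  kDesign <- ncol(design@matrix)
  if (sum(keep) < kDesign + 10)
    stop("under-determined fit: ", sum(keep), " retained volumes for ",
         kDesign, " design columns")
  X <- cbind(intercept = 1, design@matrix, outOfBandCosines(nT, run@trS, band))
  Xr <- X[keep, , drop = FALSE]
  sds <- apply(Xr, 2, stats::sd)
  const <- sds == 0 & colnames(Xr) != "intercept"
  # spike indicators are structurally zero once their volume is censored
  unexpected <- const & !grepl("^spike_", colnames(Xr))
  if (any(unexpected))
    warning("dropping zero-variance design column(s): ",
            paste(colnames(Xr)[unexpected], collapse = ", "))
  Xr <- Xr[, !const, drop = FALSE]
  if (sum(keep) <= ncol(Xr))
    stop("under-determined fit: more regressors (", ncol(Xr),
         ") than retained volumes (", sum(keep), ")")
  Y <- t(toVoxelMatrix(run@data))[keep, , drop = FALSE]
  res <- qr.resid(qr(Xr), Y)
  out <- matrix(0, prod(d[1:3]), nT)
  out[, keep] <- t(res)
  dim(out) <- d
  new("CleanRun", residuals = out, retained = keep, band = band,
      trS = run@trS, affine = run@affine, masks = run@masks,
      participant = run@participant, session = run@session)
}

#' Spatial Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian with `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis
#' in mm, converted to voxels via the affine spacing. Kernel rows are
#' renormalised at the boundary, so constant volumes are preserved exactly
#' and interior intensity is conserved.
#'
#' @param grid 3D numeric array.
#' @param fwhmMm full width at half maximum in mm (0 = identity).
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @return Smoothed array of the same shape.
#' @export
smoothVolume <- function(grid, fwhmMm = 8, affine = diag(4)) {
  stopifnot(length(dim(grid)) == 3L)
  if (fwhmMm < 0) stop("fwhmMm must be non-negative")
  if (fwhmMm == 0) return(grid)
  spacing <- affineSpacing(affine)
  if (any(spacing <= 0)) stop("non-positive voxel spacing in affine")
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / spacing
  out <- grid
  for (axis in 1:3) {
    n <- dim(out)[axis]
    r <- max(1L, ceiling(3 * sigma[axis]))
    k <- stats::dnorm(-r:r, sd = sigma[axis])
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- K %*% matrix(a, da[1], prod(da[2:3]))
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}
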