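#' Mean seed time course
#'
#' Unweighted mean of the residual time series over the seed voxels.
#' Censored volumes stay zero and are excluded downstream via the run's
#' `retained` flags.
#'
#' @param clean a [CleanRun-class].
#' @param seed logical 3D seed mask (defaults to the run's own seed mask).
#' @return Length-T numeric series.
#' @export
seedMeanTimecourse <- function(clean, seed = NULL) {
  stopifnot(is(clean, "CleanRun"))
  if (is.null(seed)) seed <- clean@masks$seed
  if (is.null(seed) || !any(seed)) stop("seed mask is empty")
  if (!identical(dim(seed), dim(clean@residuals)[1:3]))
    stop("seed mask shape differs from the run")
  colMeans(toVoxelMatrix(clean@residuals)[which(seed), , drop = FALSE])
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Pearson correlation of every voxel's residual series with the seed mean
#' time course over retained volumes, Fisher r-to-z transformed
#' (`z = atanh(r)`, with `|r|` clipped at `1 - 1e-6` so self-correlations
#' stay finite). Zero-variance voxels get z = 0 with a warning.
#'
#' @param clean a [CleanRun-class].
#' @param seedSeries optional precomputed seed series (length T); by
#'   default [seedMeanTimecourse()] on the run's seed mask.
#' @return A [ConnectivityMap-class].
#' @export
seedToVoxelMap <- function(clean, seedSeries = NULL) {
  stopifnot(is(clean, "CleanRun"))
  if (is.null(seedSeries)) seedSeries <- seedMeanTimecourse(clean)
  d <- dim(clean@residuals)
  if (length(seedSeries) != d[4])
    stop("seed series length must equal the number of volumes")
  keep <- clean@retained
  if (sum(keep) < 10) stop("fewer than 10 retained volumes")
  s <- seedSeries[keep]
  if (stats::sd(s) == 0) stop("seed series is constant over retained volumes")
  Y <- t(toVoxelMatrix(clean@residuals))[keep, , drop = FALSE]
  sdY <- apply(Y, 2, stats::sd)
  flat <- sdY == 0
  r <- numeric(ncol(Y))
  r[!flat] <- drop(stats::cor(s, Y[, !flat, drop = FALSE]))
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel(s) assigned z = 0")
    r[flat] <- 0
  }
  z <- fisherZ(r)
  dim(z) <- d[1:3]
  new("ConnectivityMap", zgrid = z, participant = clean@participant,
      session = clean@session, seed = "seed", nRetained = sum(keep))
}

#' Mean Fisher z over an ROI
#'
#' The scalar connectivity feature: unweighted mean of the Fisher-z map
#' over the ROI voxels.
#'
#' @param map a [ConnectivityMap-class].
#' @param roi logical 3D mask.
#' @param roiId label recorded in the output.
#' @return One-row data.frame: `participant`, `session`, `roi`, `z`.
#' @export
roiMeanZ <- function(map, roi, roiId = "roi") {
  stopifnot(is(map, "ConnectivityMap"))
  if (!any(roi)) stop("ROI mask is empty")
  if (!identical(dim(roi), dim(map@zgrid)))
    stop("ROI mask shape differs from the map")
  data.frame(participant = map@participant, session = map@session,
             roi = roiId, z = mean(map@zgrid[roi]),
             stringsAsFactors = FALSE)
}
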