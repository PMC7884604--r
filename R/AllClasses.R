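#' @import methods
NULL

#' Cohort simulation parameters
#'
#' A `CohortSpec` bundles every tunable of the synthetic-cohort and
#' synthetic-BOLD generators: group sizes, acquisition geometry, the planted
#' seed-to-ROI coupling per group and session, the planted slope linking
#' connectivity change to weight change, hormone parameters, and motion
#' artefact rates. All downstream ground-truth checks are phrased against
#' these values.
#'
#' @slot nLean,nObese number of lean / obese participants.
#' @slot nVolumesAcquired volumes acquired per run; the first `nDiscard`
#'   are dropped for T1 equilibration, so runs carry
#'   `nVolumesAcquired - nDiscard` volumes.
#' @slot nDiscard leading volumes discarded.
#' @slot trS repetition time in seconds.
#' @slot gridShape integer vector of 3 voxel counts.
#' @slot voxelSizeMm isotropic voxel size in mm (diagonal affine).
#' @slot couplingVstrT0,couplingVstrT8 named numeric (`lean`, `obese`):
#'   target Pearson correlation between the seed mean time course and
#'   ventral-striatum ROI voxels at each session.
#' @slot couplingDlpfcT0,couplingDlpfcT8 same for the dorsolateral
#'   prefrontal ROI (planted with a group difference but no change over
#'   time, so its change feature is a true null for prediction).
#' @slot couplingTraitSd between-participant SD of the coupling (Fisher z).
#' @slot couplingSessionSd within-participant session-to-session SD
#'   (Fisher z).
#' @slot couplingChangeSd SD of the planted individual ventral-striatum
#'   coupling change in the obese group (Fisher z).
#' @slot couplingChangeSlope planted regression slope of weight change on
#'   the individual coupling change, kg per Fisher-z unit.
#' @slot noiseSdKg residual SD of obese weight change, kg.
#' @slot weightChangeObeseKg mean obese weight change (negative = loss).
#' @slot weightChangeLeanSd SD of lean weight change about zero, kg.
#' @slot leptinFatSlope,leptinFatIntercept cross-sectional leptin(fat)
#'   line, ng/ml per kg and ng/ml.
#' @slot ratioMeanNgPerKg,ratioSd mean and SD of the individual
#'   leptin-change-per-kg-fat-lost ratio.
#' @slot hormoneEffectR planted correlation between the individual ratio
#'   and the individual connectivity change.
#' @slot leptinNoiseSd measurement noise on leptin, ng/ml.
#' @slot fatLossFraction,fatLossSdKg fat loss as a fraction of weight loss,
#'   and its residual SD in kg.
#' @slot spikeRate per-volume probability of a motion spike (lean).
#' @slot obeseMotionMult multiplier on `spikeRate` for the obese group.
#' @slot rngSeed integer master seed; all randomness derives from it.
#'
#' @seealso [CohortSpec()] for the user-facing constructor.
#' @export
setClass("CohortSpec",
  representation(
    nLean = "numeric", nObese = "numeric",
    nVolumesAcquired = "numeric", nDiscard = "numeric", trS = "numeric",
    gridShape = "integer", voxelSizeMm = "numeric",
    couplingVstrT0 = "numeric", couplingVstrT8 = "numeric",
    couplingDlpfcT0 = "numeric", couplingDlpfcT8 = "numeric",
    couplingTraitSd = "numeric", couplingSessionSd = "numeric",
    couplingChangeSd = "numeric", couplingChangeSlope = "numeric",
    noiseSdKg = "numeric",
    weightChangeObeseKg = "numeric", weightChangeLeanSd = "numeric",
    leptinFatSlope = "numeric", leptinFatIntercept = "numeric",
    ratioMeanNgPerKg = "numeric", ratioSd = "numeric",
    hormoneEffectR = "numeric", leptinNoiseSd = "numeric",
    fatLossFraction = "numeric", fatLossSdKg = "numeric",
    spikeRate = "numeric", obeseMotionMult = "numeric",
    rngSeed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  cnt <- c(nLean = object@nLean, nObese = object@nObese,
           nVolumesAcquired = object@nVolumesAcquired)
  if (any(cnt <= 0) || any(cnt != round(cnt)))
    msg <- c(msg, "participant and volume counts must be positive integers")
  if (object@nDiscard < 0 || object@nDiscard >= object@nVolumesAcquired)
    msg <- c(msg, "nDiscard must satisfy 0 <= nDiscard < nVolumesAcquired")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be three voxel counts, each >= 4")
  cps <- c(object@couplingVstrT0, object@couplingVstrT8,
           object@couplingDlpfcT0, object@couplingDlpfcT8)
  if (any(abs(cps) >= 1))
    msg <- c(msg, "planted couplings must have |r| < 1")
  sds <- c(object@couplingTraitSd, object@couplingSessionSd,
           object@couplingChangeSd, object@noiseSdKg,
           object@weightChangeLeanSd, object@ratioSd, object@leptinNoiseSd,
           object@fatLossSdKg)
  if (any(sds < 0)) msg <- c(msg, "standard deviations must be non-negative")
  if (object@spikeRate < 0 || object@spikeRate >= 1)
    msg <- c(msg, "spikeRate must lie in [0, 1)")
  if (abs(object@hormoneEffectR) >= 1)
    msg <- c(msg, "hormoneEffectR must have |r| < 1")
  if (length(msg)) msg else TRUE
})

#' Construct a cohort specification
#'
#' Defaults emulate the study conditions: 30 lean and 14 obese participants,
#' 304 acquired volumes at TR = 2 s with the first five discarded (299
#' retained), a 20x20x20 grid of 3 mm voxels, obese seed-to-ventral-striatum
#' coupling weaker than lean at baseline and increasing after surgery, a
#' mean obese weight change of -34 kg, and Table-1-scale hormone profiles
#' (leptin 70 -> 25 ng/ml as body fat drops 62 -> 42 kg).
#'
#' @param nLean,nObese group sizes.
#' @param nVolumesAcquired,nDiscard,trS acquisition parameters.
#' @param gridShape,voxelSizeMm synthetic grid geometry.
#' @param couplingVstrT0,couplingVstrT8,couplingDlpfcT0,couplingDlpfcT8
#'   named per-group target couplings (Pearson r).
#' @param couplingTraitSd,couplingSessionSd,couplingChangeSd coupling
#'   variability on the Fisher-z scale.
#' @param couplingChangeSlope kg of weight change per Fisher-z unit of
#'   coupling change.
#' @param noiseSdKg,weightChangeObeseKg,weightChangeLeanSd weight model.
#' @param leptinFatSlope,leptinFatIntercept,ratioMeanNgPerKg,ratioSd
#'   hormone model: cross-sectional leptin(fat) line and longitudinal
#'   leptin-per-fat ratio.
#' @param hormoneEffectR,leptinNoiseSd,fatLossFraction,fatLossSdKg hormone
#'   model: planted ratio-connectivity correlation, leptin noise, and the
#'   fat-loss link to weight loss.
#' @param spikeRate,obeseMotionMult motion artefact rates.
#' @param rngSeed master seed.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(rngSeed = 1)
#' spec
#' @export
CohortSpec <- function(nLean = 30, nObese = 14,
                       nVolumesAcquired = 304, nDiscard = 5, trS = 2,
                       gridShape = c(20L, 20L, 20L), voxelSizeMm = 3,
                       couplingVstrT0 = c(lean = 0.30, obese = 0.10),
                       couplingVstrT8 = c(lean = 0.30, obese = 0.28),
                       couplingDlpfcT0 = c(lean = 0.10, obese = 0.35),
                       couplingDlpfcT8 = c(lean = 0.10, obese = 0.35),
                       couplingTraitSd = 0.12, couplingSessionSd = 0.05,
                       couplingChangeSd = 0.10, couplingChangeSlope = -30,
                       noiseSdKg = 5,
                       weightChangeObeseKg = -34, weightChangeLeanSd = 1.5,
                       leptinFatSlope = 1.36, leptinFatIntercept = -14.1,
                       ratioMeanNgPerKg = 2.25, ratioSd = 0.5,
                       hormoneEffectR = 0.7, leptinNoiseSd = 2,
                       fatLossFraction = 0.6, fatLossSdKg = 2,
                       spikeRate = 0.01, obeseMotionMult = 3,
                       rngSeed = 1L) {
  new("CohortSpec",
      nLean = nLean, nObese = nObese,
      nVolumesAcquired = nVolumesAcquired, nDiscard = nDiscard, trS = trS,
      gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      couplingVstrT0 = couplingVstrT0, couplingVstrT8 = couplingVstrT8,
      couplingDlpfcT0 = couplingDlpfcT0, couplingDlpfcT8 = couplingDlpfcT8,
      couplingTraitSd = couplingTraitSd, couplingSessionSd = couplingSessionSd,
      couplingChangeSd = couplingChangeSd,
      couplingChangeSlope = couplingChangeSlope,
      noiseSdKg = noiseSdKg,
      weightChangeObeseKg = weightChangeObeseKg,
      weightChangeLeanSd = weightChangeLeanSd,
      leptinFatSlope = leptinFatSlope, leptinFatIntercept = leptinFatIntercept,
      ratioMeanNgPerKg = ratioMeanNgPerKg, ratioSd = ratioSd,
      hormoneEffectR = hormoneEffectR, leptinNoiseSd = leptinNoiseSd,
      fatLossFraction = fatLossFraction, fatLossSdKg = fatLossSdKg,
      spikeRate = spikeRate, obeseMotionMult = obeseMotionMult,
      rngSeed = rngSeed)
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nLean, "lean +", object@nObese, "obese;",
      object@nVolumesAcquired, "volumes (TR", object@trS, "s,",
      object@nDiscard, "discarded);",
      paste(object@gridShape, collapse = "x"), "grid @",
      object@voxelSizeMm, "mm\n")
  cat("  vStr coupling T0 (lean/obese):",
      paste(object@couplingVstrT0, collapse = "/"),
      " T8:", paste(object@couplingVstrT8, collapse = "/"), "\n")
  cat("  planted slope:", object@couplingChangeSlope,
      "kg per Fisher-z; weight noise", object@noiseSdKg, "kg; seed",
      object@rngSeed, "\n")
})

#' One session's synthetic BOLD run
#'
#' Holds a 4D intensity grid, the repetition time, a T x 6 rigid-body motion
#' trace (three translations in mm, three rotations in rad), the voxel-to-mm
#' affine, and the binary masks (seed, target ROIs, white matter, CSF) on
#' the same grid.
#'
#' @slot data 4D numeric array, X x Y x Z x T.
#' @slot trS repetition time, seconds.
#' @slot motion T x 6 matrix (translations mm, rotations rad).
#' @slot affine 4 x 4 voxel-to-mm matrix.
#' @slot masks named list of logical 3D arrays: `seed`, `vstr`, `dlpfc`,
#'   `wm`, `csf`.
#' @slot participant,session identifiers.
#' @export
setClass("BoldRun",
  representation(data = "array", trS = "numeric", motion = "matrix",
                 affine = "matrix", masks = "list",
                 participant = "character", session = "character"))

setValidity("BoldRun", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array")
  if (length(d) == 4L && nrow(object@motion) != d[4])
    msg <- c(msg, "motion trace length must equal the number of volumes")
  if (ncol(object@motion) != 6L) msg <- c(msg, "motion must have 6 columns")
  if (!all(c("seed", "vstr", "dlpfc", "wm", "csf") %in% names(object@masks)))
    msg <- c(msg, "masks must include seed, vstr, dlpfc, wm, csf")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!identical(dim(m), d[1:3]))
      msg <- c(msg, paste0("mask '", nm, "' shape differs from the run"))
    else if (!any(m)) msg <- c(msg, paste0("mask '", nm, "' is empty"))
  }
  if (all(c("seed", "vstr", "dlpfc") %in% names(object@masks))) {
    if (any(object@masks$seed & (object@masks$vstr | object@masks$dlpfc)))
      msg <- c(msg, "seed and target ROI masks must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat("BoldRun", object@participant, object@session, ":",
      paste(d[1:3], collapse = "x"), "voxels x", d[4], "volumes, TR",
      object@trS, "s\n")
  cat("  masks:", paste(sprintf("%s(%d)", names(object@masks),
                                vapply(object@masks, sum, 0L)),
                        collapse = " "), "\n")
})

#' Nuisance regression design
#'
#' Columns: 6 motion parameters, their first and second backward-difference
#' derivatives (18 motion-derived columns), mean white-matter and CSF
#' signals, linear and quadratic trends, and one indicator column per
#' censored volume.
#'
#' @slot matrix T x K design matrix.
#' @slot labels column labels.
#' @slot censored length-T logical; TRUE = volume flagged as outlier.
#' @export
setClass("NuisanceDesign",
  representation(matrix = "matrix", labels = "character",
                 censored = "logical"))

setValidity("NuisanceDesign", function(object) {
  msg <- character()
  if (ncol(object@matrix) != length(object@labels))
    msg <- c(msg, "labels must match design columns")
  if (nrow(object@matrix) != length(object@censored))
    msg <- c(msg, "censored flags must match design rows")
  nmot <- sum(grepl("^(mot|dmot|ddmot)_", object@labels))
  if (nmot != 18L)
    msg <- c(msg, "design must carry exactly 18 motion-derived columns")
  if (!all(c("trend_linear", "trend_quadratic") %in% object@labels))
    msg <- c(msg, "linear and quadratic trend columns are required")
  if (sum(grepl("^spike_", object@labels)) != sum(object@censored))
    msg <- c(msg, "one spike indicator per censored volume is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NuisanceDesign", function(object) {
  cat("NuisanceDesign:", nrow(object@matrix), "volumes x",
      ncol(object@matrix), "regressors;", sum(object@censored),
      "censored\n")
})

#' Denoised run (regression residuals)
#'
#' Residuals of the simultaneous nuisance + band-stop regression. Censored
#' volumes hold zeros and are excluded (via `retained`) from every
#' downstream correlation.
#'
#' @slot residuals 4D array, X x Y x Z x T.
#' @slot retained length-T logical; TRUE = volume survived censoring.
#' @slot band numeric(2), pass band in Hz.
#' @slot trS repetition time, seconds.
#' @slot affine 4 x 4 voxel-to-mm matrix.
#' @slot masks mask list carried over from the input run.
#' @slot participant,session identifiers.
#' @export
setClass("CleanRun",
  representation(residuals = "array", retained = "logical", band = "numeric",
                 trS = "numeric", affine = "matrix", masks = "list",
                 participant = "character", session = "character"))

setValidity("CleanRun", function(object) {
  msg <- character()
  d <- dim(object@residuals)
  if (length(d) != 4L) msg <- c(msg, "residuals must be a 4D array")
  if (length(d) == 4L && length(object@retained) != d[4])
    msg <- c(msg, "retained flags must match the number of volumes")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msg <- c(msg, "band must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CleanRun", function(object) {
  d <- dim(object@residuals)
  cat("CleanRun", object@participant, object@session, ":",
      sum(object@retained), "of", d[4], "volumes retained; band",
      paste(object@band, collapse = "-"), "Hz\n")
})

#' Seed-to-voxel Fisher-z connectivity map
#'
#' @slot zgrid 3D array of Fisher-z values (atanh of the voxel-wise Pearson
#'   correlation with the seed mean time course, computed over retained
#'   volumes only; |r| clipped at 1 - 1e-6 so the map stays finite).
#' @slot participant,session,seed identifiers.
#' @slot nRetained number of volumes that entered the correlation.
#' @export
setClass("ConnectivityMap",
  representation(zgrid = "array", participant = "character",
                 session = "character", seed = "character",
                 nRetained = "integer"))

setValidity("ConnectivityMap", function(object) {
  msg <- character()
  if (length(dim(object@zgrid)) != 3L) msg <- c(msg, "zgrid must be 3D")
  if (any(!is.finite(object@zgrid))) msg <- c(msg, "zgrid must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConnectivityMap", function(object) {
  cat("ConnectivityMap", object@participant, object@session, "seed",
      object@seed, ":", paste(dim(object@zgrid), collapse = "x"),
      "; z range", paste(signif(range(object@zgrid), 3), collapse = ".."),
      ";", object@nRetained, "volumes\n")
})

#' Voxel-wise contrast with cluster table
#'
#' @slot stat 3D array of t statistics.
#' @slot contrast label, e.g. `"obese-lean@T0"`.
#' @slot df degrees of freedom of the t map.
#' @slot clusters data.frame of supra-threshold clusters (extent, sign,
#'   peak position, peak value, and after [clusterFdr()] the permutation p
#'   and BH q); carries a `voxels` list-column of linear voxel indices.
#' @export
setClass("ContrastResult",
  representation(stat = "array", contrast = "character", df = "numeric",
                 clusters = "data.frame"))

setValidity("ContrastResult", function(object) {
  if (length(dim(object@stat)) != 3L) "stat must be a 3D array" else TRUE
})

setMethod("show", "ContrastResult", function(object) {
  cat("ContrastResult", object@contrast, "(df =", object@df, "):",
      nrow(object@clusters), "clusters\n")
  if (nrow(object@clusters))
    print(object@clusters[, setdiff(names(object@clusters), "voxels")])
})

#' Leave-one-participant-out prediction result
#'
#' @slot roi feature label.
#' @slot observed,predicted aligned vectors of weight change (kg).
#' @slot folds per-fold coefficients: left-out id, `beta0`, `betaRoi`,
#'   `residualSd` (each fitted on exactly n - 1 records).
#' @slot r Pearson correlation of predicted vs observed.
#' @slot pParametric two-tailed p of the t-transform of `r`.
#' @slot permLow,permHigh chance-interval bounds (5th/95th percentile of
#'   the permutation null).
#' @slot nPerm number of permutations.
#' @slot permMode `"full"` (LOOCV re-run per shuffle) or `"fixed"`
#'   (observed shuffled against fixed predictions).
#' @export
setClass("PredictionResult",
  representation(roi = "character", observed = "numeric",
                 predicted = "numeric", folds = "data.frame", r = "numeric",
                 pParametric = "numeric", permLow = "numeric",
                 permHigh = "numeric", nPerm = "integer",
                 permMode = "character"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (length(object@observed) != length(object@predicted))
    msg <- c(msg, "observed and predicted must be aligned")
  if (length(object@r) == 1L && is.finite(object@r) && abs(object@r) > 1)
    msg <- c(msg, "|r| must not exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult [", object@roi, "]: n =", length(object@observed),
      "\n  r =", signif(object@r, 3),
      ", parametric p =", signif(object@pParametric, 3),
      "\n  chance interval (", object@permMode, ",", object@nPerm,
      "perms): [", round(object@permLow, 2), ",",
      round(object@permHigh, 2), "]\n")
})

#' Hormone-connectivity correlation result
#'
#' @slot x per-participant leptin change per kg body fat lost (ng/ml/kg).
#' @slot y per-participant connectivity change (Fisher z, T8 - T0).
#' @slot rho Pearson correlation of x and y.
#' @slot pParametric two-tailed parametric p.
#' @slot permLow,permHigh permutation chance-interval bounds.
#' @slot nPerm number of permutations.
#' @export
setClass("HormoneStats",
  representation(x = "numeric", y = "numeric", rho = "numeric",
                 pParametric = "numeric", permLow = "numeric",
                 permHigh = "numeric", nPerm = "integer"))

setValidity("HormoneStats", function(object) {
  if (length(object@x) != length(object@y))
    "x and y must be aligned by participant" else TRUE
})

setMethod("show", "HormoneStats", function(object) {
  cat("HormoneStats: n =", length(object@x), ", rho =",
      signif(object@rho, 3), ", p =", signif(object@pParametric, 3),
      ", chance interval [", round(object@permLow, 2), ",",
      round(object@permHigh, 2), "]\n")
})

#' Pipeline configuration
#'
#' Thresholds default to the study's analysis settings: global-signal z
#' threshold 3, framewise-displacement threshold 0.5 mm, voxel-wise cluster-
#' forming p 0.001, cluster-level FDR q 0.05, 10 000 permutations. The
#' interaction-ROI extent threshold defaults to 10 voxels, scaled to the
#' synthetic grid (see the methods vignette).
#'
#' @slot cohort a [CohortSpec-class].
#' @slot bandHz numeric(2) pass band.
#' @slot zGlobal,fdMm outlier thresholds.
#' @slot exclusionMm participant-level peak-motion exclusion threshold.
#' @slot voxelP,clusterQ,interactionExtent cluster inference thresholds.
#' @slot nPermCluster permutations for the cluster extent null.
#' @slot loocvIntercept apply the trained intercept when predicting.
#' @slot featureType `"change"` (z_T8 - z_T0) or `"level"` (z at T0).
#' @slot nPerm permutations for correlation/prediction inference.
#' @slot smoothFwhmMm spatial smoothing applied to z maps (0 = none).
#' @slot rngSeed master seed.
#' @export
setClass("RunConfig",
  representation(cohort = "CohortSpec", bandHz = "numeric",
                 zGlobal = "numeric", fdMm = "numeric",
                 exclusionMm = "numeric", voxelP = "numeric",
                 clusterQ = "numeric", interactionExtent = "numeric",
                 nPermCluster = "numeric", loocvIntercept = "logical",
                 featureType = "character", nPerm = "numeric",
                 smoothFwhmMm = "numeric", rngSeed = "numeric"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@bandHz) != 2L || object@bandHz[1] >= object@bandHz[2])
    msg <- c(msg, "bandHz must be (low, high) with low < high")
  thr <- c(object@zGlobal, object@fdMm, object@exclusionMm, object@voxelP,
           object@clusterQ, object@interactionExtent, object@nPerm,
           object@nPermCluster)
  if (any(thr <= 0)) msg <- c(msg, "all thresholds must be positive")
  if (!object@featureType %in% c("change", "level"))
    msg <- c(msg, "featureType must be 'change' or 'level'")
  if (length(object@rngSeed) != 1L || !is.finite(object@rngSeed))
    msg <- c(msg, "a single finite rngSeed is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: band", paste(object@bandHz, collapse = "-"),
      "Hz; z >", object@zGlobal, "; FD >=", object@fdMm,
      "mm; voxel p <", object@voxelP, "; cluster q <", object@clusterQ,
      "\n  feature:", object@featureType, "; intercept:",
      object@loocvIntercept, ";", object@nPerm, "perms; seed",
      object@rngSeed, "\n")
})
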