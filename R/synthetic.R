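#' Generate a synthetic cohort of participant records
#'
#' Draws phenotypes for `nLean + nObese` participants with planted effect
#' structure. For the obese group, the individual seed-to-ventral-striatum
#' coupling change (Fisher z) is the latent driver: weight change is
#' `weightChangeObeseKg + couplingChangeSlope * (dz - mean dz) + noise`, and
#' the individual leptin-per-kg-fat ratio is drawn jointly with `dz` at
#' correlation `hormoneEffectR`. Lean participants keep a stable coupling
#' and near-zero weight change. Leptin is reported at both sessions for the
#' obese group but only at baseline for lean participants; the same holds
#' for body fat at T8.
#'
#' @param spec a [CohortSpec-class].
#' @return A data.frame with one row per participant: identifiers, group,
#'   weights, body fat, leptin, glycaemia, insulin, the planted Fisher-z
#'   couplings per ROI and session (`z_vstr_T0`, `z_vstr_T8`, `z_dlpfc_T0`,
#'   `z_dlpfc_T8`), a peak head-motion summary (`motion_max_mm`), and
#'   exclusion bookkeeping. Deterministic given `spec@rngSeed`.
#' @examples
#' rec <- generateCohort(CohortSpec(rngSeed = 7))
#' table(rec$group)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(deriveSeed(spec@rngSeed, "cohort"), {
    nL <- spec@nLean
    nO <- spec@nObese
    n <- nL + nO
    group <- c(rep("lean", nL), rep("obese", nO))
    id <- sprintf("sub-%03d", seq_len(n))

    height <- stats::rnorm(n, ifelse(group == "lean", 1.68, 1.63), 0.06)
    weight0 <- ifelse(group == "lean",
                      stats::rnorm(n, 62, 6), stats::rnorm(n, 119, 12))
    weight0 <- pmax(weight0, 40)

    # planted couplings on the Fisher-z scale
    zv0t <- fisherZ(spec@couplingVstrT0[group])
    zv8t <- fisherZ(spec@couplingVstrT8[group])
    zd0t <- fisherZ(spec@couplingDlpfcT0[group])
    zd8t <- fisherZ(spec@couplingDlpfcT8[group])
    traitV <- stats::rnorm(n, 0, spec@couplingTraitSd)
    traitD <- stats::rnorm(n, 0, spec@couplingTraitSd)
    sess <- matrix(stats::rnorm(4 * n, 0, spec@couplingSessionSd), n, 4)

    # obese latent factor u drives both the coupling change and (jointly,
    # at correlation hormoneEffectR) the leptin-per-fat ratio
    u <- stats::rnorm(nO)
    v <- stats::rnorm(nO)
    rho <- spec@hormoneEffectR
    ratio <- spec@ratioMeanNgPerKg +
      spec@ratioSd * (rho * u + sqrt(1 - rho^2) * v)

    dzGroup <- zv8t - zv0t                       # planted mean change
    dz <- dzGroup
    dz[group == "obese"] <- dzGroup[group == "obese"] +
      spec@couplingChangeSd * u

    z_vstr_T0 <- zv0t + traitV + sess[, 1]
    z_vstr_T8 <- zv0t + traitV + dz + sess[, 2]
    z_dlpfc_T0 <- zd0t + traitD + sess[, 3]
    z_dlpfc_T8 <- zd8t + traitD + sess[, 4]

    dw <- numeric(n)
    dw[group == "lean"] <- stats::rnorm(nL, 0, spec@weightChangeLeanSd)
    dzObese <- dz[group == "obese"]
    dw[group == "obese"] <- spec@weightChangeObeseKg +
      spec@couplingChangeSlope * (dzObese - mean(dzGroup[group == "obese"])) +
      stats::rnorm(nO, 0, spec@noiseSdKg)
    weight8 <- weight0 + dw

    fat0 <- ifelse(group == "lean",
                   weight0 * stats::rnorm(n, 0.27, 0.02),
                   weight0 * stats::rnorm(n, 0.52, 0.03))
    fatLoss <- pmax(-spec@fatLossFraction * dw +
                      stats::rnorm(n, 0, spec@fatLossSdKg), 0.5)
    fat8 <- ifelse(group == "obese", pmax(fat0 - fatLoss, 5), NA_real_)

    leptin0 <- pmax(spec@leptinFatIntercept + spec@leptinFatSlope * fat0 +
                      stats::rnorm(n, 0, spec@leptinNoiseSd), 0.5)
    leptin8 <- rep(NA_real_, n)
    ob <- group == "obese"
    leptin8[ob] <- pmax(leptin0[ob] - ratio * (fat0[ob] - fat8[ob]) +
                          stats::rnorm(nO, 0, spec@leptinNoiseSd), 0.5)

    glyc0 <- pmax(stats::rnorm(n, ifelse(ob, 6, 4), ifelse(ob, 1.5, 0.6)), 2)
    glyc8 <- ifelse(ob, pmax(stats::rnorm(n, 5, 1), 2), NA_real_)
    ins0 <- pmax(stats::rnorm(n, ifelse(ob, 28, 4), ifelse(ob, 15, 3)), 1)
    ins8 <- ifelse(ob, pmax(stats::rnorm(n, 10, 4), 1), NA_real_)

    rate <- spec@spikeRate * ifelse(ob, spec@obeseMotionMult, 1)
    nT <- spec@nVolumesAcquired - spec@nDiscard
    motionMax <- 0.25 + stats::rlnorm(n, log(0.1 + 25 * rate), 0.45)

    data.frame(
      id = id, group = group, height_m = height,
      weight_T0_kg = weight0, weight_T8_kg = weight8,
      body_fat_T0_kg = fat0, body_fat_T8_kg = fat8,
      leptin_T0_ngml = leptin0, leptin_T8_ngml = leptin8,
      glycaemia_T0_mmoll = glyc0, glycaemia_T8_mmoll = glyc8,
      insulin_T0_mUll = ins0, insulin_T8_mUll = ins8,
      z_vstr_T0 = z_vstr_T0, z_vstr_T8 = z_vstr_T8,
      z_dlpfc_T0 = z_dlpfc_T0, z_dlpfc_T8 = z_dlpfc_T8,
      dz_vstr_planted = dz,
      motion_max_mm = motionMax, n_volumes = nT,
      excluded = FALSE, exclusion_reason = NA_character_,
      stringsAsFactors = FALSE)
  })
}

#' Flag participants exceeding the head-motion exclusion threshold
#'
#' Participant-level exclusion uses the peak absolute displacement summary
#' (`motion_max_mm`), defaulting to 3.5 mm.
#'
#' @param records cohort data.frame from [generateCohort()].
#' @param thresholdMm exclusion threshold in mm.
#' @return The records with `excluded`/`exclusion_reason` updated.
#' @export
applyExclusions <- function(records, thresholdMm = 3.5) {
  stopifnot(is.data.frame(records), thresholdMm > 0)
  hit <- records$motion_max_mm >= thresholdMm & !records$excluded
  records$excluded[hit] <- TRUE
  records$exclusion_reason[hit] <-
    sprintf("head motion >= %.1f mm", thresholdMm)
  records
}

#' Generate one session's synthetic BOLD run
#'
#' Builds a 4D run on `spec@gridShape` with `nVolumesAcquired - nDiscard`
#' volumes. Seed voxels share a band-limited (0.01-0.1 Hz) latent course
#' `s`; each target-ROI voxel is `r * s + sqrt(1 - r^2) * noise` with
#' band-limited noise, so its expected correlation with the seed mean is
#' the session's planted coupling `r = tanh(z)` taken from the record.
#' White-matter and CSF voxels follow their own slow latent courses;
#' remaining voxels are white noise plus slow polynomial drift. The motion
#' trace is a slow random walk with spikes at the per-group spike rate;
#' spike volumes also receive a global intensity disturbance.
#'
#' @param record a single participant row from [generateCohort()].
#' @param session `"T0"` or `"T8"`.
#' @param spec the [CohortSpec-class] used for the cohort.
#' @return A [BoldRun-class]. Deterministic given `spec@rngSeed`, the
#'   participant id and the session.
#' @examples
#' spec <- CohortSpec(gridShape = c(10L, 10L, 10L), rngSeed = 1)
#' rec <- generateCohort(spec)
#' run <- generateBoldRun(rec[1, ], "T0", spec)
#' dim(runData(run))
#' @export
generateBoldRun <- function(record, session = c("T0", "T8"), spec) {
  session <- match.arg(session)
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  rV <- tanh(record[[paste0("z_vstr_", session)]])
  rD <- tanh(record[[paste0("z_dlpfc_", session)]])
  if (abs(rV) >= 1 || abs(rD) >= 1)
    stop("planted coupling must lie strictly inside (-1, 1)")

  gs <- spec@gridShape
  nT <- as.integer(spec@nVolumesAcquired - spec@nDiscard)
  tr <- spec@trS
  msk <- defaultMasks(gs)
  amp <- 10          # signal amplitude in image units (baseline 1000)

  withSeed(deriveSeed(spec@rngSeed, "bold", record$id, session), {
    nVox <- prod(gs)
    dat <- matrix(stats::rnorm(nVox * nT), nVox, nT)   # unit white noise

    # slow polynomial scanner drift, independent sign per voxel
    tt <- seq(-1, 1, length.out = nT)
    dat <- dat + outer(stats::rnorm(nVox, 0, 0.4), tt) +
      outer(stats::rnorm(nVox, 0, 0.3), tt^2)

    latent <- bandLimitedNoise(nT, tr, 0.01, 0.1, 1L)[, 1]
    iSeed <- which(msk$seed); iV <- which(msk$vstr); iD <- which(msk$dlpfc)
    dat[iSeed, ] <- rep(latent, each = length(iSeed)) +
      matrix(stats::rnorm(length(iSeed) * nT, 0, 0.1), length(iSeed), nT)
    eta <- bandLimitedNoise(nT, tr, 0.01, 0.1, length(iV) + length(iD))
    dat[iV, ] <- rV * rep(latent, each = length(iV)) +
      sqrt(1 - rV^2) * t(eta[, seq_along(iV), drop = FALSE])
    dat[iD, ] <- rD * rep(latent, each = length(iD)) +
      sqrt(1 - rD^2) *
        t(eta[, length(iV) + seq_along(iD), drop = FALSE])

    slow <- bandLimitedNoise(nT, tr, 0.002, 0.02, 2L)
    iW <- which(msk$wm); iC <- which(msk$csf)
    dat[iW, ] <- rep(slow[, 1], each = length(iW)) +
      matrix(stats::rnorm(length(iW) * nT, 0, 0.3), length(iW), nT)
    dat[iC, ] <- rep(slow[, 2], each = length(iC)) +
      matrix(stats::rnorm(length(iC) * nT, 0, 0.3), length(iC), nT)

    motion <- cbind(
      apply(matrix(stats::rnorm(3 * nT, 0, 0.008), nT, 3), 2, cumsum),
      apply(matrix(stats::rnorm(3 * nT, 0, 0.00015), nT, 3), 2, cumsum))
    rate <- spec@spikeRate *
      if (identical(record$group, "obese")) spec@obeseMotionMult else 1
    spikes <- which(stats::runif(nT) < rate)
    spikes <- spikes[spikes > 1L]
    for (sv in spikes) {
      ax <- sample(3L, 1L)
      motion[sv, ax] <- motion[sv, ax] +
        sample(c(-1, 1), 1L) * stats::runif(1, 0.6, 1.5)
      dat[, sv] <- dat[, sv] + 2     # global intensity disturbance
    }

    dat <- 1000 + amp * dat
    dim(dat) <- c(gs, nT)
    new("BoldRun", data = dat, trS = tr, motion = motion,
        affine = diagAffine(spec@voxelSizeMm), masks = msk,
        participant = as.character(record$id), session = session)
  })
}

#' Inject a sustained motion spike into a run
#'
#' Shifts the first translation axis by `magnitudeMm` from `volumeIndex`
#' onward (a step, so framewise displacement spikes once, at the
#' transition) and adds an intensity disturbance to that volume.
#'
#' @param run a [BoldRun-class].
#' @param volumeIndex index of the spiked volume (2..T).
#' @param magnitudeMm spike size in mm; 0 leaves the run unchanged.
#' @return The modified [BoldRun-class].
#' @export
injectMotionSpike <- function(run, volumeIndex, magnitudeMm) {
  stopifnot(is(run, "BoldRun"))
  nT <- dim(run@data)[4]
  if (volumeIndex < 2 || volumeIndex > nT || volumeIndex != round(volumeIndex))
    stop("volumeIndex must be an integer in 2..", nT)
  if (magnitudeMm == 0) return(run)
  run@motion[volumeIndex:nT, 1] <- run@motion[volumeIndex:nT, 1] + magnitudeMm
  run@data[, , , volumeIndex] <- run@data[, , , volumeIndex] +
    2 * magnitudeMm * stats::sd(run@data[, , , volumeIndex])
  run
}

#' Simulate per-participant Fisher-z connectivity maps directly
#'
#' Map-level counterpart of the full image generator, for studying the
#' group-level cluster inference at scale: each map is independent Gaussian
#' noise around a baseline, and group B additionally receives `delta[k]`
#' inside blob `k`. Effect defaults mirror the cohort generator: the
#' group difference in planted ventral-striatum coupling,
#' `atanh(0.30) - atanh(0.10)`, against a between-participant SD of 0.13.
#'
#' @param nA,nB group sizes (A = lean reference, B = obese).
#' @param gridShape integer vector of 3 voxel counts.
#' @param blobs list of logical 3D arrays (may be empty).
#' @param deltas numeric, one group-B offset per blob (Fisher z).
#' @param sd between-participant map SD.
#' @param seed RNG seed.
#' @return List with `maps` (4D array, last axis = participant) and
#'   `group` (factor of "A"/"B").
#' @export
simulateZmaps <- function(nA, nB, gridShape = c(12L, 12L, 12L),
                          blobs = list(), deltas = numeric(),
                          sd = 0.13, seed = 1L) {
  stopifnot(length(blobs) == length(deltas), nA >= 2, nB >= 2)
  gridShape <- as.integer(gridShape)
  withSeed(seed, {
    n <- nA + nB
    maps <- array(stats::rnorm(prod(gridShape) * n, 0, sd),
                  c(gridShape, n))
    if (length(blobs)) {
      for (k in seq_along(blobs)) {
        stopifnot(identical(dim(blobs[[k]]), gridShape))
        idx <- which(blobs[[k]])
        flat <- matrix(maps, prod(gridShape), n)
        flat[idx, nA + seq_len(nB)] <-
          flat[idx, nA + seq_len(nB)] + deltas[k]
        maps <- array(flat, c(gridShape, n))
      }
    }
    list(maps = maps,
         group = factor(rep(c("A", "B"), c(nA, nB)), levels = c("A", "B")))
  })
}
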