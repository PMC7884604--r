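# End-to-end runner: synthetic cohort -> denoised runs -> connectivity
# maps -> group contrasts and ROI selection -> LOOCV prediction and
# hormone correlation, with a manifest auditing the exclusion cascade.

# Deterministic non-cryptographic hash of a config (FNV-1a over its JSON
# serialisation), for the manifest.
configHash <- function(config) {
  s <- jsonlite::toJSON(runConfigAsList(config), auto_unbox = TRUE,
                        digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

runConfigAsList <- function(config) {
  sp <- config@cohort
  cohort <- lapply(slotNames("CohortSpec"), function(s) slot(sp, s))
  names(cohort) <- slotNames("CohortSpec")
  run <- lapply(setdiff(slotNames("RunConfig"), "cohort"),
                function(s) slot(config, s))
  names(run) <- setdiff(slotNames("RunConfig"), "cohort")
  c(run, list(cohort = cohort))
}

# Denoise one run with the config's thresholds; returns the CleanRun and
# the censor count.
denoiseWithConfig <- function(run, config) {
  flags <- detectOutlierVolumes(run, zThresh = config@zGlobal,
                                fdThreshMm = config@fdMm)
  wm <- erodeMask(run@masks$wm, 1L, name = "wm")
  csf <- erodeMask(run@masks$csf, 1L, name = "csf")
  mat <- toVoxelMatrix(run@data)
  design <- buildNuisanceDesign(run@motion,
                                colMeans(mat[which(wm), , drop = FALSE]),
                                colMeans(mat[which(csf), , drop = FALSE]),
                                flags)
  list(clean = denoiseRun(run, design, band = config@bandHz),
       nCensored = sum(flags))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage: cohort generation and motion-based exclusion,
#' per-session BOLD simulation, censoring + nuisance regression +
#' band-stop filtering, seed-to-voxel Fisher-z maps (optionally smoothed),
#' the obese-vs-lean baseline contrast with permutation cluster FDR and
#' ROI selection, the group-by-time interaction ROI, leave-one-
#' participant-out weight-change prediction per selected ROI, the
#' leptin-per-fat hormone correlation over the interaction ROI, and the
#' phenotype change tests. All outputs are written under `outputDir`
#' (TSV tables, JSON summary + manifest, NIfTI maps when
#' `writeVolumes = TRUE`) and returned invisibly.
#'
#' When no baseline cluster survives FDR (possible on small test grids),
#' the generator's planted target masks are substituted as ROIs so the
#' downstream stages still execute; the manifest records this fallback.
#'
#' @param config a [RunConfig-class].
#' @param outputDir output directory (created if needed).
#' @param writeVolumes also write stat maps and ROI masks as NIfTI.
#' @return Invisibly, a list with `records`, `features`, `contrasts`,
#'   `rois`, `prediction`, `hormones`, `changeTests`, `manifest`.
#' @export
runFullPipeline <- function(config, outputDir, writeVolumes = FALSE) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  spec <- config@cohort
  affine <- diagAffine(spec@voxelSizeMm)

  records <- applyExclusions(generateCohort(spec),
                             thresholdMm = config@exclusionMm)
  included <- records[!records$excluded, , drop = FALSE]
  writePhenotypes(records, file.path(outputDir, "phenotypes.tsv"))

  maps <- list(); mapGroup <- character(); mapTime <- character()
  mapPid <- character(); censorCount <- integer(0)
  for (i in seq_len(nrow(included))) {
    rec <- included[i, ]
    for (ses in c("T0", "T8")) {
      run <- generateBoldRun(rec, ses, spec)
      dn <- denoiseWithConfig(run, config)
      cmap <- seedToVoxelMap(dn$clean)
      if (config@smoothFwhmMm > 0)
        cmap@zgrid <- smoothVolume(cmap@zgrid, config@smoothFwhmMm, affine)
      maps[[length(maps) + 1L]] <- cmap
      mapGroup <- c(mapGroup, rec$group)
      mapTime <- c(mapTime, ses)
      mapPid <- c(mapPid, rec$id)
      censorCount <- c(censorCount, dn$nCensored)
    }
  }

  # baseline contrast -> ROI selection (T0 maps only)
  t0 <- fitGroupTimeModel(maps, mapGroup, mapTime, mapPid, "groupT0")
  t0 <- clusterThreshold(t0, voxelP = config@voxelP)
  sel <- mapTime == "T0"
  null0 <- nullMaxExtents(maps[sel], mapGroup[sel],
                          nPerm = config@nPermCluster,
                          voxelP = config@voxelP,
                          seed = deriveSeed(config@rngSeed, "null-T0"))
  t0 <- clusterFdr(t0, null0, q = config@clusterQ)
  rois <- selectObesitySensitiveRois(t0, q = config@clusterQ)
  roiFallback <- length(rois) == 0L
  if (roiFallback) {
    msk <- defaultMasks(spec@gridShape)
    rois <- list(obese_gt_lean_1 = msk$dlpfc, obese_lt_lean_1 = msk$vstr)
  }

  # interaction contrast -> vStr interaction ROI for the hormone analysis
  tI <- fitGroupTimeModel(maps, mapGroup, mapTime, mapPid, "interaction")
  tI <- clusterThreshold(tI, voxelP = config@voxelP)
  tabI <- tI@clusters
  tabI <- tabI[tabI$extent >= config@interactionExtent & tabI$sign > 0, ,
               drop = FALSE]
  if (nrow(tabI)) {
    interactionRoi <- array(FALSE, spec@gridShape)
    interactionRoi[tabI$voxels[[1]]] <- TRUE
  } else {
    interactionRoi <- defaultMasks(spec@gridShape)$vstr
  }

  # scalar features per participant / session / ROI
  featRows <- list()
  roiSet <- c(rois, list(vstr_interaction = interactionRoi))
  for (k in seq_along(maps)) {
    for (rn in names(roiSet)) {
      featRows[[length(featRows) + 1L]] <-
        roiMeanZ(maps[[k]], roiSet[[rn]], rn)
    }
  }
  featLong <- do.call(rbind, featRows)
  writeTsv(featLong, file.path(outputDir, "connectivity_features.tsv"))

  predFeatures <- do.call(rbind, lapply(names(rois), function(rn) {
    f0 <- featLong[featLong$roi == rn & featLong$session == "T0", ]
    f8 <- featLong[featLong$roi == rn & featLong$session == "T8", ]
    z <- if (config@featureType == "change")
      f8$z[match(f0$participant, f8$participant)] - f0$z else f0$z
    data.frame(participant = f0$participant, roi = rn, z = z,
               stringsAsFactors = FALSE)
  }))
  prediction <- predictWeightChange(predFeatures, included,
                                    intercept = config@loocvIntercept,
                                    nPerm = config@nPerm,
                                    seed = deriveSeed(config@rngSeed,
                                                      "loocv"))
  for (rn in names(prediction)) {
    pr <- prediction[[rn]]
    writeTsv(cbind(data.frame(participant = included$id,
                              observed_kg = pr@observed,
                              predicted_kg = pr@predicted), pr@folds),
             file.path(outputDir, paste0("prediction_", rn, ".tsv")))
  }

  fI0 <- featLong[featLong$roi == "vstr_interaction" &
                    featLong$session == "T0", ]
  fI8 <- featLong[featLong$roi == "vstr_interaction" &
                    featLong$session == "T8", ]
  obIds <- included$id[included$group == "obese"]
  yI <- fI8$z[match(obIds, fI8$participant)] -
    fI0$z[match(obIds, fI0$participant)]
  hormones <- hormoneConnectivityCorrelation(
    included, y = yI, nPerm = config@nPerm,
    seed = deriveSeed(config@rngSeed, "hormone"))
  tests <- changeTests(included)
  writeTsv(tests, file.path(outputDir, "change_tests.tsv"))

  clusterTable <- function(cr) {
    tab <- cr@clusters
    tab$voxels <- NULL
    if (nrow(tab)) {
      mm <- t(apply(as.matrix(tab[, c("peak_i", "peak_j", "peak_k")]), 1,
                    function(ijk) (affine %*% c(ijk - 1, 1))[1:3]))
      tab$peak_mm_x <- mm[, 1]; tab$peak_mm_y <- mm[, 2]
      tab$peak_mm_z <- mm[, 3]
    }
    tab
  }
  writeTsv(clusterTable(t0), file.path(outputDir, "clusters_T0.tsv"))
  writeTsv(clusterTable(tI),
           file.path(outputDir, "clusters_interaction.tsv"))

  if (writeVolumes) {
    writeVolume(t0@stat, file.path(outputDir, "tmap_T0.nii.gz"), affine)
    writeVolume(tI@stat,
                file.path(outputDir, "tmap_interaction.nii.gz"), affine)
    for (rn in names(roiSet))
      writeVolume(roiSet[[rn]],
                  file.path(outputDir, paste0("roi_", rn, ".nii.gz")),
                  affine)
  }

  summarise <- function(pr) list(
    r = pr@r, p_parametric = pr@pParametric,
    perm_low = pr@permLow, perm_high = pr@permHigh,
    n_perm = pr@nPerm, outside_chance = pr@r < pr@permLow ||
      pr@r > pr@permHigh)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bariconn")),
    config_hash = configHash(config),
    seed = config@rngSeed,
    participants = list(enrolled = nrow(records),
                        included = nrow(included),
                        excluded = sum(records$excluded)),
    volumes_censored = stats::setNames(as.list(censorCount),
                                       paste(rep(included$id, each = 2),
                                             c("T0", "T8"), sep = "_")),
    clusters_T0 = nrow(t0@clusters),
    clusters_T0_significant = sum(t0@clusters$significant %||% logical()),
    roi_fallback = roiFallback,
    rois = names(rois))
  summary <- list(
    manifest = manifest,
    prediction = lapply(prediction, summarise),
    hormones = list(rho = hormones@rho,
                    p_parametric = hormones@pParametric,
                    perm_low = hormones@permLow,
                    perm_high = hormones@permHigh,
                    n = length(hormones@x)))
  jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, features = featLong,
                 contrasts = list(groupT0 = t0, interaction = tI),
                 rois = roiSet, prediction = prediction,
                 hormones = hormones, changeTests = tests,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
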