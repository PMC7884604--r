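# File formats: NIfTI volumes via RNifti, whitespace-delimited motion
# traces, TSV phenotype tables, 0/1 censor columns, YAML/JSON configs.

#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the voxel-to-mm affine attached.
#' 3D masks are written as 0/1 volumes and read back as logical arrays
#' when `logical = TRUE`.
#'
#' @param x 3D or 4D numeric array (or logical mask).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param logical return a logical array when reading.
#' @return `writeVolume` returns `path` invisibly; `readVolume` a list
#'   with `data` and `affine`.
#' @export
writeVolume <- function(x, path, affine = diag(4)) {
  im <- RNifti::asNifti(x * 1)
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, logical = FALSE) {
  im <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(im), imagedim = NULL, code = NULL)
  dat <- array(as.numeric(im), dim(im))
  if (logical) dat <- dat != 0
  list(data = dat, affine = matrix(aff[1:4, 1:4], 4, 4))
}

#' Read and write rigid-body motion traces
#'
#' Plain-text convention: one row per volume, six whitespace-separated
#' columns — three translations in mm followed by three rotations in rad.
#'
#' @param motion T x 6 matrix.
#' @param path file path.
#' @return `writeMotionTrace` returns `path` invisibly; `readMotionTrace`
#'   the T x 6 matrix.
#' @export
writeMotionTrace <- function(motion, path) {
  stopifnot(ncol(motion) == 6L)
  utils::write.table(format(motion, digits = 10), path,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMotionTrace
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion trace must have 6 columns, found ", ncol(m))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Write censor flags as a 0/1 text column
#'
#' @param flags logical vector (TRUE = censored).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCensorFlags <- function(flags, path) {
  writeLines(as.character(as.integer(flags)), path)
  invisible(path)
}

phenotypeNumericCols <- c(
  "height_m", "weight_T0_kg", "weight_T8_kg", "body_fat_T0_kg",
  "body_fat_T8_kg", "leptin_T0_ngml", "leptin_T8_ngml",
  "glycaemia_T0_mmoll", "glycaemia_T8_mmoll", "insulin_T0_mUll",
  "insulin_T8_mUll", "z_vstr_T0", "z_vstr_T8", "z_dlpfc_T0",
  "z_dlpfc_T8", "dz_vstr_planted", "motion_max_mm", "n_volumes")

#' Write a phenotype table as TSV
#'
#' @param records cohort data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a phenotype TSV
#'
#' Strict validation: required columns present, group labels restricted to
#' lean/obese, numeric cells parseable (errors name the offending row and
#' column), positive weights, obese records complete at both time points.
#' A lean record carrying T8 leptin raises a warning but the value is
#' retained.
#'
#' @param path TSV path written by [writePhenotypes()] (or any file with
#'   the documented columns).
#' @return Validated cohort data.frame.
#' @export
readPhenotypes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "NA")
  required <- c("id", "group", "weight_T0_kg", "weight_T8_kg",
                "leptin_T0_ngml", "body_fat_T0_kg")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(raw$group %in% c("lean", "obese")))
    stop("group must be 'lean' or 'obese'; offending row(s): ",
         paste(which(!raw$group %in% c("lean", "obese")), collapse = ", "))
  out <- raw
  for (cc in intersect(phenotypeNumericCols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(!is.na(raw[[cc]]) & is.na(v))
    if (length(bad))
      stop("malformed numeric value in column '", cc, "', row ", bad[1],
           " ('", raw[[cc]][bad[1]], "')")
    out[[cc]] <- v
  }
  if ("excluded" %in% names(out))
    out$excluded <- as.logical(out$excluded)
  w <- c(out$weight_T0_kg, out$weight_T8_kg)
  if (any(is.finite(w) & w <= 0)) stop("weights must be positive")
  ob <- out$group == "obese"
  if (any(ob & (!is.finite(out$weight_T0_kg) | !is.finite(out$weight_T8_kg))))
    stop("obese records must carry weights at both time points")
  if ("leptin_T8_ngml" %in% names(out)) {
    leanT8 <- out$group == "lean" & is.finite(out$leptin_T8_ngml)
    if (any(leanT8))
      warning("lean record(s) with T8 leptin (retained): ",
              paste(out$id[leanT8], collapse = ", "))
  }
  out
}

#' Default pipeline configuration
#'
#' @param rngSeed master seed.
#' @param cohort a [CohortSpec-class]; defaults to `CohortSpec(rngSeed =
#'   rngSeed)`.
#' @param ... further [RunConfig-class] slot overrides.
#' @return A validated [RunConfig-class].
#' @export
defaultRunConfig <- function(rngSeed = 1L, cohort = NULL, ...) {
  if (is.null(cohort)) cohort <- CohortSpec(rngSeed = rngSeed)
  args <- list(...)
  base <- list(cohort = cohort, bandHz = c(0.01, 0.1), zGlobal = 3,
               fdMm = 0.5, exclusionMm = 3.5, voxelP = 0.001,
               clusterQ = 0.05, interactionExtent = 10,
               nPermCluster = 1000, loocvIntercept = TRUE,
               featureType = "change", nPerm = 10000, smoothFwhmMm = 0,
               rngSeed = rngSeed)
  base[names(args)] <- args
  do.call(new, c(list(Class = "RunConfig"), base))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys raise an error naming them; missing keys fall back to the
#' defaults of [defaultRunConfig()]. Keys matching [CohortSpec()] argument
#' names populate the cohort specification; the remaining keys populate
#' [RunConfig-class] slots.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  vals <- if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                simplifyVector = TRUE)
          else stop("config must be .yaml, .yml or .json")
  if (is.null(vals$rngSeed)) stop("config must provide rngSeed")
  cohortArgs <- names(formals(CohortSpec))
  runArgs <- setdiff(slotNames("RunConfig"), "cohort")
  unknown <- setdiff(names(vals), c(cohortArgs, runArgs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ca <- vals[intersect(names(vals), cohortArgs)]
  if (is.null(ca$rngSeed)) ca$rngSeed <- vals$rngSeed
  cohort <- do.call(CohortSpec, ca)
  ra <- vals[intersect(names(vals), setdiff(runArgs, "rngSeed"))]
  do.call(defaultRunConfig,
          c(list(rngSeed = vals$rngSeed, cohort = cohort), ra))
}
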