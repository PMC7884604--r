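#' Leptin change per kilogram of body fat lost
#'
#' `(leptin_T0 - leptin_T8) / (fat_T0 - fat_T8)` in ng/ml per kg.
#' Participants whose absolute fat change is below `epsilonKg` have an
#' undefined ratio: they are set to NA with a warning (an error if every
#' input is undefined).
#'
#' @param leptinT0,leptinT8 serum leptin, ng/ml.
#' @param fatT0,fatT8 body fat, kg.
#' @param epsilonKg minimal fat change treated as nonzero (default 0.01).
#' @param ids optional participant labels for messages.
#' @return Numeric vector of ratios (ng/ml per kg).
#' @examples
#' leptinPerFatRatio(70, 25, 62, 42)   # 2.25
#' @export
leptinPerFatRatio <- function(leptinT0, leptinT8, fatT0, fatT8,
                              epsilonKg = 0.01, ids = NULL) {
  n <- length(leptinT0)
  stopifnot(length(leptinT8) == n, length(fatT0) == n, length(fatT8) == n,
            epsilonKg > 0)
  dfat <- fatT0 - fatT8
  bad <- !is.finite(dfat) | abs(dfat) < epsilonKg
  if (all(bad))
    stop("fat change below ", epsilonKg,
         " kg for every participant: ratio undefined")
  x <- (leptinT0 - leptinT8) / dfat
  if (any(bad)) {
    if (is.null(ids)) ids <- as.character(seq_len(n))
    warning("undefined leptin/fat ratio (|fat change| < ", epsilonKg,
            " kg) for: ", paste(ids[bad], collapse = ", "))
    x[bad] <- NA_real_
  }
  x
}

#' Connectivity change between sessions
#'
#' Fisher-z difference `z_T8 - z_T0` for one ROI.
#'
#' @param zT0,zT8 Fisher-z features at T0 and T8.
#' @return Numeric vector of changes.
#' @examples
#' connectivityChange(-0.05, 0.11)   # 0.16
#' @export
connectivityChange <- function(zT0, zT8) {
  stopifnot(length(zT0) == length(zT8))
  if (any(!is.finite(zT0)) || any(!is.finite(zT8)))
    stop("both sessions must be present for every participant")
  zT8 - zT0
}

#' Hormone-connectivity correlation
#'
#' Correlates the leptin-per-kg-fat ratio `x` with the connectivity change
#' `y = z_T8 - z_T0` over the obese group, with parametric and permutation
#' inference via [correlationInference()]. Pairs with an undefined ratio
#' are dropped.
#'
#' @param records cohort data.frame; only obese rows with complete hormone
#'   data are used.
#' @param y connectivity changes aligned with the obese rows of `records`;
#'   by default taken from the planted `z_vstr_*` columns when present.
#' @param nPerm,seed passed to [correlationInference()].
#' @return A [HormoneStats-class].
#' @export
hormoneConnectivityCorrelation <- function(records, y = NULL,
                                           nPerm = 10000, seed = 1L) {
  stopifnot(is.data.frame(records))
  ob <- records[records$group == "obese", , drop = FALSE]
  if (is.null(y)) {
    if (!all(c("z_vstr_T0", "z_vstr_T8") %in% names(ob)))
      stop("supply y or records with z_vstr_T0/z_vstr_T8 columns")
    y <- connectivityChange(ob$z_vstr_T0, ob$z_vstr_T8)
  }
  stopifnot(length(y) == nrow(ob))
  x <- leptinPerFatRatio(ob$leptin_T0_ngml, ob$leptin_T8_ngml,
                         ob$body_fat_T0_kg, ob$body_fat_T8_kg, ids = ob$id)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4)
    stop("need at least 4 obese participants with complete data")
  inf <- correlationInference(x[ok], y[ok], nPerm = nPerm, seed = seed)
  new("HormoneStats", x = x[ok], y = y[ok], rho = inf$r,
      pParametric = inf$pParametric, permLow = inf$permLow,
      permHigh = inf$permHigh, nPerm = inf$nPerm)
}

#' Phenotype change tests
#'
#' Two-tailed paired t tests on the obese group (T0 vs T8) for weight,
#' BMI, body fat (kg and percent) and leptin, and two-tailed two-sample
#' (Welch) t tests of lean vs obese at baseline.
#'
#' @param records cohort data.frame from [generateCohort()] /
#'   [readPhenotypes()].
#' @return data.frame with `variable`, `comparison`, `t`, `df`, `p`.
#' @export
changeTests <- function(records) {
  stopifnot(is.data.frame(records))
  ob <- records[records$group == "obese", , drop = FALSE]
  ln <- records[records$group == "lean", , drop = FALSE]
  if (!nrow(ob)) stop("no obese participants")
  bmi <- function(w, h) w / h^2
  fatPct <- function(fat, w) 100 * fat / w
  vals <- list(
    weight_kg = list(t0 = function(d) d$weight_T0_kg,
                     t8 = function(d) d$weight_T8_kg),
    bmi = list(t0 = function(d) bmi(d$weight_T0_kg, d$height_m),
               t8 = function(d) bmi(d$weight_T8_kg, d$height_m)),
    body_fat_kg = list(t0 = function(d) d$body_fat_T0_kg,
                       t8 = function(d) d$body_fat_T8_kg),
    body_fat_pct = list(
      t0 = function(d) fatPct(d$body_fat_T0_kg, d$weight_T0_kg),
      t8 = function(d) fatPct(d$body_fat_T8_kg, d$weight_T8_kg)),
    leptin_ngml = list(t0 = function(d) d$leptin_T0_ngml,
                       t8 = function(d) d$leptin_T8_ngml))
  rows <- list()
  for (v in names(vals)) {
    a <- vals[[v]]$t0(ob); b <- vals[[v]]$t8(ob)
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3) {
      tt <- stats::t.test(b[ok], a[ok], paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, comparison = "obese T8 vs T0 (paired)",
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
    if (nrow(ln)) {
      a0 <- vals[[v]]$t0(ln); b0 <- vals[[v]]$t0(ob)
      if (sum(is.finite(a0)) >= 3 && sum(is.finite(b0)) >= 3) {
        tt2 <- stats::t.test(b0[is.finite(b0)], a0[is.finite(a0)])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, comparison = "obese vs lean at T0 (two-sample)",
          t = unname(tt2$statistic), df = unname(tt2$parameter),
          p = tt2$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
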