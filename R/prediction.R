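#' Weight change per participant
#'
#' T8 minus T0 in kg; negative values are weight loss.
#'
#' @param records cohort data.frame with `weight_T0_kg` and
#'   `weight_T8_kg`.
#' @return Named numeric vector (names = participant ids).
#' @export
weightChange <- function(records) {
  stopifnot(is.data.frame(records))
  w0 <- records$weight_T0_kg
  w8 <- records$weight_T8_kg
  if (is.null(w0) || is.null(w8)) stop("weight columns are missing")
  bad <- !is.finite(w0) | !is.finite(w8)
  if (any(bad))
    stop("missing weight for participant(s): ",
         paste(records$id[bad], collapse = ", "))
  stats::setNames(w8 - w0, records$id)
}

# O(n) closed-form leave-one-out simple-OLS predictions.
loocvPredictions <- function(z, dw, intercept = TRUE) {
  n <- length(z)
  Sx <- sum(z); Sy <- sum(dw); Sxx <- sum(z^2); Sxy <- sum(z * dw)
  m <- n - 1
  sx <- Sx - z; sy <- Sy - dw; sxx <- Sxx - z^2; sxy <- Sxy - z * dw
  den <- sxx - sx^2 / m
  if (any(den <= .Machine$double.eps * pmax(sxx, 1)))
    stop("constant feature in training fold ",
         which(den <= .Machine$double.eps * pmax(sxx, 1))[1])
  b1 <- (sxy - sx * sy / m) / den
  b0 <- sy / m - b1 * sx / m
  if (intercept) b0 + b1 * z else b1 * z
}

#' Leave-one-participant-out prediction of weight change
#'
#' For each participant i, an ordinary least-squares regression of weight
#' change on the scalar connectivity feature is fitted on the other n - 1
#' participants and evaluated at z_i. By default the trained intercept is
#' applied (standard OLS prediction); `intercept = FALSE` reproduces the
#' slope-only prediction form.
#'
#' @param z connectivity features (Fisher z), one per participant.
#' @param dw observed weight changes (kg).
#' @param intercept apply the trained intercept when predicting.
#' @param roi label stored in the result.
#' @param ids optional participant ids.
#' @return A [PredictionResult-class] with `observed`, `predicted` and
#'   per-fold coefficients filled; inference slots are NA until
#'   [predictionInference()] is applied.
#' @examples
#' z <- c(0, 1, 2, 3); dw <- 2 * z + 1
#' predicted(loocvPredict(z, dw))   # equals dw exactly
#' @export
loocvPredict <- function(z, dw, intercept = TRUE, roi = "roi", ids = NULL) {
  stopifnot(length(z) == length(dw))
  n <- length(z)
  if (n < 4) stop("need at least 4 participants")
  if (any(!is.finite(z)) || any(!is.finite(dw)))
    stop("features and weight changes must be finite")
  if (is.null(ids)) ids <- if (!is.null(names(dw))) names(dw)
                           else sprintf("p%02d", seq_len(n))
  pred <- loocvPredictions(z, dw, intercept)
  fold <- do.call(rbind, lapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(cbind(1, z[-i]), dw[-i])
    rsd <- sqrt(sum(fit$residuals^2) / (n - 3))
    data.frame(leftOut = ids[i], beta0 = fit$coefficients[1],
               betaRoi = fit$coefficients[2], residualSd = rsd,
               stringsAsFactors = FALSE)
  }))
  rownames(fold) <- NULL
  attr(fold, "feature") <- as.numeric(z)  # needed to re-run folds in
                                          # permutation mode "full"
  new("PredictionResult", roi = roi, observed = as.numeric(dw),
      predicted = pred, folds = fold, r = NA_real_,
      pParametric = NA_real_, permLow = NA_real_, permHigh = NA_real_,
      nPerm = 0L, permMode = NA_character_)
}

#' Two-tailed p value of a Pearson correlation via the t transform
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#'
#' @param r Pearson correlation.
#' @param n sample size.
#' @return Two-tailed p value.
#' @examples
#' correlationPValue(0.58, 14)   # ~0.03
#' @export
correlationPValue <- function(r, n) {
  stopifnot(n > 2, abs(r) <= 1)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Correlation with parametric and permutation inference
#'
#' Pearson correlation of two vectors with (i) the two-tailed parametric p
#' from the t transform and (ii) a permutation chance interval: `b` is
#' randomly shuffled `nPerm` times against fixed `a` and the requested
#' percentiles (default 5th/95th) of the permuted correlations are
#' reported. These percentile bounds match the study's printed "95% CI due
#' to chance" (about 1.65/sqrt(n - 1) at moderate n).
#'
#' @param a,b numeric vectors of equal length (n >= 4), non-constant.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed for the shuffles.
#' @param probs percentile pair for the chance interval.
#' @return List with `r`, `pParametric`, `permLow`, `permHigh`, `nPerm`.
#' @export
correlationInference <- function(a, b, nPerm = 10000, seed = 1L,
                                 probs = c(0.05, 0.95)) {
  stopifnot(length(a) == length(b), length(probs) == 2)
  n <- length(a)
  if (n < 4) stop("need at least 4 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("inputs must be non-constant")
  r <- stats::cor(a, b)
  rs <- withSeed(seed, vapply(seq_len(nPerm),
                              function(i) stats::cor(a, sample(b)),
                              numeric(1)))
  bounds <- stats::quantile(rs, probs, names = FALSE)
  list(r = r, pParametric = correlationPValue(r, n),
       permLow = bounds[1], permHigh = bounds[2], nPerm = as.integer(nPerm))
}

#' Quantiles of the permutation null of the Pearson correlation
#'
#' Draws `nDatasets` pairs of independent standard-normal vectors of
#' length `n`, shuffles one member of each pair `nPerm` times, and returns
#' the requested quantiles of the pooled permuted correlations. With
#' `nDatasets = 1` this is the study's chance-interval construction for a
#' single data set; pooling many data sets estimates the unconditional
#' null quantile (closed form `q_p = t_p / sqrt(t_p^2 + n - 2)`, about
#' `1.65 / sqrt(n - 1)` at the 95th percentile).
#'
#' @param n sample size.
#' @param nPerm shuffles per data set.
#' @param seed RNG seed.
#' @param probs quantiles to report.
#' @param nDatasets number of independent data sets pooled.
#' @return Named numeric vector of quantiles.
#' @examples
#' permutationNullQuantile(44, nPerm = 2000, seed = 1)
#' @export
permutationNullQuantile <- function(n, nPerm = 10000, seed = 1L,
                                    probs = c(0.05, 0.95),
                                    nDatasets = 1L) {
  stopifnot(n >= 4, nPerm >= 1, nDatasets >= 1)
  withSeed(seed, {
    rs <- unlist(lapply(seq_len(nDatasets), function(d) {
      a <- stats::rnorm(n)
      b <- stats::rnorm(n)
      ac <- a - mean(a)
      va <- sum(ac^2)
      vapply(seq_len(nPerm), function(i) {
        bs <- b[sample.int(n)]
        bc <- bs - mean(bs)
        sum(ac * bc) / sqrt(va * sum(bc^2))
      }, numeric(1))
    }))
    stats::quantile(rs, probs, names = TRUE)
  })
}

#' Permutation inference for a leave-one-out prediction
#'
#' Fills the inference slots of a [PredictionResult-class]: Pearson r of
#' predicted vs observed, its parametric p, and a permutation chance
#' interval. Mode `"full"` (default) re-runs the entire leave-one-out
#' regression for every shuffled observed vector, so the null distribution
#' is that of the complete statistic and the interval is exactly
#' calibrated; mode `"fixed"` shuffles the observed values against the
#' fixed predictions (the simple convention; see the methods vignette for
#' why it is biased for cross-validated predictions).
#'
#' @param fit a [PredictionResult-class] from [loocvPredict()].
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param permMode `"full"` or `"fixed"`.
#' @param intercept intercept setting used when re-fitting in mode
#'   `"full"` (use the same value as in [loocvPredict()]).
#' @param probs percentile pair for the chance interval.
#' @return The completed [PredictionResult-class].
#' @export
predictionInference <- function(fit, nPerm = 10000, seed = 1L,
                                permMode = c("full", "fixed"),
                                intercept = TRUE, probs = c(0.05, 0.95)) {
  stopifnot(is(fit, "PredictionResult"))
  permMode <- match.arg(permMode)
  obs <- fit@observed
  prd <- fit@predicted
  n <- length(obs)
  r <- stats::cor(prd, obs)
  rs <- withSeed(seed, {
    if (permMode == "fixed") {
      vapply(seq_len(nPerm), function(i) stats::cor(prd, sample(obs)),
             numeric(1))
    } else {
      zf <- attr(fit@folds, "feature")
      if (is.null(zf)) stop("feature vector unavailable for mode 'full'")
      vapply(seq_len(nPerm), function(i) {
        ys <- sample(obs)
        stats::cor(loocvPredictions(zf, ys, intercept), ys)
      }, numeric(1))
    }
  })
  bounds <- stats::quantile(rs, probs, names = FALSE)
  fit@r <- r
  fit@pParametric <- correlationPValue(r, n)
  fit@permLow <- bounds[1]
  fit@permHigh <- bounds[2]
  fit@nPerm <- as.integer(nPerm)
  fit@permMode <- permMode
  fit
}

#' Predict weight change from ROI connectivity features
#'
#' Runs the leave-one-participant-out prediction and its permutation
#' inference once per ROI. Features may be connectivity changes
#' (z_T8 - z_T0) or baseline levels, one value per participant per ROI.
#'
#' @param features data.frame with columns `participant`, `roi`, `z`.
#' @param records cohort data.frame (for [weightChange()]).
#' @param intercept apply the trained intercept when predicting.
#' @param nPerm,seed,permMode passed to [predictionInference()].
#' @return Named list of [PredictionResult-class], one per ROI.
#' @export
predictWeightChange <- function(features, records, intercept = TRUE,
                                nPerm = 10000, seed = 1L,
                                permMode = c("full", "fixed")) {
  permMode <- match.arg(permMode)
  stopifnot(is.data.frame(features),
            all(c("participant", "roi", "z") %in% names(features)))
  dw <- weightChange(records)
  out <- list()
  for (roi in unique(features$roi)) {
    ft <- features[features$roi == roi, ]
    if (any(duplicated(ft$participant)))
      stop("duplicate feature rows for ROI '", roi, "'")
    miss <- setdiff(names(dw), ft$participant)
    if (length(miss))
      stop("ROI '", roi, "' lacks features for: ",
           paste(miss, collapse = ", "))
    z <- ft$z[match(names(dw), ft$participant)]
    fit <- loocvPredict(z, dw, intercept = intercept, roi = roi,
                        ids = names(dw))
    out[[roi]] <- predictionInference(fit, nPerm = nPerm,
                                      seed = deriveSeed(seed, roi),
                                      permMode = permMode,
                                      intercept = intercept)
  }
  out
}
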