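test_that("weight change is T8 minus T0 with strict missingness", {
  rec <- data.frame(id = c("a", "b"), weight_T0_kg = c(119, 60),
                    weight_T8_kg = c(85, 60))
  expect_equal(unname(weightChange(rec)), c(-34, 0))
  rec$weight_T8_kg[2] <- NA
  expect_error(weightChange(rec), "b")
})

test_that("leave-one-out predictions match the brute-force fold oracle", {
  z <- c(0, 1, 2, 3)
  dw <- c(0, 1, 2, 10)
  fit <- loocvPredict(z, dw)
  expect_equal(predicted(fit), oracleLoocv(z, dw), tolerance = 1e-10)
  fit0 <- loocvPredict(z, dw, intercept = FALSE)
  expect_equal(predicted(fit0), oracleLoocv(z, dw, intercept = FALSE),
               tolerance = 1e-10)
  # a larger random problem, both intercept settings
  set.seed(17)
  z2 <- rnorm(23); dw2 <- 1.5 - 4 * z2 + rnorm(23)
  expect_equal(predicted(loocvPredict(z2, dw2)), oracleLoocv(z2, dw2),
               tolerance = 1e-10)
  expect_equal(predicted(loocvPredict(z2, dw2, intercept = FALSE)),
               oracleLoocv(z2, dw2, intercept = FALSE), tolerance = 1e-10)
  # every fold is fitted on exactly n - 1 records
  expect_equal(nrow(folds(fit)), 4L)
})

test_that("noiseless linear data are predicted exactly", {
  z <- seq(-1, 2, length.out = 8)
  dw <- 2 * z + 1
  fit <- loocvPredict(z, dw)
  expect_equal(predicted(fit), dw, tolerance = 1e-10)
  expect_equal(cor(predicted(fit), observed(fit)), 1, tolerance = 1e-12)
  expect_equal(folds(fit)$betaRoi, rep(2, 8), tolerance = 1e-10)
})

test_that("a participant's own pairing never enters their fold", {
  set.seed(5)
  z <- rnorm(12); dw <- rnorm(12)
  p1 <- predicted(loocvPredict(z, dw))
  dw2 <- dw; dw2[4] <- dw2[4] + 100
  p2 <- predicted(loocvPredict(z, dw2))
  expect_equal(p1[4], p2[4], tolerance = 1e-10)  # fold 4 unchanged
  expect_false(isTRUE(all.equal(p1[-4], p2[-4])))
})

test_that("degenerate folds are reported", {
  expect_error(loocvPredict(c(1, 1, 1, 2), rnorm(4)), "constant")
  expect_error(loocvPredict(1:3, 1:3), "at least 4")
})

test_that("the t-transform p value reproduces printed correlation tests", {
  expect_equal(round(correlationPValue(0.58, 14), 2), 0.03)
  expect_equal(round(correlationPValue(0.68, 14), 3), 0.007)
  # closed-form identity with cor.test
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(correlationPValue(cor(a, b), 20),
               cor.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("permutation null of r has the expected moments and quantile", {
  set.seed(8)
  n <- 44
  a <- rnorm(n); b <- rnorm(n)
  inf <- correlationInference(a, b, nPerm = 5000, seed = 2)
  expect_lt(abs(inf$r - cor(a, b)), 1e-12)
  # closed-form 95th percentile of the exact null:
  # t95 / sqrt(t95^2 + n - 2)
  t95 <- qt(0.95, n - 2)
  q95 <- t95 / sqrt(t95^2 + n - 2)
  expect_lt(abs(inf$permHigh - q95), 0.03)
  expect_lt(abs(inf$permLow + q95), 0.03)
  # identity case: r = 1 while the chance bounds stay at their null size,
  # untouched by the observed correlation
  infSame <- correlationInference(a, a, nPerm = 5000, seed = 3)
  expect_equal(infSame$r, 1)
  expect_lt(abs(infSame$permHigh - q95), 0.05)
  expect_lt(abs(infSame$permLow + q95), 0.05)
  expect_error(correlationInference(a, rep(1, n)), "non-constant")
})

test_that("full-permutation inference calibrates the chance interval", {
  # under a null feature the full-LOOCV permutation interval contains the
  # observed statistic at its nominal 90% rate; the fixed-prediction
  # interval is biased for LOOCV output (see the methods vignette)
  set.seed(31)
  inside <- vapply(1:60, function(k) {
    z <- rnorm(20); dw <- rnorm(20, 0, 5)
    fit <- loocvPredict(z, dw)
    fit <- predictionInference(fit, nPerm = 300, seed = k,
                               permMode = "full")
    fit@r >= fit@permLow && fit@r <= fit@permHigh
  }, logical(1))
  expect_gte(mean(inside), 0.75)   # nominal 0.90, binomial n = 60
  # perm_low < 0 < perm_high
  z <- rnorm(30); dw <- rnorm(30)
  fit <- predictionInference(loocvPredict(z, dw), nPerm = 500, seed = 1)
  expect_lt(fit@permLow, 0)
  expect_gt(fit@permHigh, 0)
})

test_that("per-ROI pipeline separates a planted feature from a null one", {
  # the null-ROI containment is a 90%-coverage event per cohort, so the
  # dissociation is asserted as a rate over 20 cohorts
  hits <- vapply(1:20, function(k) {
    rec <- generateCohort(CohortSpec(rngSeed = 600L + k))
    features <- rbind(
      data.frame(participant = rec$id, roi = "vstr",
                 z = rec$z_vstr_T8 - rec$z_vstr_T0),
      data.frame(participant = rec$id, roi = "dlpfc",
                 z = rec$z_dlpfc_T8 - rec$z_dlpfc_T0))
    res <- predictWeightChange(features, rec, nPerm = 400,
                               seed = 600L + k)
    c(vstr = res$vstr@r > res$vstr@permHigh,
      vstrP = res$vstr@pParametric < 0.001,
      dlpfc = res$dlpfc@r >= res$dlpfc@permLow &&
        res$dlpfc@r <= res$dlpfc@permHigh)
  }, logical(3))
  expect_gte(mean(hits["vstr", ]), 0.8)    # planted effect detected
  expect_gte(mean(hits["vstrP", ]), 0.8)
  expect_gte(mean(hits["dlpfc", ]), 0.7)   # nominal 90% containment
})
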