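test_that("cohort has the requested composition and is reproducible", {
  spec <- CohortSpec(rngSeed = 11L)
  rec <- generateCohort(spec)
  expect_equal(nrow(rec), 44L)
  expect_equal(sum(rec$group == "lean"), 30L)
  expect_equal(sum(rec$group == "obese"), 14L)
  expect_identical(rec, generateCohort(spec))
  # lean hormone sampling happens at baseline only
  expect_true(all(is.na(rec$leptin_T8_ngml[rec$group == "lean"])))
  expect_true(all(is.finite(rec$leptin_T0_ngml)))
  expect_true(all(rec$weight_T0_kg > 0 & rec$weight_T8_kg > 0))
})

test_that("zero noise and zero slope collapse obese weight change to the group offset", {
  spec <- CohortSpec(noiseSdKg = 0, couplingChangeSlope = 0, rngSeed = 3L)
  rec <- generateCohort(spec)
  dw <- weightChange(rec[rec$group == "obese", ])
  expect_equal(unname(dw), rep(spec@weightChangeObeseKg, 14), tolerance = 1e-12)
})

test_that("leptin change tracks fat change exactly as noise vanishes", {
  # ratio 1 ng/ml/kg keeps every leptin value above the physiological
  # floor so the linear relation is exact
  spec <- CohortSpec(leptinNoiseSd = 0, ratioSd = 0,
                     ratioMeanNgPerKg = 1, rngSeed = 5L)
  rec <- generateCohort(spec)
  ob <- rec[rec$group == "obese", ]
  dlep <- ob$leptin_T0_ngml - ob$leptin_T8_ngml
  dfat <- ob$body_fat_T0_kg - ob$body_fat_T8_kg
  expect_equal(cor(dlep, dfat), 1, tolerance = 1e-10)
  expect_equal(dlep / dfat, rep(spec@ratioMeanNgPerKg, nrow(ob)),
               tolerance = 1e-10)
})

test_that("default runs carry 299 volumes with a matching motion trace", {
  spec <- CohortSpec(gridShape = c(8L, 8L, 8L), rngSeed = 2L)
  rec <- generateCohort(spec)
  run <- generateBoldRun(rec[1, ], "T0", spec)
  expect_equal(dim(runData(run))[4], 299L)  # 304 acquired - 5 discarded
  expect_equal(nrow(motionTrace(run)), 299L)
  expect_identical(runData(run),
                   runData(generateBoldRun(rec[1, ], "T0", spec)))
  # a different session gives a different realisation
  expect_false(identical(runData(run),
                         runData(generateBoldRun(rec[1, ], "T8", spec))))
})

test_that("planted seed-ROI coupling is calibrated across replicates", {
  # Monte-Carlo check: mean empirical seed-ROI r over 100 seeded
  # replicates within +/- 0.02 of the planted r = 0.5 at T = 299.
  # artifact-free runs: the calibration claim concerns the planted
  # coupling itself, not the (censorable) spike disturbances
  target <- 0.5
  rs <- vapply(seq_len(100), function(k) {
    spec <- CohortSpec(gridShape = c(8L, 8L, 8L), spikeRate = 0,
                       rngSeed = 1000L + k)
    rec <- generateCohort(spec)
    rec$z_vstr_T0[1] <- atanh(target)
    run <- generateBoldRun(rec[1, ], "T0", spec)
    mat <- matrix(runData(run), prod(dim(runData(run))[1:3]),
                  dim(runData(run))[4])
    s <- colMeans(mat[which(masks(run)$seed), , drop = FALSE])
    mean(cor(s, t(mat[which(masks(run)$vstr), , drop = FALSE])))
  }, numeric(1))
  expect_lt(abs(mean(rs) - target), 0.02)
})

test_that("null coupling yields near-zero empirical correlation", {
  spec <- CohortSpec(gridShape = c(8L, 8L, 8L), spikeRate = 0,
                     rngSeed = 77L)
  rec <- generateCohort(spec)
  rec$z_vstr_T0[1] <- 0
  run <- generateBoldRun(rec[1, ], "T0", spec)
  mat <- matrix(runData(run), prod(dim(runData(run))[1:3]), 299)
  s <- colMeans(mat[which(masks(run)$seed), , drop = FALSE])
  r <- mean(cor(s, t(mat[which(masks(run)$vstr), , drop = FALSE])))
  expect_lt(abs(r), 2 / sqrt(299))
})

test_that("injected motion spikes behave as sustained steps", {
  run <- makeStillRun()
  spiked <- injectMotionSpike(run, 40L, 1.2)
  fd <- framewiseDisplacement(motionTrace(spiked))
  expect_gte(fd[40], 1.2)
  # zero magnitude is the identity
  expect_identical(injectMotionSpike(run, 40L, 0), run)
  # two spikes on a still trace: exactly two volumes exceed 0.5 mm FD
  two <- injectMotionSpike(injectMotionSpike(run, 20L, 0.9), 55L, 0.7)
  fd2 <- framewiseDisplacement(motionTrace(two))
  expect_equal(sum(fd2 >= 0.5), 2L)
  expect_equal(which(fd2 >= 0.5), c(20L, 55L))
  expect_error(injectMotionSpike(run, 1L, 1), "volumeIndex")
  expect_error(injectMotionSpike(run, 999L, 1), "volumeIndex")
})

test_that("regressing weight change on the planted coupling change recovers the slope", {
  # pool 20 cohorts so the planted beta is estimated with a usable SE
  recs <- do.call(rbind, lapply(1:20, function(k)
    generateCohort(CohortSpec(rngSeed = 100L + k))))
  ob <- recs[recs$group == "obese", ]
  fit <- summary(lm(
    weightChange(ob) ~ ob$dz_vstr_planted))$coefficients
  est <- fit[2, 1]; se <- fit[2, 2]
  expect_lt(abs(est - (-30)), 2 * se)
})

test_that("motion-based exclusion flags heavy movers", {
  rec <- generateCohort(CohortSpec(rngSeed = 4L))
  rec$motion_max_mm[c(2, 5, 9, 20, 40)] <- c(3.6, 4.2, 5.0, 3.5, 7.1)
  rec$motion_max_mm[-c(2, 5, 9, 20, 40)] <- 0.8
  out <- applyExclusions(rec, thresholdMm = 3.5)
  expect_equal(sum(out$excluded), 5L)
  expect_true(all(grepl("head motion", out$exclusion_reason[out$excluded])))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(CohortSpec(nLean = 0), "positive")
  expect_error(CohortSpec(nDiscard = 400), "nDiscard")
  expect_error(CohortSpec(couplingVstrT0 = c(lean = 1.2, obese = 0.1)),
               "couplings")
  expect_error(CohortSpec(noiseSdKg = -1), "non-negative")
})
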