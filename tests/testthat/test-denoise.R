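test_that("framewise displacement follows the backward-difference convention", {
  m <- matrix(0, 6, 6)
  expect_equal(framewiseDisplacement(m), rep(0, 6))
  # translation step of (0.2, 0.2, 0.1) mm
  m2 <- m; m2[4:6, 1] <- 0.2; m2[4:6, 2] <- 0.2; m2[4:6, 3] <- 0.1
  expect_equal(framewiseDisplacement(m2)[4], 0.5)
  # 0.01 rad rotation step on one axis = 0.5 mm on a 50 mm sphere
  m3 <- m; m3[3:6, 5] <- 0.01
  expect_equal(framewiseDisplacement(m3)[3], 0.5)
  expect_equal(framewiseDisplacement(m3)[4], 0)
  # invariance to a constant offset of the whole trace
  expect_equal(framewiseDisplacement(m2 + 1.7),
               framewiseDisplacement(m2))
  expect_error(framewiseDisplacement(m[1, , drop = FALSE]), "at least 2")
})

test_that("outlier detection censors motion spikes and global intensity spikes", {
  run <- makeStillRun()
  expect_equal(sum(detectOutlierVolumes(run)), 0L)
  spiked <- injectMotionSpike(run, 33L, 1.2)
  expect_true(detectOutlierVolumes(spiked)[33])
  # raise one volume's mean intensity by 4 SD of the volume-mean series
  bumped <- run
  g <- colMeans(matrix(runData(run), prod(dim(runData(run))[1:3]), 80))
  bumped@data[, , , 50] <- bumped@data[, , , 50] + 4 * sd(g)
  expect_true(detectOutlierVolumes(bumped)[50])
})

test_that("nuisance design carries 18 motion columns plus tissue, trends and spikes", {
  nT <- 50L
  motion <- matrix(rnorm(nT * 6, 0, 0.01), nT, 6)
  flags <- rep(FALSE, nT); flags[c(10, 30)] <- TRUE
  des <- buildNuisanceDesign(motion, rnorm(nT), rnorm(nT), flags)
  expect_equal(ncol(designMatrix(des)), 18L + 2L + 2L + 2L)
  # each spike indicator is one-hot
  X <- designMatrix(des)
  expect_equal(unname(colSums(X[, grepl("^spike_", colnames(X))])),
               c(1, 1))
  expect_equal(unname(X[10, "spike_10"]), 1)
  # derivatives pad the first row with zero
  expect_equal(unname(X[1, grepl("^d", colnames(X))]), rep(0, 12))
  expect_error(buildNuisanceDesign(motion, rnorm(10), rnorm(nT), flags),
               "length")
})

test_that("erosion matches a brute-force morphology oracle on a cube", {
  gs <- c(9L, 9L, 9L)
  cube <- array(FALSE, gs); cube[3:7, 3:7, 3:7] <- TRUE
  er <- erodeMask(cube, 1L)
  # independent oracle: voxel survives iff all 6 face neighbours inside
  oracle <- array(FALSE, gs)
  for (i in 2:8) for (j in 2:8) for (k in 2:8) {
    oracle[i, j, k] <- cube[i, j, k] &&
      cube[i - 1, j, k] && cube[i + 1, j, k] &&
      cube[i, j - 1, k] && cube[i, j + 1, k] &&
      cube[i, j, k - 1] && cube[i, j, k + 1]
  }
  expect_identical(er, oracle)
  expect_equal(sum(er), 27L)           # 5^3 cube erodes to 3^3
  expect_identical(erodeMask(cube, 0L), cube)
  # anti-extensive
  expect_true(all(cube[er]))
  one <- array(FALSE, gs); one[5, 5, 5] <- TRUE
  expect_error(erodeMask(one, 1L, name = "wm"), "wm")
})

test_that("simultaneous regression removes nuisance and out-of-band signal", {
  spec <- smallSpec(seed = 21L)
  rec <- generateCohort(spec)
  run <- generateBoldRun(rec[1, ], "T0", spec)
  nT <- dim(runData(run))[4]
  tt <- seq_len(nT) * spec@trS
  # plant a pure 0.2 Hz sinusoid (outside the 0.01-0.1 Hz band) and a
  # voxel equal to a design column
  run@data[1, 1, 1, ] <- 100 * sin(2 * pi * 0.2 * tt)
  flags <- detectOutlierVolumes(run)
  mat <- matrix(runData(run), 1000, nT)
  des <- buildNuisanceDesign(motionTrace(run),
                             colMeans(mat[which(masks(run)$wm), ]),
                             colMeans(mat[which(masks(run)$csf), ]),
                             flags)
  run@data[2, 1, 1, ] <- designMatrix(des)[, "mot_tx"]
  clean <- denoiseRun(run, des)
  keep <- retained(clean)

  res <- matrix(runData(clean), 1000, nT)
  # out-of-band sinusoid: residual variance < 5% of input variance
  expect_lt(var(res[1, keep]) / var(mat[1, keep]), 0.05)
  # design-column voxel: residual ~ 0
  expect_lt(max(abs(res[2, keep])), 1e-8 * sd(mat[2, keep]))
  # orthogonality of residuals to every design column over retained rows
  X <- designMatrix(des)[keep, ]
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  cors <- abs(cor(t(res[3:100, keep]), X))
  expect_lt(max(cors), 1e-6)
})

test_that("in-band signal survives denoising and broadband power is band-stopped", {
  # full-length runs (T = 299): with ~25 nuisance regressors the chance
  # projection of an in-band voxel onto the design stays small
  spec <- CohortSpec(gridShape = c(8L, 8L, 8L), rngSeed = 22L)
  rec <- generateCohort(spec)
  run <- generateBoldRun(rec[1, ], "T0", spec)
  nT <- dim(runData(run))[4]
  set.seed(9)
  # in-band signal expressed in the filter's own cosine basis (a signal
  # band-limited in another basis leaks into the stop band at the edges)
  kk <- 1:(nT - 1)
  ff <- kk / (2 * nT * spec@trS)
  keep <- ff >= 0.02 & ff <= 0.09
  Bin <- cos(outer(seq_len(nT) - 0.5, kk[keep]) * (pi / nT))
  inband <- drop(Bin %*% rnorm(sum(keep)))
  broadband <- rnorm(nT)
  flags <- rep(FALSE, nT)   # keep the full grid for a clean spectrum
  mat0 <- matrix(runData(run), 512, nT)
  des <- buildNuisanceDesign(motionTrace(run),
                             colMeans(mat0[which(masks(run)$wm), ]),
                             colMeans(mat0[which(masks(run)$csf), ]),
                             flags)
  # the contract concerns in-band signal orthogonal to the design
  inband <- qr.resid(qr(cbind(1, designMatrix(des))), inband)
  run@data[1, 1, 1, ] <- 50 * inband
  run@data[2, 1, 1, ] <- 50 * broadband
  mat <- matrix(runData(run), 512, nT)
  clean <- denoiseRun(run, des)
  res <- matrix(runData(clean), 512, nT)
  # band-limited voxel nearly untouched
  expect_gt(cor(res[1, ], mat[1, ]), 0.95)
  # out-of-band spectral power of a broadband voxel attenuated >= 20x
  pw <- function(x) {
    p <- Mod(fft(x))^2 / length(x)
    f <- (seq_along(x) - 1) / (length(x) * spec@trS)
    f <- pmin(f, 1 / spec@trS - f)
    sum(p[f < 0.01 | f > 0.1])
  }
  expect_gt(pw(mat[2, ]) / pw(res[2, ]), 20)
})

test_that("degenerate designs are reported", {
  run <- makeStillRun(nT = 80L)
  flags <- rep(FALSE, 80L)
  mat <- matrix(runData(run), prod(dim(runData(run))[1:3]), 80)
  des <- buildNuisanceDesign(motionTrace(run),
                             colMeans(mat[which(masks(run)$wm), ]),
                             colMeans(mat[which(masks(run)$csf), ]),
                             flags)
  # a still trace makes all 18 motion-derived columns constant
  expect_warning(denoiseRun(run, des), "zero-variance")
  # censoring almost everything leaves the fit under-determined
  flags2 <- rep(TRUE, 80L); flags2[1:20] <- FALSE
  des2 <- buildNuisanceDesign(motionTrace(run), rnorm(80), rnorm(80),
                              flags2)
  expect_error(denoiseRun(run, des2), "under-determined")
})

test_that("Gaussian smoothing preserves constants and matches the kernel at an impulse", {
  gs <- c(15L, 15L, 15L)
  aff <- diag(c(3, 3, 3, 1))
  cst <- array(7, gs)
  expect_equal(smoothVolume(cst, 8, aff), cst, tolerance = 1e-12)
  expect_identical(smoothVolume(cst, 0, aff), cst)
  imp <- array(0, gs); imp[8, 8, 8] <- 1
  sm <- smoothVolume(imp, 8, aff)
  # oracle: centre weight of the normalised discrete 1D kernel, cubed
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  expect_equal(sm[8, 8, 8], k[r + 1]^3, tolerance = 1e-10)
  # interior intensity conserved
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  expect_error(smoothVolume(imp, 8, diag(c(0, 3, 3, 1))), "spacing")
})
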