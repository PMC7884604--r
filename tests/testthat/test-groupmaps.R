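test_that("two-sample contrast behaves like a t statistic", {
  gs <- c(6L, 6L, 6L)
  set.seed(101)
  base <- array(rnorm(prod(gs) * 8), c(gs, 8))
  maps <- abind_local(base, base)   # identical maps in both groups
  grp <- rep(c("lean", "obese"), each = 8)
  tim <- rep("T0", 16)
  res <- fitGroupTimeModel(maps, grp, tim, contrast = "groupT0")
  expect_equal(max(abs(statGrid(res))), 0)
  expect_equal(res@df, 14)

  sim <- simulateZmaps(6, 6, gs, seed = 7)
  grp2 <- c(rep("lean", 6), rep("obese", 6))
  t1 <- fitGroupTimeModel(sim$maps, grp2, rep("T0", 12),
                          contrast = "groupT0")
  t2 <- fitGroupTimeModel(sim$maps, rev(grp2), rep("T0", 12),
                          contrast = "groupT0")
  # swapping the group labels negates the t map
  expect_equal(statGrid(t1), -statGrid(t2), tolerance = 1e-12)
})

test_that("planted group offsets produce the expected in-blob t values", {
  gs <- c(8L, 8L, 8L)
  blob <- array(FALSE, gs); blob[3:5, 3:5, 3:5] <- TRUE
  delta <- 1; sdv <- 0.5; npg <- 5
  tin <- vapply(1:30, function(k) {
    sim <- simulateZmaps(npg, npg, gs, list(blob), delta, sd = sdv,
                         seed = 500 + k)
    res <- fitGroupTimeModel(sim$maps,
                             ifelse(sim$group == "A", "lean", "obese"),
                             rep("T0", 2 * npg), contrast = "groupT0")
    mean(statGrid(res)[blob])
  }, numeric(1))
  # exact oracle for the mean of a noncentral t with df = 2 npg - 2:
  # E[t] = ncp * sqrt(df / 2) * gamma((df - 1) / 2) / gamma(df / 2)
  ncp <- delta / (sdv * sqrt(2 / npg))
  df <- 2 * npg - 2
  expected <- ncp * sqrt(df / 2) * gamma((df - 1) / 2) / gamma(df / 2)
  expect_lt(abs(mean(tin) - expected),
            2 * sd(tin) / sqrt(length(tin)) + 0.1)
})

test_that("cluster extraction matches an independent connected-components oracle", {
  gs <- c(7L, 7L, 7L)
  stat <- array(0, gs)
  stat[2:3, 2:3, 2] <- 10          # 8-voxel blob, plus 2 more below
  stat[2:3, 2:3, 3] <- 10
  cl <- clusterThreshold(stat, df = 20, voxelP = 0.001)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$extent, 8L)
  expect_equal(cl$sign, 1)

  # two blobs touching only at a corner: 2 clusters at 6-connectivity,
  # 1 at 26-connectivity; verify both against the igraph oracle
  stat2 <- array(0, gs)
  stat2[2, 2, 2] <- 8; stat2[3, 3, 3] <- 8
  for (conn in c(6, 26)) {
    cl2 <- clusterThreshold(stat2, df = 20, voxelP = 0.001,
                            connectivity = conn)
    expect_equal(nrow(cl2), oracleComponentCount(stat2 > 3, conn))
  }
  expect_equal(nrow(clusterThreshold(array(0, gs), df = 20)), 0L)

  # negative clusters are tracked with their sign
  stat3 <- array(0, gs); stat3[5:6, 5, 5] <- -9
  cl3 <- clusterThreshold(stat3, df = 20)
  expect_equal(cl3$sign, -1)
  expect_equal(cl3$extent, 2L)
})

test_that("cluster p values obey the permutation bound and BH is monotone", {
  clusters <- data.frame(extent = c(40L, 6L, 2L), sign = 1,
                         peak_i = 1L, peak_j = 1L, peak_k = 1L,
                         peak_value = c(8, 5, 4))
  clusters$voxels <- list(1:40, 41:46, 47:48)
  null <- c(rep(3L, 995), rep(7L, 4))   # 999 permutation maxima
  out <- clusterFdr(clusters, null, q = 0.05)
  expect_equal(out$p[1], 1 / 1000)      # larger than all 999 maxima
  expect_equal(out$p[2], (1 + 4) / 1000)
  expect_true(all(diff(out$q[order(out$p)]) >= 0))
  expect_error(clusterFdr(clusters, integer(0)), "no permutations")
})

test_that("obesity-sensitive ROI selection recovers planted blobs with signs", {
  gs <- c(10L, 10L, 10L)
  hyper <- array(FALSE, gs); hyper[2:4, 2:4, 2:4] <- TRUE
  hypo <- array(FALSE, gs); hypo[7:9, 7:9, 7:9] <- TRUE
  sim <- simulateZmaps(20, 10, gs, list(hyper, hypo), c(0.6, -0.6),
                       sd = 0.15, seed = 11)
  grp <- ifelse(sim$group == "A", "lean", "obese")
  tim <- rep("T0", 30)
  res <- fitGroupTimeModel(sim$maps, grp, tim, contrast = "groupT0")
  res <- clusterThreshold(res)
  null <- nullMaxExtents(sim$maps, grp, nPerm = 200, seed = 3)
  res <- clusterFdr(res, null)
  rois <- selectObesitySensitiveRois(res)
  expect_equal(sum(grepl("gt", names(rois))), 1L)
  expect_equal(sum(grepl("lt", names(rois))), 1L)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice(rois$obese_gt_lean_1, hyper), 0.5)
  expect_gt(dice(rois$obese_lt_lean_1, hypo), 0.5)

  # a null cohort yields no ROI
  simN <- simulateZmaps(20, 10, gs, sd = 0.15, seed = 12)
  resN <- clusterFdr(
    clusterThreshold(fitGroupTimeModel(simN$maps, grp, tim,
                                       contrast = "groupT0")),
    nullMaxExtents(simN$maps, grp, nPerm = 200, seed = 4))
  expect_length(selectObesitySensitiveRois(resN), 0L)
})

test_that("ROI selection uses baseline data only (no leakage from T8)", {
  gs <- c(8L, 8L, 8L)
  blob <- array(FALSE, gs); blob[2:4, 2:4, 2:4] <- TRUE
  sim <- simulateZmaps(10, 8, gs, list(blob), 0.7, sd = 0.15, seed = 21)
  grp <- ifelse(sim$group == "A", "lean", "obese")
  n <- length(grp)
  # build a two-session data set; T8 maps are irrelevant to selection
  set.seed(99)
  mapsT8a <- array(rnorm(prod(gs) * n, 0, 0.15), c(gs, n))
  mapsT8b <- array(rnorm(prod(gs) * n, 5, 2), c(gs, n))
  pick <- function(mapsT8) {
    allMaps <- abind_local(sim$maps, mapsT8)
    g2 <- c(grp, grp); t2 <- rep(c("T0", "T8"), each = n)
    res <- fitGroupTimeModel(allMaps, g2, t2, contrast = "groupT0")
    res <- clusterThreshold(res)
    res <- clusterFdr(res, nullMaxExtents(sim$maps, grp, nPerm = 100,
                                          seed = 5))
    selectObesitySensitiveRois(res)
  }
  expect_identical(pick(mapsT8a), pick(mapsT8b))
})

test_that("interaction contrast pairs sessions within participant", {
  gs <- c(6L, 6L, 6L)
  set.seed(55)
  n <- 10
  pid <- sprintf("s%02d", 1:n)
  grp <- rep(c("lean", "obese"), each = n / 2)
  t0maps <- array(rnorm(prod(gs) * n, 0, 0.2), c(gs, n))
  t8maps <- t0maps + array(rnorm(prod(gs) * n, 0, 0.02), c(gs, n))
  blob <- array(FALSE, gs); blob[2:3, 2:3, 2:3] <- TRUE
  # obese participants gain a large offset at T8 inside the blob
  for (i in which(grp == "obese")) {
    v <- t8maps[, , , i]; v[blob] <- v[blob] + 1; t8maps[, , , i] <- v
  }
  maps <- abind_local(t0maps, t8maps)
  res <- fitGroupTimeModel(maps, c(grp, grp),
                           rep(c("T0", "T8"), each = n),
                           c(pid, pid), contrast = "interaction")
  # change maps carry only tiny noise outside the planted interaction
  expect_gt(min(statGrid(res)[blob]), 15)
  expect_lt(max(abs(statGrid(res)[!blob])), 10)
})
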