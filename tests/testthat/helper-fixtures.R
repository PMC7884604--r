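# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Small, fast cohort spec: 10^3 grid, 100 retained volumes.
smallSpec <- function(seed = 1L, ...) {
  CohortSpec(gridShape = c(10L, 10L, 10L), nVolumesAcquired = 104L,
             nDiscard = 4L, rngSeed = seed, ...)
}

# A fully deterministic run: still motion trace, smooth in-band sinusoidal
# content (no random noise), so the outlier detector finds nothing.
makeStillRun <- function(nT = 80L, gs = c(8L, 8L, 8L), trS = 2) {
  msk <- defaultMasks(gs)
  tt <- seq_len(nT)
  base <- 1000 + 5 * sin(2 * pi * 0.03 * trS * tt)   # 0.03 Hz, in band
  dat <- array(rep(base, each = prod(gs)), c(gs, nT))
  new("BoldRun", data = dat, trS = trS,
      motion = matrix(0, nT, 6), affine = diag(c(3, 3, 3, 1)),
      masks = msk, participant = "fix-01", session = "T0")
}

# Wrap a raw BoldRun as a CleanRun with all volumes retained (identity
# "denoising"), for connectivity tests that need the planted structure
# untouched.
asCleanRun <- function(run) {
  new("CleanRun", residuals = run@data,
      retained = rep(TRUE, dim(run@data)[4]),
      band = c(0.01, 0.1), trS = run@trS, affine = run@affine,
      masks = run@masks, participant = run@participant,
      session = run@session)
}

# Build a ConnectivityMap directly from a z array.
makeZMap <- function(z, participant = "fix-01", session = "T0") {
  new("ConnectivityMap", zgrid = z, participant = participant,
      session = session, seed = "seed", nRetained = 100L)
}

# Independent connected-components oracle built on igraph (used to check
# the package's own labelling).
oracleComponentCount <- function(mask, connectivity = 6) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  d <- dim(mask)
  co <- arrayInd(idx, d)
  edges <- c()
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a >= b) next
    dd <- abs(co[a, ] - co[b, ])
    near <- switch(as.character(connectivity),
                   "6" = sum(dd) == 1,
                   "18" = max(dd) == 1 && sum(dd) <= 2,
                   "26" = max(dd) == 1)
    if (near) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Concatenate two 4D arrays along the fourth (participant) axis.
abind_local <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

# Brute-force per-fold OLS oracle for the leave-one-out prediction.
oracleLoocv <- function(z, dw, intercept = TRUE) {
  n <- length(z)
  vapply(seq_len(n), function(i) {
    fit <- stats::lm(dw[-i] ~ z[-i])
    b <- stats::coef(fit)
    (if (intercept) b[1] else 0) + b[2] * z[i]
  }, numeric(1))
}
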