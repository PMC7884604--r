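# Group-level factorial contrasts on Fisher-z maps with a permutation
# cluster-extent null and cluster-level FDR.

# Pooled-variance two-sample t per row of V x n matrices (B - A).
tMapTwoSample <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2); vB <- rowSums((B - mB)^2)
  sp2 <- (vA + vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mB - mA) / se
  t[se == 0] <- 0
  t
}

# Stack a list of ConnectivityMap (or a 4D array) into V x n, returning
# spatial dims too.
stackMaps <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    d <- dim(maps)
    return(list(mat = matrix(maps, prod(d[1:3]), d[4]), dims = d[1:3]))
  }
  stopifnot(is.list(maps), length(maps) > 0)
  dims <- dim(zGrid(maps[[1]]))
  mat <- vapply(maps, function(m) as.vector(zGrid(m)),
                numeric(prod(dims)))
  list(mat = matrix(mat, prod(dims), length(maps)), dims = dims)
}

#' Group-by-time contrasts on connectivity maps
#'
#' Realises the 2 x 2 (group x time) factorial analysis as planned
#' two-sample contrasts on per-participant Fisher-z maps: obese vs lean at
#' T0, obese vs lean at T8, and the interaction as an unpaired contrast on
#' per-participant change maps (T8 - T0). Positive t = obese > lean.
#'
#' @param maps list of [ConnectivityMap-class] or 4D array (last axis =
#'   map index).
#' @param group character/factor per map: `"lean"` or `"obese"`.
#' @param time character per map: `"T0"` or `"T8"`.
#' @param participant identifiers per map (needed for the interaction,
#'   which pairs T0 and T8 within participant).
#' @param contrast which contrast to compute.
#' @return A [ContrastResult-class] with an empty cluster table (see
#'   [clusterThreshold()]).
#' @export
fitGroupTimeModel <- function(maps, group, time = NULL, participant = NULL,
                              contrast = c("groupT0", "groupT8",
                                           "interaction")) {
  contrast <- match.arg(contrast)
  st <- stackMaps(maps)
  n <- ncol(st$mat)
  group <- as.character(group)
  stopifnot(length(group) == n)
  if (contrast %in% c("groupT0", "groupT8")) {
    tp <- if (contrast == "groupT0") "T0" else "T8"
    if (is.null(time)) stop("time labels are required")
    sel <- time == tp
    A <- st$mat[, sel & group == "lean", drop = FALSE]
    B <- st$mat[, sel & group == "obese", drop = FALSE]
  } else {
    if (is.null(time) || is.null(participant))
      stop("interaction contrast needs time and participant labels")
    pid <- as.character(participant)
    both <- intersect(pid[time == "T0"], pid[time == "T8"])
    if (!length(both)) stop("no participant has both sessions")
    i0 <- match(both, ifelse(time == "T0", pid, NA))
    i8 <- match(both, ifelse(time == "T8", pid, NA))
    change <- st$mat[, i8, drop = FALSE] - st$mat[, i0, drop = FALSE]
    g <- group[i0]
    A <- change[, g == "lean", drop = FALSE]
    B <- change[, g == "obese", drop = FALSE]
  }
  if (ncol(A) < 2 || ncol(B) < 2)
    stop("contrast '", contrast, "' needs >= 2 maps per cell")
  tv <- tMapTwoSample(A, B)
  dim(tv) <- st$dims
  lab <- switch(contrast, groupT0 = "obese-lean@T0",
                groupT8 = "obese-lean@T8",
                interaction = "obese-lean@(T8-T0)")
  new("ContrastResult", stat = tv, contrast = lab,
      df = ncol(A) + ncol(B) - 2,
      clusters = data.frame())
}

# Neighbour offsets for 6/18/26 connectivity in voxel steps.
neighbourOffsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  d1 <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  sel <- switch(as.character(connectivity),
                "6" = d1 == 1, "18" = d1 <= 2, "26" = rep(TRUE, nrow(off)),
                stop("connectivity must be 6, 18 or 26"))
  as.matrix(off[sel, ])
}

# Label connected components of a logical 3D array. Returns an integer
# array (0 = background) and the number of components.
labelComponents <- function(mask, connectivity = 6) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = lab, n = 0L))
  off <- neighbourOffsets(connectivity)
  coords <- arrayInd(idx, d)
  inMask <- array(FALSE, d); inMask[idx] <- TRUE
  cur <- 0L
  for (start in seq_along(idx)) {
    if (lab[idx[start]] != 0L) next
    cur <- cur + 1L
    queue <- idx[start]
    lab[queue] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vc <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        nb <- vc + off[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (inMask[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Cluster table for one sign of a t map.
clustersOneSign <- function(stat, thresh, sign, connectivity) {
  mask <- if (sign > 0) stat > thresh else stat < -thresh
  cc <- labelComponents(mask, connectivity)
  if (cc$n == 0L) return(NULL)
  d <- dim(stat)
  out <- lapply(seq_len(cc$n), function(k) {
    vox <- which(cc$labels == k)
    pk <- vox[which.max(abs(stat[vox]))]
    ijk <- arrayInd(pk, d)
    data.frame(extent = length(vox), sign = sign,
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
               peak_value = stat[pk])
  })
  out <- do.call(rbind, out)
  out$voxels <- lapply(seq_len(cc$n), function(k) which(cc$labels == k))
  out
}

#' Supra-threshold clusters of a t map
#'
#' Thresholds the statistic map at the two-tailed cluster-forming level
#' (`|t| > qt(1 - voxelP, df)`), groups supra-threshold voxels by the given
#' connectivity separately for each sign, and sorts clusters by extent.
#'
#' @param stat 3D t map (or a [ContrastResult-class]).
#' @param df degrees of freedom (taken from the object if one is given).
#' @param voxelP uncorrected cluster-forming p (default 0.001, one-sided
#'   per sign).
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return If given a [ContrastResult-class], the object with its cluster
#'   table filled; otherwise the cluster data.frame. Columns: `extent`,
#'   `sign`, peak voxel indices, `peak_value`, plus a `voxels` list-column.
#' @export
clusterThreshold <- function(stat, df = NULL, voxelP = 0.001,
                             connectivity = 6) {
  obj <- NULL
  if (is(stat, "ContrastResult")) {
    obj <- stat
    df <- obj@df
    stat <- obj@stat
  }
  stopifnot(!is.null(df), all(is.finite(stat)), voxelP > 0, voxelP < 1)
  thresh <- stats::qt(1 - voxelP, df)
  tab <- rbind(clustersOneSign(stat, thresh, +1, connectivity),
               clustersOneSign(stat, thresh, -1, connectivity))
  if (is.null(tab)) {
    tab <- data.frame(extent = integer(), sign = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_value = numeric())
    tab$voxels <- list()
  } else {
    tab <- tab[order(-tab$extent), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (is.null(obj)) return(tab)
  obj@clusters <- tab
  obj
}

#' Permutation null of the maximum cluster extent
#'
#' Shuffles the group labels `nPerm` times, recomputes the two-sample t
#' map and records the maximum supra-threshold cluster extent over both
#' signs (0 when no voxel survives). For the interaction contrast, pass
#' the per-participant change maps.
#'
#' @param maps 4D array or list of [ConnectivityMap-class] (one map per
#'   participant).
#' @param group labels, `"lean"`/`"obese"` per map.
#' @param nPerm number of label permutations (default 1000).
#' @param voxelP,connectivity as in [clusterThreshold()].
#' @param seed RNG seed for the permutations.
#' @return Integer vector of length `nPerm`.
#' @export
nullMaxExtents <- function(maps, group, nPerm = 1000, voxelP = 0.001,
                           connectivity = 6, seed = 1L) {
  st <- stackMaps(maps)
  group <- as.character(group)
  n <- ncol(st$mat)
  stopifnot(length(group) == n, nPerm >= 1)
  isB <- group == "obese"
  df <- n - 2
  thresh <- stats::qt(1 - voxelP, df)
  withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      perm <- sample(n)
      A <- st$mat[, perm[!isB], drop = FALSE]
      B <- st$mat[, perm[isB], drop = FALSE]
      tv <- tMapTwoSample(A, B)
      supra <- abs(tv) > thresh
      if (!any(supra)) return(0L)
      dim(supra) <- st$dims
      tv3 <- tv; dim(tv3) <- st$dims
      ext <- c(0L)
      for (sgn in c(1, -1)) {
        m <- if (sgn > 0) tv3 > thresh else tv3 < -thresh
        if (any(m)) {
          cc <- labelComponents(m, connectivity)
          ext <- c(ext, tabulate(cc$labels[cc$labels > 0]))
        }
      }
      max(ext)
    }, integer(1))
  })
}

#' Cluster-level permutation p and FDR q values
#'
#' Cluster p = proportion of permutation-maximum extents at least as large
#' as the observed extent, with +1 smoothing (`(1 + #{null >= ext}) /
#' (B + 1)`), then Benjamini-Hochberg across the observed clusters.
#'
#' @param clusters cluster table from [clusterThreshold()] (or a
#'   [ContrastResult-class] carrying one).
#' @param nullExtents permutation maxima from [nullMaxExtents()]; at least
#'   one permutation is required.
#' @param q FDR level used to set the `significant` column (default 0.05).
#' @return The cluster table (or object) with `p`, `q` and `significant`
#'   columns added.
#' @export
clusterFdr <- function(clusters, nullExtents, q = 0.05) {
  obj <- NULL
  if (is(clusters, "ContrastResult")) {
    obj <- clusters
    clusters <- obj@clusters
  }
  if (length(nullExtents) < 1) stop("no permutations supplied")
  if (nrow(clusters)) {
    B <- length(nullExtents)
    clusters$p <- vapply(clusters$extent, function(e)
      (1 + sum(nullExtents >= e)) / (B + 1), numeric(1))
    clusters$q <- stats::p.adjust(clusters$p, method = "BH")
    clusters$significant <- clusters$q < q
  } else {
    clusters$p <- numeric()
    clusters$q <- numeric()
    clusters$significant <- logical()
  }
  if (is.null(obj)) return(clusters)
  obj@clusters <- clusters
  obj
}

#' Obesity-sensitive ROI masks from the baseline contrast
#'
#' Converts the FDR-surviving clusters of the obese-vs-lean baseline (T0)
#' contrast into binary ROI masks, labelled by the sign of the group
#' difference. Only T0 maps enter this selection, so no information about
#' T8 or weight change can leak into the ROI definition.
#'
#' @param result a [ContrastResult-class] whose cluster table carries
#'   `q` values (run [clusterThreshold()] then [clusterFdr()] first).
#' @param q significance level on the cluster q values (default 0.05).
#' @return Named list of logical 3D masks (`obese_gt_lean_1`, ...,
#'   `obese_lt_lean_1`, ...), largest cluster first within each sign;
#'   empty list when nothing survives.
#' @export
selectObesitySensitiveRois <- function(result, q = 0.05) {
  stopifnot(is(result, "ContrastResult"))
  tab <- result@clusters
  if (!nrow(tab) || is.null(tab$q))
    if (!nrow(tab)) return(list()) else stop("run clusterFdr() first")
  tab <- tab[tab$q < q, , drop = FALSE]
  if (!nrow(tab)) return(list())
  d <- dim(result@stat)
  out <- list()
  cnt <- c(pos = 0L, neg = 0L)
  for (i in seq_len(nrow(tab))) {
    m <- array(FALSE, d)
    m[tab$voxels[[i]]] <- TRUE
    if (tab$sign[i] > 0) {
      cnt["pos"] <- cnt["pos"] + 1L
      out[[paste0("obese_gt_lean_", cnt["pos"])]] <- m
    } else {
      cnt["neg"] <- cnt["neg"] + 1L
      out[[paste0("obese_lt_lean_", cnt["neg"])]] <- m
    }
  }
  out
}
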