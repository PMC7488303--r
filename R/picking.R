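#' @include AllClasses.R utils.R volume.R
NULL

# Separable 3D Gaussian blur with replicated edges; sigma in voxels.
gaussianBlur3d <- function(arr, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  dims <- dim(arr)
  for (d in 1:3) {
    out <- array(0, dims)
    n <- dims[d]
    base <- seq_len(n)
    for (t in (-half):half) {
      idx <- pmin(pmax(base + t, 1L), n)
      shifted <- switch(d,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + kern[t + half + 1L] * shifted
    }
    arr <- out
  }
  arr
}

#' Difference-of-Gaussian transform
#'
#' Subtracts two Gaussian-filtered copies of the volume:
#' G(sigma1) * V - G(sigma1 * ratio) * V, with the conventional ratio of
#' 1.1 between the two sigmas. Sigmas are in voxel units.
#'
#' @param volume a [DensityVolume-class].
#' @param sigma1 first Gaussian sigma in voxels (> 0).
#' @param ratio sigma2 / sigma1 (> 1, default 1.1).
#' @return a [DensityVolume-class] on the same grid.
#' @export
dogTransform <- function(volume, sigma1, ratio = 1.1) {
  stopifnot(is(volume, "DensityVolume"))
  if (!is.numeric(sigma1) || sigma1 <= 0) stop("sigma1 must be > 0")
  if (!is.numeric(ratio) || ratio <= 1) stop("ratio must be > 1")
  g1 <- gaussianBlur3d(volume@data, sigma1)
  g2 <- gaussianBlur3d(volume@data, sigma1 * ratio)
  DensityVolume(g1 - g2, volume@voxelSize, volume@origin,
                volume@resolution)
}

# 26-neighbourhood local maxima. A voxel is a peak when its value is >=
# all neighbours, strictly > those earlier in linear (lexicographic)
# order, so exactly one voxel of an exact plateau survives. Border
# voxels compare against their existing neighbours only.
localMaxima26 <- function(arr) {
  dims <- dim(arr)
  ok <- array(TRUE, dims)
  pad <- function(idx, n) pmin(pmax(idx, 1L), n)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ix <- seq_len(dims[1]) + dx
    iy <- seq_len(dims[2]) + dy
    iz <- seq_len(dims[3]) + dz
    inside <- outer(outer(ix >= 1 & ix <= dims[1],
                          iy >= 1 & iy <= dims[2]),
                    iz >= 1 & iz <= dims[3])
    neigh <- arr[pad(ix, dims[1]), pad(iy, dims[2]), pad(iz, dims[3])]
    # linear-order offset of this neighbour relative to the voxel
    earlier <- (dx + dims[1] * (dy + dims[2] * dz)) < 0
    cmp <- if (earlier) arr > neigh else arr >= neigh
    ok <- ok & (cmp | !inside)
  }
  which(ok, arr.ind = TRUE)
}

#' Detect thresholded DoG peaks
#'
#' Finds local maxima of the 26-neighbourhood, then keeps those at or
#' above the density threshold T = m + t (M - m) / 20, where M and m are
#' the largest and smallest local-peak values and t is the threshold
#' level (default 5). Optionally keeps only the topK strongest peaks.
#'
#' @param dogVolume a [DensityVolume-class], typically a
#'   [dogTransform()] output.
#' @param t threshold level in [0, 20].
#' @param topK if given, retain only the topK highest peaks after
#'   thresholding (ties broken by lexicographic voxel order).
#' @param sigma1,ratio metadata echoed into the result.
#' @return a [PickResult-class]; empty for a constant volume.
#' @export
detectPeaks <- function(dogVolume, t = 5, topK = NULL, sigma1 = NA_real_,
                        ratio = 1.1) {
  stopifnot(is(dogVolume, "DensityVolume"))
  if (t < 0 || t > 20) stop("threshold level t must lie in [0, 20]")
  arr <- dogVolume@data
  emptyRes <- function(threshold) new("PickResult",
    peaks = matrix(integer(0), 0, 3), coords = matrix(numeric(0), 0, 3),
    intensities = numeric(0), sigma1 = sigma1, sigmaRatio = ratio,
    thresholdLevel = t, threshold = threshold)
  if (max(arr) == min(arr)) return(emptyRes(NA_real_))
  pk <- localMaxima26(arr)
  if (nrow(pk) == 0L) return(emptyRes(NA_real_))
  vals <- arr[pk]
  M <- max(vals); m <- min(vals)
  threshold <- m + t * (M - m) / 20
  keep <- vals >= threshold
  pk <- pk[keep, , drop = FALSE]
  vals <- vals[keep]
  ord <- order(-vals, pk[, 1], pk[, 2], pk[, 3])
  pk <- pk[ord, , drop = FALSE]
  vals <- vals[ord]
  if (!is.null(topK) && nrow(pk) > topK) {
    pk <- pk[seq_len(topK), , drop = FALSE]
    vals <- vals[seq_len(topK)]
  }
  coords <- sweep((pk - 0.5) * dogVolume@voxelSize, 2,
                  -dogVolume@origin)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  dimnames(pk) <- list(NULL, c("i", "j", "k"))
  new("PickResult", peaks = pk, coords = coords, intensities = vals,
      sigma1 = sigma1, sigmaRatio = ratio, thresholdLevel = t,
      threshold = threshold)
}

#' Build a PickScore from confusion counts
#'
#' @param tp,fp,fn confusion counts.
#' @return a [PickScore-class] with precision, recall and F-score filled
#'   in (zero when undefined).
#' @export
pickScore <- function(tp, fp, fn) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  new("PickScore", tp = tp, fp = fp, fn = fn, precision = prec,
      recall = rec, fscore = fscore(prec, rec))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall scores in [0, 1].
#' @return 2 p r / (p + r), or 0 when both are 0.
#' @export
fscore <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Match picked peaks against ground-truth particles
#'
#' Greedy one-to-one matching in increasing peak-to-center distance: a
#' truth particle with a matched peak inside its radius is a true
#' positive, unmatched peaks are false positives and unmatched particles
#' false negatives. With `permissive = TRUE` every particle with any
#' peak within its radius counts as a true positive (no one-to-one
#' constraint on the particle side).
#'
#' @param peaks matrix of peak world coordinates (or a
#'   [PickResult-class]).
#' @param truth data.frame with columns x, y, z and radius (e.g.
#'   [groundTruth()] output or a blob fixture table).
#' @param permissive use the any-peak-within-radius rule.
#' @return a [PickScore-class].
#' @export
matchPicks <- function(peaks, truth, permissive = FALSE) {
  if (is(peaks, "PickResult")) peaks <- peaks@coords
  peaks <- as.matrix(peaks)
  if (!is.data.frame(truth) || nrow(truth) == 0L)
    stop("empty ground truth: nothing to evaluate")
  stopifnot(all(c("x", "y", "z", "radius") %in% names(truth)))
  nP <- nrow(peaks); nT <- nrow(truth)
  if (nP == 0L) return(pickScore(0L, 0L, nT))
  centers <- as.matrix(truth[, c("x", "y", "z")])
  d2 <- outer(rowSums(peaks^2), rep(1, nT)) +
    outer(rep(1, nP), rowSums(centers^2)) -
    2 * peaks %*% t(centers)
  d <- sqrt(pmax(d2, 0))
  within <- d <= matrix(truth$radius, nP, nT, byrow = TRUE)
  if (permissive) {
    tp <- sum(apply(within, 2, any))
    matchedPeaks <- sum(apply(within, 1, any))
    return(pickScore(tp, nP - matchedPeaks, nT - tp))
  }
  cand <- which(within, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand)) {
    ord <- order(d[cand])
    usedP <- logical(nP); usedT <- logical(nT)
    for (r in ord) {
      p <- cand[r, 1L]; tt <- cand[r, 2L]
      if (!usedP[p] && !usedT[tt]) {
        usedP[p] <- TRUE; usedT[tt] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  pickScore(tp, nP - tp, nT - tp)
}

#' Reference-free DoG particle picking
#'
#' Runs the DoG transform and thresholded peak detection in one call.
#' With `topK` set (e.g. to the known particle count) the strongest
#' topK peaks are returned, the protocol used for fixed-size pick lists.
#'
#' @param volume a [DensityVolume-class] (the tomogram).
#' @param sigma1 first Gaussian sigma in voxels.
#' @param ratio sigma ratio (default 1.1).
#' @param t threshold level (default 5).
#' @param topK optional cap on the number of picks.
#' @return a [PickResult-class].
#' @export
pickParticles <- function(volume, sigma1, ratio = 1.1, t = 5,
                          topK = NULL) {
  dog <- dogTransform(volume, sigma1, ratio)
  detectPeaks(dog, t = t, topK = topK, sigma1 = sigma1, ratio = ratio)
}

#' Score a pick result against ground truth
#'
#' @param picks a [PickResult-class] or coordinate matrix.
#' @param truth a ground-truth table with x, y, z, radius.
#' @param permissive see [matchPicks()].
#' @return a [PickScore-class].
#' @export
evaluatePicking <- function(picks, truth, permissive = FALSE) {
  matchPicks(picks, truth, permissive = permissive)
}
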