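#' @include AllClasses.R utils.R pose.R
NULL

#' Construct a DensityVolume
#'
#' @param data 3D numeric array, dim = c(nx, ny, nz), x fastest.
#' @param voxelSize voxel edge length (default 10 units = 1 nm).
#' @param origin world coordinate of the low corner of voxel (1,1,1).
#' @param resolution rendering-kernel FWHM (NA if unknown).
#' @return a [DensityVolume-class].
#' @export
DensityVolume <- function(data, voxelSize = 10, origin = c(0, 0, 0),
                          resolution = NA_real_) {
  new("DensityVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as3d(origin, "origin"), resolution = as.numeric(resolution))
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Deposit per-ball Gaussian kernels (FWHM = resolution) into an array.
# Kernels are truncated at 3 sigma and each ball's kernel is normalised
# so its integrated density (sum * voxel volume) equals the ball mass
# exactly.
splatBalls <- function(arr, origin, voxelSize, centers, masses, sigma) {
  dims <- dim(arr)
  half <- 3 * sigma / voxelSize
  voxVol <- voxelSize^3
  for (b in seq_len(nrow(centers))) {
    u <- (centers[b, ] - origin) / voxelSize + 0.5  # index coords
    # voxel centers within 3 sigma of the ball center, per axis
    i0 <- pmax(1L, as.integer(ceiling(u - half)))
    i1 <- pmin(dims, as.integer(floor(u + half)))
    if (any(i0 > i1)) next
    ax <- lapply(1:3, function(d) {
      idx <- i0[d]:i1[d]
      w <- exp(-((idx - u[d]) * voxelSize)^2 / (2 * sigma^2))
      list(idx = idx, w = w)
    })
    kern <- outer(outer(ax[[1]]$w, ax[[2]]$w), ax[[3]]$w)
    total <- sum(ax[[1]]$w) * sum(ax[[2]]$w) * sum(ax[[3]]$w)
    if (total == 0) next
    scale <- masses[b] / (total * voxVol)
    arr[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] <-
      arr[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] + kern * scale
  }
  arr
}

#' Rasterize a structure into a density map
#'
#' Every ball contributes an isotropic Gaussian kernel centred at its
#' center with FWHM equal to the target resolution, scaled so the ball's
#' integrated density equals its mass. The grid tightly bounds the ball
#' centers plus 3 sigma of padding.
#'
#' @param structure a [BallStructure-class].
#' @param voxelSize voxel edge (default 10 units = 1 nm pixels).
#' @param resolution kernel FWHM (default 40 units = 4 nm).
#' @param centers optional override of the ball centers (e.g. final
#'   packed positions).
#' @return a [DensityVolume-class].
#' @export
rasterizeStructure <- function(structure, voxelSize = 10, resolution = 40,
                               centers = NULL) {
  stopifnot(is(structure, "BallStructure"))
  if (is.null(centers)) centers <- structure@centers
  if (nrow(centers) < 1L) stop("cannot rasterize an empty structure")
  sigma <- fwhmToSigma(resolution)
  pad <- 3 * sigma + voxelSize  # one guard voxel keeps kernels unclipped
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxelSize)))
  arr <- array(0, dims)
  arr <- splatBalls(arr, lo, voxelSize, centers, structure@masses, sigma)
  DensityVolume(arr, voxelSize, lo, resolution)
}

# Trilinear interpolation of a volume at world points (outside -> 0).
trilinearSample <- function(volume, points) {
  arr <- volume@data
  dims <- dim(arr)
  u <- sweep(points, 2, volume@origin) / volume@voxelSize + 0.5
  i0 <- floor(u)
  fr <- u - i0
  val <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
          iz >= 1 & iz <= dims[3] & w > 0
    if (any(ok))
      val[ok] <- val[ok] + w[ok] * arr[cbind(ix[ok], iy[ok], iz[ok])]
  }
  val
}

#' Resample a volume under a rigid rotation
#'
#' Returns a volume on the same grid whose value at world point x is the
#' input sampled (trilinearly) at center + R^-1 (x - center).
#'
#' @param volume a [DensityVolume-class].
#' @param R 3 x 3 rotation matrix.
#' @param center world point the rotation pivots about (default: grid
#'   center).
#' @return a [DensityVolume-class] on the same grid.
#' @export
rotateVolume <- function(volume, R, center = NULL) {
  dims <- dim(volume@data)
  if (is.null(center))
    center <- volume@origin + dims * volume@voxelSize / 2
  pts <- as.matrix(expand.grid(
    x = volume@origin[1] + (seq_len(dims[1]) - 0.5) * volume@voxelSize,
    y = volume@origin[2] + (seq_len(dims[2]) - 0.5) * volume@voxelSize,
    z = volume@origin[3] + (seq_len(dims[3]) - 0.5) * volume@voxelSize))
  rel <- sweep(pts, 2, center)
  src <- rel %*% R + matrix(center, nrow(pts), 3, byrow = TRUE)  # R^-1 = t(R), rel %*% (t(R))^T
  vals <- trilinearSample(volume, src)
  DensityVolume(array(vals, dims), volume@voxelSize, volume@origin,
                volume@resolution)
}

#' Compose the density map of a packed scene
#'
#' Rigid structures are rendered once in their initial pose (the
#' per-type reference map), then that map is rotated by the structure's
#' extracted rotation and translated to its final centroid and summed
#' into the scene grid (trilinear resampling). Deformable structures are
#' rasterized directly from their final ball positions with zero
#' rotation.
#'
#' @param scene a packed [Scene-class].
#' @param voxelSize voxel edge (default 10 = 1 nm).
#' @param resolution kernel FWHM (default 40 = 4 nm).
#' @param truth optional precomputed [groundTruth()] table (unused for
#'   geometry, only checked for length).
#' @param refOversample reference maps of rigid structures are rendered
#'   at voxelSize / refOversample before rotation, halving the trilinear
#'   resampling error at the default of 2.
#' @return a [DensityVolume-class] covering the scene box.
#' @export
composeSceneMap <- function(scene, voxelSize = 10, resolution = 40,
                            truth = NULL, refOversample = 2) {
  stopifnot(is(scene, "Scene"))
  if (!is.null(truth) && nrow(truth) != length(scene@structures))
    stop("truth table does not match the scene structures")
  sigma <- fwhmToSigma(resolution)
  pad <- 3 * sigma + voxelSize
  lo <- scene@center - scene@box / 2 - pad
  dims <- pmax(1L, as.integer(ceiling((scene@box + 2 * pad) / voxelSize)))
  arr <- array(0, dims)
  for (s in seq_along(scene@structures)) {
    st <- scene@structures[[s]]
    sel <- scene@ballStructure == s
    p0 <- scene@initialPositions[sel, , drop = FALSE]
    p1 <- scene@positions[sel, , drop = FALSE]
    if (st@kind != "rigid") {
      arr <- splatBalls(arr, lo, voxelSize, p1, st@masses, sigma)
      next
    }
    c0 <- structureCentroid(p0)
    c1 <- structureCentroid(p1)
    R <- extractRigidRotation(p0[1, ], p0[2, ], p0[3, ],
                              p1[1, ], p1[2, ], p1[3, ])
    refStruct <- st
    refStruct@centers <- p0 - matrix(c0, nrow(p0), 3, byrow = TRUE)
    ref <- rasterizeStructure(refStruct, voxelSize / refOversample,
                              resolution)
    bound <- max(rowNorms(refStruct@centers)) + pad + voxelSize
    iLo <- pmax(1L, floor((c1 - bound - lo) / voxelSize))
    iHi <- pmin(dims, ceiling((c1 + bound - lo) / voxelSize))
    if (any(iLo > iHi)) next
    idx <- lapply(1:3, function(d) iLo[d]:iHi[d])
    pts <- as.matrix(expand.grid(
      x = lo[1] + (idx[[1]] - 0.5) * voxelSize,
      y = lo[2] + (idx[[2]] - 0.5) * voxelSize,
      z = lo[3] + (idx[[3]] - 0.5) * voxelSize))
    src <- sweep(pts, 2, c1) %*% R  # = t(R) %*% (x - c1), rowwise
    vals <- trilinearSample(ref, src)
    arr[idx[[1]], idx[[2]], idx[[3]]] <-
      arr[idx[[1]], idx[[2]], idx[[3]]] +
      array(vals, c(length(idx[[1]]), length(idx[[2]]),
                    length(idx[[3]])))
  }
  DensityVolume(arr, voxelSize, lo, resolution)
}

#' Add white Gaussian noise at a requested SNR
#'
#' SNR is defined as the variance ratio Var(signal) / Var(noise); the
#' added noise is zero-mean i.i.d. Gaussian with variance
#' Var(signal) / snr.
#'
#' @param volume a [DensityVolume-class] with nonzero variance.
#' @param snr requested signal-to-noise ratio (> 0).
#' @param seed integer seed for reproducibility.
#' @return the noisy [DensityVolume-class] (the simulated tomogram).
#' @export
addNoise <- function(volume, snr, seed = 1L) {
  stopifnot(is(volume, "DensityVolume"))
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
    stop("snr must be a single positive number")
  v <- stats::var(as.vector(volume@data))
  if (v == 0) stop("zero-variance signal: SNR is undefined")
  noise <- withSeed(seed,
                    stats::rnorm(length(volume@data),
                                 sd = sqrt(v / snr)))
  volume@data <- volume@data + array(noise, dim(volume@data))
  volume
}

#' Measure the realised SNR of a noisy volume
#'
#' @param clean,noisy [DensityVolume-class] objects on the same grid.
#' @return Var(clean) / Var(noisy - clean); Inf if the volumes are
#'   identical.
#' @export
measureSNR <- function(clean, noisy) {
  stopifnot(is(clean, "DensityVolume"), is(noisy, "DensityVolume"))
  if (!identical(dim(clean@data), dim(noisy@data)))
    stop("volumes have different grid shapes")
  nv <- stats::var(as.vector(noisy@data - clean@data))
  if (nv == 0) return(Inf)
  stats::var(as.vector(clean@data)) / nv
}
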