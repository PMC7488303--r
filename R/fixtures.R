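#' @include AllClasses.R utils.R structures.R volume.R
NULL

#' Generate a synthetic atom cloud
#'
#' Samples an atom point cloud of a named overall shape, standing in for
#' downloaded macromolecule structures so the whole pipeline can run
#' self-contained. Shapes: "globular" (isotropic Gaussian), "rod"
#' (uniform in a cylinder of length `extent`, aspect ratio 5), "planar"
#' (thin slab) and "dumbbell" (two displaced Gaussians).
#'
#' @param shape one of "globular", "rod", "planar", "dumbbell".
#' @param nAtoms number of atoms (>= 1).
#' @param extent characteristic size in Angstrom (diameter / length /
#'   edge).
#' @param seed integer seed; the cloud is deterministic given the
#'   arguments.
#' @return an [AtomCloud-class] labelled `synthetic-<shape>`.
#' @examples
#' synthAtomCloud("rod", 15000, extent = 250, seed = 7)
#' @export
synthAtomCloud <- function(shape = c("globular", "rod", "planar",
                                     "dumbbell"),
                           nAtoms, extent, seed = 1L) {
  if (!is.character(shape) || !shape[1L] %in%
      c("globular", "rod", "planar", "dumbbell"))
    stop("unknown shape '", shape[1L], "'")
  shape <- shape[1L]
  nAtoms <- as.integer(nAtoms)
  if (nAtoms < 1L) stop("nAtoms must be >= 1")
  if (extent <= 0) stop("extent must be > 0")
  coords <- withSeed(seed, switch(shape,
    globular = matrix(stats::rnorm(3 * nAtoms, sd = extent / 6),
                      nAtoms, 3),
    rod = {
      ang <- stats::runif(nAtoms, 0, 2 * pi)
      rad <- (extent / 10) * sqrt(stats::runif(nAtoms))
      cbind(stats::runif(nAtoms, -extent / 2, extent / 2),
            rad * cos(ang), rad * sin(ang))
    },
    planar = cbind(stats::runif(nAtoms, -extent / 2, extent / 2),
                   stats::runif(nAtoms, -extent / 2, extent / 2),
                   stats::runif(nAtoms, -extent / 20, extent / 20)),
    dumbbell = {
      side <- stats::runif(nAtoms) < 0.5
      sh <- ifelse(side, extent / 4, -extent / 4)
      cbind(stats::rnorm(nAtoms, mean = sh, sd = extent / 8),
            stats::rnorm(nAtoms, sd = extent / 8),
            stats::rnorm(nAtoms, sd = extent / 8))
    }))
  AtomCloud(coords, paste0("synthetic-", shape))
}

#' A small library of coarse-grained synthetic structures
#'
#' Generates `nTypes` synthetic clouds with shapes cycling through
#' globular / dumbbell / rod / planar, atom counts between 4000 and
#' 16000 and overall sizes of 120-160 Angstrom (the range where most
#' real macromolecule sizes concentrate), then coarse-grains each into a
#' rigid multi-ball model.
#'
#' @param nTypes number of structure types.
#' @param seed integer seed.
#' @return list of rigid [BallStructure-class] objects.
#' @export
fixtureStructureLibrary <- function(nTypes = 5L, seed = 1L) {
  shapes <- c("globular", "dumbbell", "rod", "planar")
  nAtomChoices <- c(4000L, 8000L, 12000L, 15000L, 16000L)
  lapply(seq_len(nTypes), function(i) {
    cloud <- synthAtomCloud(shapes[(i - 1L) %% length(shapes) + 1L],
                            nAtomChoices[(i - 1L) %%
                                           length(nAtomChoices) + 1L],
                            extent = 120 + 10 * ((i - 1L) %% 5L),
                            seed = subSeed(seed, i))
    st <- coarseGrain(cloud, seed = subSeed(seed, 100L + i))
    st@label <- sprintf("synth%02d", i)
    st
  })
}

#' Synthetic blob volume with matching ground truth
#'
#' Sums unit-mass Gaussian blobs of width `sigma` (in voxels) at the
#' given world coordinates and returns the matching truth table with
#' radius 3 sigma, the standard picking-test fixture.
#'
#' @param centers matrix of blob centers in world coordinates.
#' @param sigma blob sigma in voxels.
#' @param gridDim length-3 grid dimensions.
#' @param voxelSize voxel edge (default 1).
#' @param origin grid origin (default c(0,0,0)).
#' @return list with elements `volume` ([DensityVolume-class]) and
#'   `truth` (data.frame label, x, y, z, radius).
#' @export
synthBlobVolume <- function(centers, sigma, gridDim, voxelSize = 1,
                            origin = c(0, 0, 0)) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L)
    stop("at least one blob center is required")
  gridDim <- rep_len(as.integer(gridDim), 3L)
  origin <- as3d(origin, "origin")
  hi <- origin + gridDim * voxelSize
  inGrid <- centers >= matrix(origin, nrow(centers), 3, byrow = TRUE) &
    centers <= matrix(hi, nrow(centers), 3, byrow = TRUE)
  if (!all(inGrid))
    stop("blob center outside the grid")
  arr <- array(0, gridDim)
  arr <- splatBalls(arr, origin, voxelSize, centers,
                    masses = rep(1, nrow(centers)),
                    sigma = sigma * voxelSize)
  truth <- data.frame(label = sprintf("blob%02d", seq_len(nrow(centers))),
                      x = centers[, 1], y = centers[, 2],
                      z = centers[, 3],
                      radius = 3 * sigma * voxelSize,
                      stringsAsFactors = FALSE)
  list(volume = DensityVolume(arr, voxelSize, origin), truth = truth)
}

#' Well-separated blob centers on a jittered lattice
#'
#' Deterministic helper for picking fixtures: places n centers on a
#' regular lattice with spacing at least `minSep`, jittered by up to a
#' quarter voxel-spacing, guaranteeing the pairwise separation.
#'
#' @param n number of centers.
#' @param gridDim grid dimensions (length 3 or scalar).
#' @param minSep minimum pairwise separation (world units).
#' @param voxelSize voxel edge.
#' @param margin distance kept from the grid faces.
#' @param seed integer seed for the jitter.
#' @return matrix of n center coordinates.
#' @export
blobLattice <- function(n, gridDim, minSep, voxelSize = 1, margin = NULL,
                        seed = 1L) {
  gridDim <- rep_len(as.integer(gridDim), 3L)
  ext <- gridDim * voxelSize
  if (is.null(margin)) margin <- minSep / 2
  avail <- ext - 2 * margin
  if (any(avail <= 0)) stop("margin leaves no usable grid volume")
  perAxis <- pmax(1L, floor(avail / minSep) + 1L)
  if (prod(perAxis) < n)
    stop("grid too small for ", n, " centers at separation ", minSep)
  grid <- expand.grid(i = seq_len(perAxis[1]), j = seq_len(perAxis[2]),
                      k = seq_len(perAxis[3]))
  step <- ifelse(perAxis > 1L, avail / (perAxis - 1L), 0)
  step <- pmax(step, minSep)
  pts <- cbind(margin + (grid$i - 1L) * step[1],
               margin + (grid$j - 1L) * step[2],
               margin + (grid$k - 1L) * step[3])
  pts <- pts[seq_len(n), , drop = FALSE]
  jitter <- withSeed(seed,
    matrix(stats::runif(3 * n, -minSep / 8, minSep / 8), n, 3))
  pts <- pts + jitter
  pts <- pmin(pmax(pts, margin / 2), matrix(ext - margin / 2, n, 3,
                                            byrow = TRUE))
  unname(pts)
}
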