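#' @include AllClasses.R utils.R
NULL

#' Construct an AtomCloud
#'
#' @param coords numeric matrix (n x 3) of atomic positions in Angstrom.
#' @param sourceId character label for the cloud.
#' @return an [AtomCloud-class].
#' @export
AtomCloud <- function(coords, sourceId = "unknown") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  new("AtomCloud", coords = coords, sourceId = as.character(sourceId))
}

#' Parse atom coordinates from PDB text
#'
#' Extracts the orthogonal coordinates (columns 31-54, Angstrom) of all
#' ATOM and HETATM records, in file order. Only the first model of a
#' multi-model file is read; for atoms with alternate locations the first
#' occurrence is kept.
#'
#' @param pdbText character: the PDB file content (one string or a vector
#'   of lines).
#' @param sourceId label for the resulting cloud (e.g. the PDB ID).
#' @return an [AtomCloud-class].
#' @examples
#' txt <- paste0("ATOM      1  CA  ALA A   1    ",
#'               "   0.000   0.000   0.000  1.00  0.00           C")
#' parsePdbAtoms(txt, "toy")
#' @export
parsePdbAtoms <- function(pdbText, sourceId = "unknown") {
  lines <- unlist(strsplit(paste(pdbText, collapse = "\n"), "\n",
                           fixed = TRUE))
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec))
    stop("no ATOM/HETATM coordinate records in '", sourceId, "'")
  rec <- formatC(rec, width = 54L, flag = "-")
  altLoc <- substr(rec, 17L, 17L)
  atomKey <- paste0(substr(rec, 13L, 16L), substr(rec, 18L, 27L))
  keep <- altLoc %in% c(" ", "") | !duplicated(atomKey)
  rec <- rec[keep]
  coords <- cbind(
    x = as.numeric(substr(rec, 31L, 38L)),
    y = as.numeric(substr(rec, 39L, 46L)),
    z = as.numeric(substr(rec, 47L, 54L))
  )
  if (anyNA(coords))
    stop("malformed coordinate fields in '", sourceId, "'")
  AtomCloud(coords, sourceId)
}

#' Read atom coordinates from a PDB file
#'
#' @param path path to a PDB file.
#' @param sourceId label; defaults to the file name without extension.
#' @return an [AtomCloud-class].
#' @export
readPdbAtoms <- function(path, sourceId = NULL) {
  if (is.null(sourceId))
    sourceId <- sub("\\.[^.]*$", "", basename(path))
  parsePdbAtoms(readLines(path, warn = FALSE), sourceId)
}

#' Number of balls for a given atom count
#'
#' Every 5000 atoms are represented by one ball (rounding up), with a
#' floor of three so that a rigid structure always offers two linearly
#' independent internal vectors for pose extraction.
#'
#' @param nAtoms positive integer atom count.
#' @return the cluster count, max(3, ceiling(nAtoms / 5000)).
#' @examples
#' clusterCount(4000)   # 3
#' clusterCount(16000)  # 4
#' @export
clusterCount <- function(nAtoms) {
  nAtoms <- as.numeric(nAtoms)
  if (length(nAtoms) != 1L || !is.finite(nAtoms) || nAtoms < 1)
    stop("nAtoms must be a positive integer")
  max(3L, as.integer(ceiling(nAtoms / 5000)))
}

# Seeded Lloyd iteration: initial centers drawn from the atoms, nearest
# assignment to a fixed point (cap maxIter); an emptied cluster is
# re-seeded at the atom farthest from its current center.
.kmeansLloyd <- function(coords, k, seed, maxIter = 300L) {
  n <- nrow(coords)
  centers <- withSeed(seed, coords[sample.int(n, k), , drop = FALSE])
  assign <- integer(n)
  for (iter in seq_len(maxIter)) {
    d2 <- vapply(seq_len(k), function(j) {
      dx <- coords[, 1L] - centers[j, 1L]
      dy <- coords[, 2L] - centers[j, 2L]
      dz <- coords[, 3L] - centers[j, 3L]
      dx * dx + dy * dy + dz * dz
    }, numeric(n))
    if (n == 1L) d2 <- matrix(d2, 1L, k)
    newAssign <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(newAssign))
    for (j in empty) {
      worst <- which.max(d2[cbind(seq_len(n), newAssign)])
      centers[j, ] <- coords[worst, ]
      newAssign[worst] <- j
    }
    for (j in unique(newAssign))
      centers[j, ] <- colMeans(coords[newAssign == j, , drop = FALSE])
    if (identical(newAssign, assign)) break
    assign <- newAssign
  }
  list(centers = centers, cluster = assign)
}

.fullyConnectedTopology <- function(centers, kb) {
  k <- nrow(centers)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  r0 <- rowNorms(centers[i, , drop = FALSE] - centers[j, , drop = FALSE])
  new("Topology",
      bonds = data.frame(i = as.integer(i), j = as.integer(j),
                         r0 = r0, kb = kb),
      angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                          theta0 = numeric(0), ktheta = numeric(0)))
}

#' Coarse-grain an atom cloud into a rigid multi-ball model
#'
#' Atoms are partitioned into k clusters by seeded Lloyd k-means on their
#' coordinates. Each ball sits at a cluster centroid with radius equal to
#' the maximum distance from the centroid to a member atom, and carries a
#' mass of 5000 (one ball per 5000 atoms). Balls are fully
#' bond-connected, with equilibrium lengths equal to the initial
#' center-to-center distances, which freezes the shape during packing.
#'
#' @param cloud an [AtomCloud-class].
#' @param k number of balls; defaults to [clusterCount()] of the atom
#'   count.
#' @param seed integer seed for the k-means initialisation.
#' @param kb bond stiffness for the rigid topology.
#' @param ballMass mass per ball.
#' @return a rigid [BallStructure-class]; the cluster assignment is kept
#'   in `structMetadata(x)$cluster`.
#' @examples
#' cloud <- synthAtomCloud("globular", 5000, extent = 120, seed = 1)
#' coarseGrain(cloud, seed = 1)
#' @export
coarseGrain <- function(cloud, k = NULL, seed = 1L, kb = 2000,
                        ballMass = 5000) {
  stopifnot(is(cloud, "AtomCloud"))
  coords <- cloud@coords
  n <- nrow(coords)
  if (is.null(k)) k <- clusterCount(n)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k > n)
    stop("k (", k, ") exceeds the number of atoms (", n, ")")
  fit <- .kmeansLloyd(coords, k, seed)
  centers <- fit$centers
  radii <- vapply(seq_len(k), function(j) {
    member <- coords[fit$cluster == j, , drop = FALSE]
    max(rowNorms(member - matrix(centers[j, ], nrow(member), 3,
                                 byrow = TRUE)))
  }, numeric(1))
  centered <- centers - matrix(colMeans(centers), k, 3, byrow = TRUE)
  sv <- svd(centered)$d
  if (sum(sv > 1e-8 * max(sv, 1)) < 2L)
    stop("degenerate cloud: the ", k, " ball centers are collinear, ",
         "pose extraction needs two linearly independent vectors")
  new("BallStructure", kind = "rigid", centers = centers, radii = radii,
      masses = rep(ballMass, k),
      topology = .fullyConnectedTopology(centers, kb),
      label = cloud@sourceId,
      metadata = list(cluster = fit$cluster, nAtoms = n, seed = seed))
}

#' Build a deformable bead-chain filament
#'
#' Balls are placed on a straight line and chained by stiff bonds
#' (inextensible) with zero-stiffness angle terms (freely bendable).
#'
#' @param nBalls number of balls (>= 2).
#' @param ballRadius ball radius; default 20 (filament diameter 40).
#' @param spacing center-to-center distance; defaults to the ball
#'   diameter (beads initially touching).
#' @param origin position of the first ball.
#' @param axis direction of the chain (normalised internally).
#' @param kb bond stiffness.
#' @param ktheta angle stiffness (0 keeps the chain freely bendable).
#' @param ballMass mass per ball.
#' @param label structure label.
#' @return a filament [BallStructure-class].
#' @examples
#' buildFilament(9)
#' @export
buildFilament <- function(nBalls, ballRadius = 20,
                          spacing = 2 * ballRadius, origin = c(0, 0, 0),
                          axis = c(1, 0, 0), kb = 2000, ktheta = 0,
                          ballMass = 5000, label = "filament") {
  nBalls <- as.integer(nBalls)
  if (nBalls < 2L) stop("a filament needs at least 2 balls")
  if (spacing <= 0) stop("spacing must be > 0")
  axis <- normalize(as3d(axis, "axis"))
  origin <- as3d(origin, "origin")
  idx <- seq_len(nBalls) - 1L
  centers <- matrix(origin, nBalls, 3, byrow = TRUE) +
    outer(idx * spacing, axis)
  bonds <- data.frame(i = seq_len(nBalls - 1L),
                      j = seq_len(nBalls - 1L) + 1L,
                      r0 = spacing, kb = kb)
  if (nBalls >= 3L) {
    mid <- 2:(nBalls - 1L)
    angles <- data.frame(i = mid - 1L, j = mid, k = mid + 1L,
                         theta0 = pi, ktheta = ktheta)
  } else {
    angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                         theta0 = numeric(0), ktheta = numeric(0))
  }
  new("BallStructure", kind = "filament", centers = centers,
      radii = rep(ballRadius, nBalls), masses = rep(ballMass, nBalls),
      topology = new("Topology", bonds = bonds, angles = angles),
      label = label, metadata = list())
}

#' Build a deformable bead-mesh membrane
#'
#' Balls are placed on an m x n planar grid; each ball is bonded to its
#' four axial and four diagonal neighbours (each bond listed once), so
#' corners have degree 3, non-corner edge balls degree 5 and interior
#' balls degree 8. Bonds are stiff (non-stretchable); angle terms along
#' rows and columns have zero stiffness, so the mesh can bend.
#'
#' @param m,n grid dimensions (each >= 2).
#' @param ballRadius ball radius; default 40 (membrane diameter 80).
#' @param spacing grid spacing; defaults to the ball diameter.
#' @param origin position of grid node (1, 1).
#' @param normal plane normal (normalised internally).
#' @param kb bond stiffness.
#' @param ktheta angle stiffness.
#' @param ballMass mass per ball.
#' @param label structure label.
#' @return a membrane [BallStructure-class].
#' @examples
#' buildMembrane(3, 3)
#' @export
buildMembrane <- function(m, n, ballRadius = 40, spacing = 2 * ballRadius,
                          origin = c(0, 0, 0), normal = c(0, 0, 1),
                          kb = 2000, ktheta = 0, ballMass = 5000,
                          label = "membrane") {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 2L || n < 2L) stop("membrane grid needs m >= 2 and n >= 2")
  if (spacing <= 0) stop("spacing must be > 0")
  origin <- as3d(origin, "origin")
  basis <- planeBasis(normal)
  idx <- function(i, j) (j - 1L) * m + i
  grid <- expand.grid(i = seq_len(m), j = seq_len(n))
  centers <- matrix(origin, m * n, 3, byrow = TRUE) +
    outer((grid$i - 1) * spacing, basis$u) +
    outer((grid$j - 1) * spacing, basis$v)
  bi <- integer(0); bj <- integer(0)
  for (j in seq_len(n)) for (i in seq_len(m)) {
    if (i < m) { bi <- c(bi, idx(i, j)); bj <- c(bj, idx(i + 1L, j)) }
    if (j < n) { bi <- c(bi, idx(i, j)); bj <- c(bj, idx(i, j + 1L)) }
    if (i < m && j < n) {
      bi <- c(bi, idx(i, j)); bj <- c(bj, idx(i + 1L, j + 1L))
    }
    if (i < m && j > 1L) {
      bi <- c(bi, idx(i, j)); bj <- c(bj, idx(i + 1L, j - 1L))
    }
  }
  r0 <- rowNorms(centers[bi, , drop = FALSE] -
                 centers[bj, , drop = FALSE])
  bonds <- data.frame(i = bi, j = bj, r0 = r0, kb = kb)
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (j in seq_len(n)) for (i in 2:(m - 1L)) if (m >= 3L) {
    ai <- c(ai, idx(i - 1L, j)); aj <- c(aj, idx(i, j))
    ak <- c(ak, idx(i + 1L, j))
  }
  for (i in seq_len(m)) for (j in 2:(n - 1L)) if (n >= 3L) {
    ai <- c(ai, idx(i, j - 1L)); aj <- c(aj, idx(i, j))
    ak <- c(ak, idx(i, j + 1L))
  }
  angles <- data.frame(i = ai, j = aj, k = ak,
                       theta0 = rep(pi, length(ai)),
                       ktheta = rep(ktheta, length(ai)))
  new("BallStructure", kind = "membrane", centers = centers,
      radii = rep(ballRadius, m * n), masses = rep(ballMass, m * n),
      topology = new("Topology", bonds = bonds, angles = angles),
      label = label, metadata = list(grid = c(m = m, n = n)))
}

#' Per-ball bond degrees of a structure
#'
#' @param structure a [BallStructure-class].
#' @return integer vector: number of bonds incident to each ball.
#' @export
ballDegrees <- function(structure) {
  stopifnot(is(structure, "BallStructure"))
  .ballDegrees(nrow(structure@centers), structure@topology@bonds)
}

#' Bounding-sphere radius of a structure
#'
#' Radius of the sphere centred at the ball centroid that covers every
#' ball (centroid-to-center distance plus ball radius).
#'
#' @param structure a [BallStructure-class].
#' @param centers optional replacement ball centers (e.g. final packed
#'   positions).
#' @return a single numeric radius.
#' @export
boundingRadius <- function(structure, centers = NULL) {
  stopifnot(is(structure, "BallStructure"))
  if (is.null(centers)) centers <- structure@centers
  ctr <- colMeans(centers)
  max(rowNorms(centers - matrix(ctr, nrow(centers), 3, byrow = TRUE)) +
        structure@radii)
}
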