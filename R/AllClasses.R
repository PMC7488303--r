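#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' AtomCloud: raw atomic coordinates
#'
#' A set of 3D atomic positions (in Angstrom) extracted from a structure
#' file or synthesized, the input to coarse graining.
#'
#' @slot coords numeric matrix with one row per atom and columns x, y, z.
#' @slot sourceId character label (e.g. a PDB identifier).
#' @exportClass AtomCloud
setClass("AtomCloud",
  representation(coords = "matrix", sourceId = "character"),
  prototype(coords = matrix(numeric(0), 0, 3), sourceId = "unknown")
)

setValidity("AtomCloud", function(object) {
  msg <- NULL
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be a numeric matrix with 3 columns")
  else {
    if (nrow(object@coords) < 1L)
      msg <- c(msg, "at least one atom coordinate is required")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
  }
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' Topology: bonds and angles of a multi-ball model
#'
#' Bonds are harmonic springs between ball pairs; angles are harmonic
#' terms on ball triples (vertex at the middle index). Ball indices are
#' 1-based within the owning structure.
#'
#' @slot bonds data.frame with columns i, j (ball indices), r0
#'   (equilibrium length, Angstrom) and kb (stiffness).
#' @slot angles data.frame with columns i, j, k (ball indices, vertex j),
#'   theta0 (equilibrium angle, radians) and ktheta (stiffness).
#' @exportClass Topology
setClass("Topology",
  representation(bonds = "data.frame", angles = "data.frame"),
  prototype(
    bonds = data.frame(i = integer(0), j = integer(0),
                       r0 = numeric(0), kb = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), ktheta = numeric(0))
  )
)

setValidity("Topology", function(object) {
  b <- object@bonds; a <- object@angles
  msg <- NULL
  if (!all(c("i", "j", "r0", "kb") %in% names(b)))
    return("bonds must have columns i, j, r0, kb")
  if (!all(c("i", "j", "k", "theta0", "ktheta") %in% names(a)))
    return("angles must have columns i, j, k, theta0, ktheta")
  if (nrow(b)) {
    if (any(b$i == b$j))
      msg <- c(msg, "bond indices must be distinct")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate bonds are not allowed")
    if (any(b$r0 <= 0))
      msg <- c(msg, "equilibrium bond lengths must be > 0")
  }
  if (nrow(a)) {
    if (any(a$theta0 <= 0 | a$theta0 > pi + 1e-12))
      msg <- c(msg, "equilibrium angles must lie in (0, pi]")
  }
  if (is.null(msg)) TRUE else msg
})

#' BallStructure: a coarse-grained multi-ball model
#'
#' A named structure represented by balls (center, covering radius, mass)
#' plus the topology that encodes its rigidity or deformability. Rigid
#' macromolecules are fully bond-connected; filaments are bead chains;
#' membranes are bead meshes with axial and diagonal bonds.
#'
#' @slot kind one of "rigid", "filament", "membrane".
#' @slot centers numeric matrix of ball centers (rows), Angstrom.
#' @slot radii numeric vector of covering radii, Angstrom.
#' @slot masses numeric vector of ball masses (atom-count units).
#' @slot topology a [Topology-class].
#' @slot label character label.
#' @slot metadata list of provenance details (cluster assignment, grid
#'   dimensions for membranes, ...).
#' @exportClass BallStructure
setClass("BallStructure",
  representation(kind = "character", centers = "matrix", radii = "numeric",
                 masses = "numeric", topology = "Topology",
                 label = "character", metadata = "list"),
  prototype(kind = "rigid", label = "structure", metadata = list())
)

.ballDegrees <- function(nBalls, bonds) {
  deg <- integer(nBalls)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$i, bonds$j), levels = seq_len(nBalls)))
    deg <- as.integer(tab)
  }
  deg
}

setValidity("BallStructure", function(object) {
  msg <- NULL
  k <- nrow(object@centers)
  if (ncol(object@centers) != 3L || !is.numeric(object@centers))
    return("centers must be a numeric matrix with 3 columns")
  if (!all(is.finite(object@centers)))
    msg <- c(msg, "ball centers must be finite")
  if (length(object@radii) != k || length(object@masses) != k)
    msg <- c(msg, "radii and masses must have one entry per ball")
  if (any(object@radii < 0))
    msg <- c(msg, "radii must be >= 0")
  if (any(object@masses <= 0))
    msg <- c(msg, "masses must be > 0")
  if (!(object@kind %in% c("rigid", "filament", "membrane")))
    msg <- c(msg, "kind must be rigid, filament or membrane")
  b <- object@topology@bonds
  if (nrow(b) && (max(b$i, b$j) > k || min(b$i, b$j) < 1L))
    msg <- c(msg, "bond indices out of range")
  a <- object@topology@angles
  if (nrow(a) && (max(a$i, a$j, a$k) > k || min(a$i, a$j, a$k) < 1L))
    msg <- c(msg, "angle indices out of range")
  if (is.null(msg)) {
    deg <- .ballDegrees(k, b)
    if (object@kind == "rigid") {
      if (k < 3L)
        msg <- c(msg, "rigid structures need at least 3 balls")
      else if (nrow(b) != k * (k - 1L) / 2L)
        msg <- c(msg, "rigid structures must be fully bond-connected")
    } else if (object@kind == "filament") {
      if (k < 2L || nrow(b) != k - 1L)
        msg <- c(msg, "filaments need exactly nBalls - 1 chain bonds")
      else if (sum(deg == 1L) != 2L || any(deg > 2L))
        msg <- c(msg, "filament degrees must be 1 at ends, 2 inside")
    } else if (object@kind == "membrane") {
      if (!all(deg %in% c(3L, 5L, 8L)) || sum(deg == 3L) != 4L)
        msg <- c(msg, paste("membrane degrees must be 3 at corners,",
                            "5 on edges, 8 inside"))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' ForceFieldParams: parameters of the packing force field
#'
#' Defaults follow the reference parameterisation: bond stiffness 2000,
#' zero angle stiffness for deformable kinds, Lennard-Jones well depth 1
#' with switching between S = 600 and cutoff C = 610, a centripetal
#' external field growing as 10 * r up to r = 300 and saturating at 3000,
#' ball mass 5000 and time step 1. All lengths are internal units
#' (1 unit = 1 Angstrom).
#'
#' @slot kb default bond stiffness.
#' @slot ktheta default angle stiffness.
#' @slot epsilon Lennard-Jones well depth.
#' @slot switchdist distance S where the LJ switching taper starts.
#' @slot cutoff distance C where the LJ potential reaches zero.
#' @slot extInnerRadius radius of the linearly growing external field.
#' @slot extSlope slope of the external field inside the inner radius.
#' @slot extMax saturated external force magnitude.
#' @slot mass ball mass.
#' @slot dt integration time step.
#' @exportClass ForceFieldParams
setClass("ForceFieldParams",
  representation(kb = "numeric", ktheta = "numeric", epsilon = "numeric",
                 switchdist = "numeric", cutoff = "numeric",
                 extInnerRadius = "numeric", extSlope = "numeric",
                 extMax = "numeric", mass = "numeric", dt = "numeric"),
  prototype(kb = 2000, ktheta = 0, epsilon = 1, switchdist = 600,
            cutoff = 610, extInnerRadius = 300, extSlope = 10,
            extMax = 3000, mass = 5000, dt = 1)
)

setValidity("ForceFieldParams", function(object) {
  msg <- NULL
  if (!(object@switchdist > 0 && object@switchdist < object@cutoff))
    msg <- c(msg, "need 0 < switchdist < cutoff")
  if (object@extInnerRadius <= 0)
    msg <- c(msg, "extInnerRadius must be > 0")
  if (abs(object@extMax - object@extSlope * object@extInnerRadius) >
      1e-9 * max(1, object@extMax))
    msg <- c(msg, paste("extMax must equal extSlope * extInnerRadius",
                        "(continuity of the external field)"))
  if (object@mass <= 0) msg <- c(msg, "mass must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Scene: structures placed in a box
#'
#' Holds a list of structures with a global ball indexing, the per-ball
#' position state evolved by the packing engine, and the immutable
#' initial snapshot used for pose extraction.
#'
#' @slot structures list of [BallStructure-class] instances.
#' @slot positions numeric matrix of current ball positions (global order).
#' @slot initialPositions snapshot of positions at t = 0.
#' @slot box numeric length-3 full box extents, centred on `center`.
#' @slot center 3D origin of the external field.
#' @slot ballStructure integer vector mapping each global ball to its
#'   structure index.
#' @exportClass Scene
setClass("Scene",
  representation(structures = "list", positions = "matrix",
                 initialPositions = "matrix", box = "numeric",
                 center = "numeric", ballStructure = "integer"),
  prototype(box = c(1200, 1200, 1200), center = c(0, 0, 0))
)

setValidity("Scene", function(object) {
  msg <- NULL
  nb <- sum(vapply(object@structures, function(s) nrow(s@centers), 1L))
  if (nrow(object@positions) != nb)
    msg <- c(msg, "positions must have one row per ball")
  if (!identical(dim(object@positions), dim(object@initialPositions)))
    msg <- c(msg, "initialPositions must match positions in shape")
  if (length(object@box) != 3L || any(object@box <= 0))
    msg <- c(msg, "box must be three positive extents")
  if (length(object@center) != 3L)
    msg <- c(msg, "center must be a 3D point")
  if (length(object@ballStructure) != nb)
    msg <- c(msg, "ballStructure must map every ball")
  if (is.null(msg)) TRUE else msg
})

#' Trajectory: position snapshots of a packing run
#'
#' @slot steps integer step indices, starting at 0 (the initial state).
#' @slot frames list of position matrices, one per recorded step.
#' @slot converged logical, whether the displacement stop rule fired.
#' @slot nSteps number of integration steps actually taken.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(steps = "integer", frames = "list",
                 converged = "logical", nSteps = "integer"),
  prototype(converged = FALSE, nSteps = 0L)
)

setValidity("Trajectory", function(object) {
  msg <- NULL
  if (length(object@steps) != length(object@frames))
    msg <- c(msg, "one frame per recorded step is required")
  if (length(object@steps)) {
    if (object@steps[1L] != 0L)
      msg <- c(msg, "frame 0 must be the initial snapshot")
    if (any(diff(object@steps) <= 0L))
      msg <- c(msg, "step indices must be strictly increasing")
  }
  if (is.null(msg)) TRUE else msg
})

#' DensityVolume: a 3D scalar grid
#'
#' Stored as an R array with dim = c(nx, ny, nz), x fastest (the MRC
#' on-disk layout). The world coordinate of the centre of 1-based voxel
#' (i, j, k) is origin + (i - 1/2, j - 1/2, k - 1/2) * voxelSize.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize edge length of a voxel (internal units; default 10,
#'   i.e. 1 nm).
#' @slot origin world coordinate of the low corner of voxel (1,1,1).
#' @slot resolution target resolution (FWHM of the rendering kernel);
#'   NA for volumes read from disk.
#' @exportClass DensityVolume
setClass("DensityVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric",
                 resolution = "numeric"),
  prototype(voxelSize = 10, origin = c(0, 0, 0), resolution = NA_real_)
)

setValidity("DensityVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  else if (!all(is.finite(object@data)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must be a 3D point")
  if (is.null(msg)) TRUE else msg
})

#' PickResult: Difference-of-Gaussian peak detections
#'
#' @slot peaks integer matrix of 1-based voxel indices (rows: i, j, k).
#' @slot coords numeric matrix of peak world coordinates.
#' @slot intensities DoG values at the peaks.
#' @slot sigma1 first Gaussian sigma (voxels).
#' @slot sigmaRatio ratio sigma2 / sigma1 (default 1.1).
#' @slot thresholdLevel the level t in T = m + t (M - m) / 20.
#' @slot threshold the realised threshold T.
#' @exportClass PickResult
setClass("PickResult",
  representation(peaks = "matrix", coords = "matrix",
                 intensities = "numeric", sigma1 = "numeric",
                 sigmaRatio = "numeric", thresholdLevel = "numeric",
                 threshold = "numeric"),
  prototype(sigmaRatio = 1.1, thresholdLevel = 5, threshold = NA_real_)
)

setValidity("PickResult", function(object) {
  msg <- NULL
  if (nrow(object@peaks) != length(object@intensities) ||
      nrow(object@coords) != length(object@intensities))
    msg <- c(msg, "peaks, coords and intensities must align")
  if (length(object@intensities) && !is.na(object@threshold) &&
      any(object@intensities < object@threshold - 1e-12))
    msg <- c(msg, "every retained peak must be >= the threshold")
  if (is.null(msg)) TRUE else msg
})

#' PickScore: confusion counts and derived detection scores
#'
#' @slot tp,fp,fn confusion counts.
#' @slot precision,recall,fscore derived scores in [0, 1].
#' @exportClass PickScore
setClass("PickScore",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric",
                 fscore = "numeric")
)

setValidity("PickScore", function(object) {
  msg <- NULL
  if (any(c(object@tp, object@fp, object@fn) < 0L))
    msg <- c(msg, "confusion counts must be non-negative")
  ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!ok(object@precision) || !ok(object@recall) || !ok(object@fscore))
    msg <- c(msg, "precision, recall and fscore must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
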