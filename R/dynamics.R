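#' @include AllClasses.R utils.R structures.R
NULL

#' Force-field parameter constructor
#'
#' @param kb,ktheta,epsilon,switchdist,cutoff,extInnerRadius,extSlope
#'   see [ForceFieldParams-class]; `extMax` is derived as
#'   `extSlope * extInnerRadius` so the field is continuous.
#' @param mass,dt ball mass and time step.
#' @return a validated [ForceFieldParams-class].
#' @export
forceFieldParams <- function(kb = 2000, ktheta = 0, epsilon = 1,
                             switchdist = 600, cutoff = 610,
                             extInnerRadius = 300, extSlope = 10,
                             mass = 5000, dt = 1) {
  new("ForceFieldParams", kb = kb, ktheta = ktheta, epsilon = epsilon,
      switchdist = switchdist, cutoff = cutoff,
      extInnerRadius = extInnerRadius, extSlope = extSlope,
      extMax = extSlope * extInnerRadius, mass = mass, dt = dt)
}

#' Centripetal external force field
#'
#' The field points from each ball toward the scene center. Its
#' magnitude grows linearly (slope 10 by default) with the distance to
#' the center up to the inner radius (300), beyond which it saturates at
#' the maximum (3000); it vanishes at the center itself, and the two
#' branches agree at the inner radius.
#'
#' @param position numeric 3-vector or matrix of positions (rows).
#' @param params a [ForceFieldParams-class].
#' @param center scene center (default origin).
#' @return force vector(s), same shape as `position`.
#' @examples
#' p <- forceFieldParams()
#' externalForce(c(100, 0, 0), p)   # magnitude 1000 toward the origin
#' externalForce(c(500, 0, 0), p)   # saturated at 3000
#' @export
externalForce <- function(position, params = forceFieldParams(),
                          center = c(0, 0, 0)) {
  single <- is.null(dim(position))
  x <- if (single) matrix(as3d(position, "position"), 1, 3)
       else as.matrix(position)
  center <- as3d(center, "center")
  d <- x - matrix(center, nrow(x), 3, byrow = TRUE)
  r <- rowNorms(d)
  mag <- ifelse(r < params@extInnerRadius, params@extSlope * r,
                params@extMax)
  scale <- ifelse(r > 0, -mag / pmax(r, .Machine$double.eps), 0)
  f <- d * scale
  if (single) as.numeric(f) else f
}

#' Harmonic bond potential and forces
#'
#' U(r) = kb (r - r0)^2, the spring bond potential; the force on each
#' ball is minus the gradient, equal and opposite along the pair axis.
#'
#' @param r bond length(s).
#' @param r0 equilibrium length.
#' @param kb spring stiffness (default 2000).
#' @return `bondEnergy`: energy value(s). `bondForces`: list with 3-vector
#'   forces `fi`, `fj` on the two balls.
#' @examples
#' bondEnergy(11, 10, 2000)   # 2000
#' @export
bondEnergy <- function(r, r0, kb = 2000) {
  if (any(r <= 0)) stop("bond length must be > 0")
  kb * (r - r0)^2
}

#' @rdname bondEnergy
#' @param xi,xj positions of the bonded balls.
#' @export
bondForces <- function(xi, xj, r0, kb = 2000) {
  xi <- as3d(xi, "xi"); xj <- as3d(xj, "xj")
  d <- xi - xj
  r <- vnorm(d)
  if (r == 0)
    stop("coincident ball centers: bond force direction undefined")
  fi <- -2 * kb * (r - r0) * d / r
  list(fi = fi, fj = -fi)
}

#' Harmonic angle potential and forces
#'
#' U(theta) = ktheta (theta - theta0)^2 for the angle at the middle ball
#' j of a bonded triple (i, j, k). With ktheta = 0 (the deformable
#' default) the term contributes neither energy nor force, which is what
#' makes filaments and membranes freely bendable.
#'
#' @param theta angle(s) in radians.
#' @param theta0 equilibrium angle.
#' @param ktheta angle stiffness.
#' @return `angleEnergy`: energy value(s). `angleForces`: 3 x 3 matrix of
#'   forces with rows fi, fj, fk (net force and torque are zero).
#' @export
angleEnergy <- function(theta, theta0, ktheta = 0) {
  ktheta * (theta - theta0)^2
}

#' @rdname angleEnergy
#' @param xi,xj,xk positions of the triple (vertex at xj).
#' @export
angleForces <- function(xi, xj, xk, theta0, ktheta = 0) {
  xi <- as3d(xi, "xi"); xj <- as3d(xj, "xj"); xk <- as3d(xk, "xk")
  u <- xi - xj; v <- xk - xj
  ru <- vnorm(u); rv <- vnorm(v)
  if (ru == 0 || rv == 0)
    stop("degenerate angle: zero-length bond vector")
  if (ktheta == 0)
    return(rbind(fi = c(0, 0, 0), fj = c(0, 0, 0), fk = c(0, 0, 0)))
  uh <- u / ru; vh <- v / rv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(1 - ct * ct, 1e-16))
  theta <- acos(ct)
  dUdT <- 2 * ktheta * (theta - theta0)
  dTi <- (ct * uh - vh) / (ru * st)
  dTk <- (ct * vh - uh) / (rv * st)
  fi <- -dUdT * dTi
  fk <- -dUdT * dTk
  rbind(fi = fi, fj = -(fi + fk), fk = fk)
}

#' Switched Lennard-Jones potential and forces
#'
#' U_LJ(r) = epsilon ((Rmin/r)^12 - 2 (Rmin/r)^6), with the well of depth
#' epsilon at r = Rmin. To save neighbour computation the potential is
#' tapered linearly between the switch distance S and the cutoff C:
#' U = U_LJ for r < S, U = U_LJ (C - r)/(C - S) for S <= r < C, and 0
#' beyond C.
#'
#' @param r pair distance(s), > 0.
#' @param rmin distance of the potential minimum (pair contact distance,
#'   the sum of the two ball radii in the packing engine).
#' @param epsilon well depth.
#' @param switchdist,cutoff taper window (defaults 600 and 610).
#' @return `ljEnergy`: energy value(s). `ljForces`: list with forces `fi`,
#'   `fj`. `ljForceMag`: the scalar radial force -dU/dr (positive =
#'   repulsive).
#' @examples
#' ljEnergy(60, rmin = 60)            # -epsilon, the well
#' ljEnergy(60 * 2^(-1/6), rmin = 60) # 0, the root
#' @export
ljEnergy <- function(r, rmin, epsilon = 1, switchdist = 600,
                     cutoff = 610) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  s6 <- (rmin / r)^6
  u <- epsilon * (s6 * s6 - 2 * s6)
  taper <- pmin(pmax((cutoff - r) / (cutoff - switchdist), 0), 1)
  ifelse(r >= cutoff, 0, u * taper)
}

#' @rdname ljEnergy
#' @export
ljForceMag <- function(r, rmin, epsilon = 1, switchdist = 600,
                       cutoff = 610) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  s6 <- (rmin / r)^6
  u <- epsilon * (s6 * s6 - 2 * s6)
  dudr <- epsilon * (-12 * s6 * s6 + 12 * s6) / r
  inSwitch <- r >= switchdist & r < cutoff
  taper <- ifelse(inSwitch, (cutoff - r) / (cutoff - switchdist), 1)
  f <- -dudr * taper + ifelse(inSwitch, u / (cutoff - switchdist), 0)
  ifelse(r >= cutoff, 0, f)
}

#' @rdname ljEnergy
#' @param xi,xj positions of the two balls.
#' @export
ljForces <- function(xi, xj, rmin, epsilon = 1, switchdist = 600,
                     cutoff = 610) {
  xi <- as3d(xi, "xi"); xj <- as3d(xj, "xj")
  d <- xi - xj
  r <- vnorm(d)
  if (r == 0) stop("coincident ball centers in Lennard-Jones pair")
  fmag <- ljForceMag(r, rmin, epsilon, switchdist, cutoff)
  fi <- fmag * d / r
  list(fi = fi, fj = -fi)
}

#' Create a scene from structures at their current centers
#'
#' The structures' own ball centers become the initial positions; the
#' scene center is the origin of the external field.
#'
#' @param structures list of [BallStructure-class] objects.
#' @param box full box extents (length-3 or one number).
#' @param center scene center.
#' @return a [Scene-class].
#' @export
newScene <- function(structures, box = c(1200, 1200, 1200),
                     center = c(0, 0, 0)) {
  if (is(structures, "BallStructure")) structures <- list(structures)
  stopifnot(all(vapply(structures, is, TRUE, "BallStructure")))
  if (length(box) == 1L) box <- rep(box, 3L)
  pos <- do.call(rbind, lapply(structures, ballCenters))
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  map <- rep(seq_along(structures),
             vapply(structures, nBalls, 1L))
  new("Scene", structures = structures, positions = pos,
      initialPositions = pos, box = as.numeric(box),
      center = as3d(center, "center"), ballStructure = as.integer(map))
}

# Global per-scene tables reused across steps: stacked bonds/angles with
# global indices, per-ball radii/masses, and the bonded-pair exclusion
# keys for the non-bonded loop.
sceneTables <- function(scene) {
  structs <- scene@structures
  sizes <- vapply(structs, nBalls, 1L)
  offs <- cumsum(c(0L, sizes))[seq_along(structs)]
  bondList <- vector("list", length(structs))
  angleList <- vector("list", length(structs))
  for (s in seq_along(structs)) {
    b <- structs[[s]]@topology@bonds
    if (nrow(b)) {
      b$i <- b$i + offs[s]; b$j <- b$j + offs[s]
      bondList[[s]] <- b
    }
    a <- structs[[s]]@topology@angles
    a <- a[a$ktheta != 0, , drop = FALSE]
    if (nrow(a)) {
      a$i <- a$i + offs[s]; a$j <- a$j + offs[s]; a$k <- a$k + offs[s]
      angleList[[s]] <- a
    }
  }
  bonds <- do.call(rbind, bondList)
  angles <- do.call(rbind, angleList)
  n <- sum(sizes)
  exclKey <- if (is.null(bonds)) numeric(0) else
    pmin(bonds$i, bonds$j) * (n + 1) + pmax(bonds$i, bonds$j)
  list(
    bonds = bonds, angles = angles, n = n,
    radii = unlist(lapply(structs, ballRadii), use.names = FALSE),
    masses = unlist(lapply(structs, ballMasses), use.names = FALSE),
    exclKey = exclKey
  )
}

# Candidate non-bonded pairs within the cutoff, via cell lists with cell
# edge = cutoff (all-pairs fallback when everything fits in few cells).
cellPairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  lo <- apply(pos, 2L, min)
  cell <- floor(sweep(pos, 2L, lo) / cutoff)
  dims <- apply(cell, 2L, max) + 1L
  if (prod(dims) <= 8) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(i = idx[, 1L], j = idx[, 2L])
  } else {
    id <- cell[, 1L] + dims[1L] * (cell[, 2L] + dims[2L] * cell[, 3L])
    byCell <- split(seq_len(n), id)
    cellOf <- function(cx, cy, cz) {
      ok <- cx >= 0 & cx < dims[1L] & cy >= 0 & cy < dims[2L] &
        cz >= 0 & cz < dims[3L]
      if (!ok) return(integer(0))
      byCell[[as.character(cx + dims[1L] * (cy + dims[2L] * cz))]]
    }
    neigh <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    neigh <- neigh[neigh$dx > 0 |
                   (neigh$dx == 0 & (neigh$dy > 0 |
                    (neigh$dy == 0 & neigh$dz >= 0))), ]
    acc <- vector("list", length(byCell) * nrow(neigh))
    a <- 0L
    for (key in names(byCell)) {
      members <- byCell[[key]]
      kNum <- as.numeric(key)
      cx <- kNum %% dims[1L]
      cy <- (kNum %/% dims[1L]) %% dims[2L]
      cz <- kNum %/% (dims[1L] * dims[2L])
      for (r in seq_len(nrow(neigh))) {
        if (neigh$dx[r] == 0 && neigh$dy[r] == 0 && neigh$dz[r] == 0) {
          if (length(members) >= 2L) {
            cmb <- utils::combn(members, 2L)
            a <- a + 1L
            acc[[a]] <- cbind(i = cmb[1L, ], j = cmb[2L, ])
          }
        } else {
          other <- cellOf(cx + neigh$dx[r], cy + neigh$dy[r],
                          cz + neigh$dz[r])
          if (length(other)) {
            a <- a + 1L
            acc[[a]] <- cbind(i = rep(members, each = length(other)),
                              j = rep(other, length(members)))
          }
        }
      }
    }
    pairs <- do.call(rbind, acc[seq_len(a)])
    if (is.null(pairs)) return(cbind(i = integer(0), j = integer(0)))
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, c(2L, 1L)]
  }
  d <- pos[pairs[, 1L], , drop = FALSE] - pos[pairs[, 2L], , drop = FALSE]
  keep <- rowSums(d * d) < cutoff^2
  pairs[keep, , drop = FALSE]
}

# Core force evaluation on a position matrix given precomputed tables.
.forcesCore <- function(pos, tables, params, center,
                        pairMethod = c("cell", "all")) {
  pairMethod <- match.arg(pairMethod)
  n <- tables$n
  f <- externalForce(pos, params, center)
  b <- tables$bonds
  if (!is.null(b) && nrow(b)) {
    d <- pos[b$i, , drop = FALSE] - pos[b$j, , drop = FALSE]
    r <- rowNorms(d)
    if (any(r == 0)) {
      bad <- which(r == 0)[1L]
      stop("coincident bonded balls ", b$i[bad], " and ", b$j[bad])
    }
    fmag <- -2 * b$kb * (r - b$r0) / r
    fi <- d * fmag
    f <- addRowsAt(f, b$i, fi)
    f <- addRowsAt(f, b$j, -fi)
  }
  a <- tables$angles
  if (!is.null(a) && nrow(a)) {
    for (row in seq_len(nrow(a))) {
      fa <- angleForces(pos[a$i[row], ], pos[a$j[row], ], pos[a$k[row], ],
                        a$theta0[row], a$ktheta[row])
      f[a$i[row], ] <- f[a$i[row], ] + fa[1L, ]
      f[a$j[row], ] <- f[a$j[row], ] + fa[2L, ]
      f[a$k[row], ] <- f[a$k[row], ] + fa[3L, ]
    }
  }
  if (params@epsilon > 0 && n >= 2L) {
    pairs <- if (pairMethod == "cell") cellPairs(pos, params@cutoff) else {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      cbind(i = idx[, 1L], j = idx[, 2L])
    }
    if (nrow(pairs)) {
      key <- pairs[, 1L] * (n + 1) + pairs[, 2L]
      pairs <- pairs[!(key %in% tables$exclKey), , drop = FALSE]
    }
    if (nrow(pairs)) {
      i <- pairs[, 1L]; j <- pairs[, 2L]
      d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
      r <- rowNorms(d)
      within <- r < params@cutoff
      if (any(r == 0)) {
        bad <- which(r == 0)[1L]
        stop("coincident non-bonded balls ", i[bad], " and ", j[bad])
      }
      if (any(within)) {
        i <- i[within]; j <- j[within]
        d <- d[within, , drop = FALSE]; r <- r[within]
        rmin <- tables$radii[i] + tables$radii[j]
        fmag <- ljForceMag(r, rmin, params@epsilon, params@switchdist,
                           params@cutoff) / r
        fi <- d * fmag
        f <- addRowsAt(f, i, fi)
        f <- addRowsAt(f, j, -fi)
      }
    }
  }
  f
}

#' Total per-ball forces in a scene
#'
#' Sums bonded (bond and angle), non-bonded (switched Lennard-Jones over
#' non-excluded pairs within the cutoff; directly bonded pairs are
#' excluded, which covers all intra-rigid pairs) and external forces.
#' The Lennard-Jones contact distance of a pair is the sum of the two
#' ball radii.
#'
#' @param scene a [Scene-class].
#' @param params a [ForceFieldParams-class].
#' @param pairMethod "cell" for cell-list neighbour search (cell edge =
#'   cutoff) or "all" for the brute-force all-pairs loop.
#' @return numeric matrix of forces, one row per ball.
#' @export
totalForces <- function(scene, params = forceFieldParams(),
                        pairMethod = c("cell", "all")) {
  stopifnot(is(scene, "Scene"))
  .forcesCore(scene@positions, sceneTables(scene), params, scene@center,
              match.arg(pairMethod))
}

# Number of fractional substeps needed for linear stability of the
# stiffest bonded ball: the per-substep multiplier of a bonded normal
# mode is bounded by 1 - 2 kappa dtSub^2 / m with kappa the total
# incident bond stiffness (2 kb per bond); dtSub = dt / sqrt(n) keeps
# the substepped update's net free-ball displacement at (F/m) dt^2.
stabilitySubsteps <- function(tables, params) {
  b <- tables$bonds
  if (is.null(b) || nrow(b) == 0L) return(1L)
  kappa <- numeric(tables$n)
  for (side in c("i", "j")) {
    s <- rowsum(2 * b$kb, group = b[[side]], reorder = FALSE)
    rows <- as.integer(rownames(s))
    kappa[rows] <- kappa[rows] + s
  }
  max(1L, as.integer(ceiling(2 * params@dt^2 * max(kappa) /
                               params@mass)))
}

#' Advance a scene by one integration step
#'
#' First-order update: a = F/m, v = a dt, dx = v dt, i.e. the position
#' increment is (F/m) dt^2 computed from the instantaneous force only;
#' no velocity is carried between steps. Because this update is
#' linearly unstable for balls whose total incident bond stiffness
#' exceeds the stability bound (fully connected rigid models at the
#' default stiffness do), the step is evaluated as n fractional
#' substeps with dtSub = dt / sqrt(n); for a constant force the
#' substeps telescope to exactly the printed (F/m) dt^2, so unbonded
#' motion is unchanged.
#'
#' @param scene a [Scene-class].
#' @param params a [ForceFieldParams-class].
#' @param nSub number of substeps; NULL (default) picks the smallest
#'   stable count, 1 forces the single literal update.
#' @return the scene with updated positions.
#' @export
packStep <- function(scene, params = forceFieldParams(), nSub = NULL) {
  stopifnot(is(scene, "Scene"))
  tables <- sceneTables(scene)
  if (is.null(nSub)) nSub <- stabilitySubsteps(tables, params)
  pos <- scene@positions
  scaleSub <- params@dt^2 / (params@mass * nSub)
  for (s in seq_len(nSub)) {
    f <- .forcesCore(pos, tables, params, scene@center)
    if (!all(is.finite(f))) {
      bad <- which(!is.finite(rowSums(f)))[1L]
      stop("non-finite force on ball ", bad,
           " (structure ", scene@ballStructure[bad], ")")
    }
    pos <- pos + f * scaleSub
  }
  scene@positions <- pos
  scene
}

#' Randomly place structure copies in a box
#'
#' Each requested copy receives a uniform random orientation (uniform
#' over rotations, via random unit quaternions) and a uniform random
#' centroid position such that its bounding sphere stays inside the box;
#' placements are rejected until all bounding spheres are pairwise
#' disjoint.
#'
#' @param library list of template [BallStructure-class] objects.
#' @param counts integer copies per template (recycled to the library
#'   length).
#' @param box full box extents (length-3 or one number), centred on
#'   `center`.
#' @param seed integer seed; placement is reproducible.
#' @param center scene center.
#' @param maxTries rejection-sampling budget per copy.
#' @param restarts whole-scene restarts before giving up.
#' @return a [Scene-class].
#' @examples
#' lib <- fixtureStructureLibrary(2, seed = 1)
#' placeStructures(lib, counts = 2, box = 600, seed = 1)
#' @export
placeStructures <- function(library, counts = 1L, box = c(1200, 1200, 1200),
                            seed = 1L, center = c(0, 0, 0),
                            maxTries = 2000L, restarts = 20L) {
  if (is(library, "BallStructure")) library <- list(library)
  stopifnot(all(vapply(library, is, TRUE, "BallStructure")))
  counts <- rep_len(as.integer(counts), length(library))
  if (length(box) == 1L) box <- rep(box, 3L)
  box <- as.numeric(box)
  center <- as3d(center, "center")
  bound <- vapply(library, boundingRadius, numeric(1))
  total <- sum(counts)
  if (total == 0L) return(newScene(list(), box, center))
  sphereVol <- sum(rep(4 / 3 * pi * bound^3, counts))
  if (sphereVol > prod(box))
    stop("box too small: total bounding-sphere volume ",
         signif(sphereVol, 4), " exceeds the box volume ",
         signif(prod(box), 4))
  type <- rep(seq_along(library), counts)
  copyNo <- unlist(lapply(counts, seq_len), use.names = FALSE)
  rad <- bound[type]
  if (any(2 * rad > min(box)))
    stop("box too small for structure '",
         library[[type[which.max(rad)]]]@label,
         "' (bounding radius ", signif(max(rad), 4), ")")
  # largest instances first eases the rejection sampling; the scene
  # keeps the original library order
  ord <- order(-rad)
  withSeed(seed, {
    ctrs <- NULL
    for (attempt in seq_len(restarts)) {
      ctrs <- matrix(NA_real_, total, 3)
      failed <- FALSE
      for (pos in seq_len(total)) {
        inst <- ord[pos]
        lo <- center - box / 2 + rad[inst]
        hi <- center + box / 2 - rad[inst]
        prev <- ord[seq_len(pos - 1L)]
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          p <- lo + stats::runif(3) * (hi - lo)
          if (pos == 1L ||
              all(rowNorms(ctrs[prev, , drop = FALSE] -
                    matrix(p, pos - 1L, 3, byrow = TRUE)) >=
                  rad[inst] + rad[prev])) {
            ctrs[inst, ] <- p
            ok <- TRUE
            break
          }
        }
        if (!ok) { failed <- FALSE; failed <- TRUE; break }
      }
      if (!failed) break
      ctrs <- NULL
    }
    if (is.null(ctrs))
      stop("could not place all structures without overlap after ",
           restarts, " restarts of ", maxTries,
           " tries each; use a larger box")
    placed <- lapply(seq_len(total), function(inst) {
      tmpl <- library[[type[inst]]]
      tCtr <- colMeans(tmpl@centers)
      rel <- tmpl@centers - matrix(tCtr, nBalls(tmpl), 3, byrow = TRUE)
      out <- tmpl
      out@centers <- rel %*% t(randomRotation()) +
        matrix(ctrs[inst, ], nBalls(tmpl), 3, byrow = TRUE)
      out@label <- sprintf("%s_%d", tmpl@label, copyNo[inst])
      out
    })
    newScene(placed, box, center)
  })
}

#' Run the packing simulation
#'
#' Iterates [packStep()] up to `maxSteps`, recording position snapshots
#' (step 0, every `snapshotEvery` steps, and the final step), and stops
#' early once the mean per-ball displacement over a trailing window
#' falls below `tol`.
#'
#' @param scene a [Scene-class].
#' @param params a [ForceFieldParams-class].
#' @param maxSteps maximum number of steps (>= 1).
#' @param snapshotEvery snapshot cadence in steps.
#' @param tol convergence tolerance on the windowed mean per-ball
#'   displacement per step.
#' @param window number of trailing steps averaged by the stop rule.
#' @param nSub substeps per step (NULL = smallest stable count, see
#'   [packStep()]).
#' @return a [Trajectory-class]; the packed scene is
#'   `setPositions(scene, finalFrame(trajectory))`.
#' @export
runPacking <- function(scene, params = forceFieldParams(),
                       maxSteps = 2000L, snapshotEvery = 100L,
                       tol = 1e-3, window = 50L, nSub = NULL) {
  stopifnot(is(scene, "Scene"))
  maxSteps <- as.integer(maxSteps)
  if (maxSteps < 1L) stop("maxSteps must be >= 1")
  tables <- sceneTables(scene)
  if (is.null(nSub)) nSub <- stabilitySubsteps(tables, params)
  pos <- scene@positions
  n <- max(1L, nrow(pos))
  scaleSub <- params@dt^2 / (params@mass * nSub)
  steps <- 0L
  frames <- list(pos)
  recorded <- 0L
  disp <- numeric(window)
  converged <- FALSE
  for (stepIdx in seq_len(maxSteps)) {
    before <- pos
    for (sub in seq_len(nSub)) {
      f <- .forcesCore(pos, tables, params, scene@center)
      if (!all(is.finite(f))) {
        bad <- which(!is.finite(rowSums(f)))[1L]
        stop("non-finite force on ball ", bad, " at step ", stepIdx)
      }
      pos <- pos + f * scaleSub
    }
    dx <- pos - before
    disp[(stepIdx - 1L) %% window + 1L] <- sum(rowNorms(dx)) / n
    if (stepIdx %% snapshotEvery == 0L) {
      steps <- c(steps, stepIdx)
      frames[[length(frames) + 1L]] <- pos
      recorded <- stepIdx
    }
    if (stepIdx >= window && mean(disp) < tol) {
      converged <- TRUE
      if (recorded != stepIdx) {
        steps <- c(steps, stepIdx)
        frames[[length(frames) + 1L]] <- pos
        recorded <- stepIdx
      }
      break
    }
    if (stepIdx == maxSteps && recorded != stepIdx) {
      steps <- c(steps, stepIdx)
      frames[[length(frames) + 1L]] <- pos
    }
  }
  nTaken <- if (converged) stepIdx else maxSteps
  new("Trajectory", steps = as.integer(steps), frames = frames,
      converged = converged, nSteps = as.integer(nTaken))
}

#' Replace scene positions (keeping the initial snapshot)
#'
#' @param scene a [Scene-class].
#' @param pos new position matrix.
#' @return the updated scene.
#' @export
setPositions <- function(scene, pos) {
  positions(scene) <- pos
  scene
}

#' Per-structure centroids of a scene
#'
#' @param scene a [Scene-class].
#' @param initial use the initial snapshot instead of current positions.
#' @return numeric matrix, one centroid row per structure.
#' @export
structureCentroids <- function(scene, initial = FALSE) {
  pos <- if (initial) scene@initialPositions else scene@positions
  t(vapply(seq_along(scene@structures), function(s)
    colMeans(pos[scene@ballStructure == s, , drop = FALSE]),
    numeric(3)))
}
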