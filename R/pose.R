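#' @include AllClasses.R utils.R dynamics.R
NULL

#' Centroid of a set of ball centers
#'
#' @param balls numeric matrix of ball centers (rows).
#' @return the component-wise arithmetic mean, a 3-vector.
#' @export
structureCentroid <- function(balls) {
  balls <- as.matrix(balls)
  if (nrow(balls) < 1L) stop("centroid of an empty ball set")
  colMeans(balls)
}

#' Displacement vector between two centroids
#'
#' Computed as `init - final` (the convention used by the annotation
#' tables); set `fromInitial = TRUE` for the geometric initial-to-final
#' vector `final - init`.
#'
#' @param init,final 3D points.
#' @param fromInitial flip the sign to the initial-to-final direction.
#' @return a 3-vector.
#' @export
displacementVector <- function(init, final, fromInitial = FALSE) {
  init <- as3d(init, "init"); final <- as3d(final, "final")
  if (fromInitial) final - init else init - final
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle` radians about the (normalised) `axis`.
#'
#' @param axis 3D axis.
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  a <- normalize(as3d(axis, "axis"))
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Minimal rotation mapping one direction onto another
#'
#' Returns the rotation about axis a x b that maps the direction of `a`
#' onto the direction of `b`. For antiparallel inputs (axis undefined) a
#' deterministic perpendicular axis is used: the standard basis vector of
#' smallest index least aligned with `a`, orthogonalised against it.
#'
#' @param a,b nonzero 3D vectors.
#' @return 3 x 3 rotation matrix R with R a/|a| = b/|b|.
#' @export
rotationBetweenVectors <- function(a, b) {
  ah <- normalize(as3d(a, "a"))
  bh <- normalize(as3d(b, "b"))
  ct <- max(-1, min(1, sum(ah * bh)))
  axis <- c(ah[2] * bh[3] - ah[3] * bh[2],
            ah[3] * bh[1] - ah[1] * bh[3],
            ah[1] * bh[2] - ah[2] * bh[1])
  if (vnorm(axis) < 1e-12) {
    if (ct > 0) return(diag(3))
    ref <- diag(3)[, which.min(abs(ah))]
    perp <- normalize(ref - sum(ref * ah) * ah)
    return(rotationAboutAxis(perp, pi))
  }
  rotationAboutAxis(axis, atan2(vnorm(axis), ct))
}

#' Rigid rotation from two point triples
#'
#' Recovers the rotation that carried the non-collinear triple
#' (A0, B0, C0) to (A1, B1, C1): first the minimal rotation R_AB taking
#' the direction A0B0 to A1B1, then the residual spin R_AC about the
#' A1B1 axis that maps R_AB (A0C0) onto A1C1. The result R = R_AC R_AB
#' is orthonormal with determinant +1. If the two triples are not
#' related by a rigid motion the best fit about the two vectors is
#' returned with attribute `bestFit = TRUE`.
#'
#' @param A0,B0,C0 initial points (non-collinear).
#' @param A1,B1,C1 final points.
#' @param tol relative residual above which the result is flagged as a
#'   best fit.
#' @return 3 x 3 rotation matrix, possibly with attribute `bestFit`.
#' @export
extractRigidRotation <- function(A0, B0, C0, A1, B1, C1, tol = 1e-6) {
  A0 <- as3d(A0, "A0"); B0 <- as3d(B0, "B0"); C0 <- as3d(C0, "C0")
  A1 <- as3d(A1, "A1"); B1 <- as3d(B1, "B1"); C1 <- as3d(C1, "C1")
  ab0 <- B0 - A0; ac0 <- C0 - A0
  ab1 <- B1 - A1; ac1 <- C1 - A1
  crossNorm <- function(u, v) vnorm(c(u[2] * v[3] - u[3] * v[2],
                                      u[3] * v[1] - u[1] * v[3],
                                      u[1] * v[2] - u[2] * v[1]))
  if (vnorm(ab0) == 0 || vnorm(ac0) == 0 ||
      crossNorm(ab0, ac0) < 1e-10 * vnorm(ab0) * vnorm(ac0))
    stop("collinear initial points: rotation is not determined")
  if (vnorm(ab1) == 0 || vnorm(ac1) == 0 ||
      crossNorm(ab1, ac1) < 1e-10 * vnorm(ab1) * vnorm(ac1))
    stop("collinear final points: rotation is not determined")
  rAB <- rotationBetweenVectors(ab0, ab1)
  u <- normalize(ab1)
  v <- as.numeric(rAB %*% ac0)
  vp <- v - sum(v * u) * u
  wp <- ac1 - sum(ac1 * u) * u
  if (vnorm(vp) < 1e-12 || vnorm(wp) < 1e-12)
    stop("degenerate configuration: C lies on the AB axis")
  crossVW <- c(vp[2] * wp[3] - vp[3] * wp[2],
               vp[3] * wp[1] - vp[1] * wp[3],
               vp[1] * wp[2] - vp[2] * wp[1])
  spin <- atan2(sum(crossVW * u), sum(vp * wp))
  R <- rotationAboutAxis(u, spin) %*% rAB
  resid <- vnorm(as.numeric(R %*% ac0) - ac1) / max(vnorm(ac1), 1e-12)
  if (resid > tol) attr(R, "bestFit") <- TRUE
  R
}

#' ZYZ Euler angles of a rotation matrix
#'
#' Factors R = Rz(alpha) Ry(beta) Rz(gamma) with beta in [0, pi] and
#' alpha, gamma in (-pi, pi]. At gimbal lock (beta = 0 or pi) gamma is
#' set to 0 and the full spin folded into alpha.
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1, validated to
#'   1e-6).
#' @return numeric c(alpha, beta, gamma) in radians.
#' @export
eulerZYZFromMatrix <- function(R) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R is not a proper rotation matrix")
  fold <- function(x) if (x <= -pi) x + 2 * pi else x
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-9) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else if (R[3, 3] > 0) {      # beta = 0: R = Rz(alpha + gamma)
    beta <- 0
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {                        # beta = pi: R = Rz(alpha) Ry(pi)
    beta <- pi
    alpha <- atan2(-R[2, 1], R[2, 2])
    gamma <- 0
  }
  c(alpha = fold(alpha), beta = beta, gamma = fold(gamma))
}

#' Rotation matrix from ZYZ Euler angles
#'
#' @param angles numeric c(alpha, beta, gamma) in radians.
#' @return the matrix Rz(alpha) Ry(beta) Rz(gamma).
#' @export
matrixFromEulerZYZ <- function(angles) {
  angles <- as.numeric(angles)
  stopifnot(length(angles) == 3L)
  rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t),
                             0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(angles[1]) %*% ry(angles[2]) %*% rz(angles[3])
}

#' Per-structure ground-truth annotation of a packed scene
#'
#' For every structure: the initial and final centroids, the
#' displacement vector (initial minus final, the printed convention),
#' the ZYZ Euler angles of the rigid rotation extracted from the first
#' three ball centers (deformable structures are assigned zero rotation,
#' since they are rendered in their final shape), and the bounding
#' radius of the final ball configuration.
#'
#' @param scene a packed [Scene-class] (positions = final state).
#' @return data.frame with one row per structure: label, kind,
#'   deformable, x, y, z (final centroid), dx, dy, dz (displacement),
#'   alphaDeg, betaDeg, gammaDeg, radius.
#' @export
groundTruth <- function(scene) {
  stopifnot(is(scene, "Scene"))
  structs <- scene@structures
  rows <- lapply(seq_along(structs), function(s) {
    sel <- scene@ballStructure == s
    p0 <- scene@initialPositions[sel, , drop = FALSE]
    p1 <- scene@positions[sel, , drop = FALSE]
    c0 <- structureCentroid(p0)
    c1 <- structureCentroid(p1)
    disp <- displacementVector(c0, c1)
    deform <- structs[[s]]@kind != "rigid"
    if (deform) {
      eul <- c(0, 0, 0)
    } else {
      R <- extractRigidRotation(p0[1, ], p0[2, ], p0[3, ],
                                p1[1, ], p1[2, ], p1[3, ])
      eul <- eulerZYZFromMatrix(R)
    }
    ctr <- matrix(c1, nrow(p1), 3, byrow = TRUE)
    radius <- max(rowNorms(p1 - ctr) + structs[[s]]@radii)
    data.frame(label = structs[[s]]@label, kind = structs[[s]]@kind,
               deformable = deform,
               x = c1[1], y = c1[2], z = c1[3],
               dx = disp[1], dy = disp[2], dz = disp[3],
               alphaDeg = eul[1] * 180 / pi,
               betaDeg = eul[2] * 180 / pi,
               gammaDeg = eul[3] * 180 / pi,
               radius = radius, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
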