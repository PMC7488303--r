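# Shared oracles and fixture builders, independent of the package's
# internal computation paths.

# central-difference gradient of a scalar function of a coordinate vector
numGradient <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

# plain-loop all-pairs force summation, the O(N^2) reference for
# totalForces (uses only the exported scalar force functions)
bruteTotalForces <- function(scene, params) {
  pos <- positions(scene)
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (b in seq_len(n))
    f[b, ] <- externalForce(pos[b, ], params, sceneCenter(scene))
  structs <- structures(scene)
  offs <- cumsum(c(0L, vapply(structs, nBalls, 1L)))
  bondedKey <- character(0)
  for (s in seq_along(structs)) {
    tb <- bonds(structs[[s]])
    if (nrow(tb)) for (r in seq_len(nrow(tb))) {
      gi <- tb$i[r] + offs[s]; gj <- tb$j[r] + offs[s]
      bf <- bondForces(pos[gi, ], pos[gj, ], tb$r0[r], tb$kb[r])
      f[gi, ] <- f[gi, ] + bf$fi
      f[gj, ] <- f[gj, ] + bf$fj
      bondedKey <- c(bondedKey, paste(min(gi, gj), max(gi, gj)))
    }
    ta <- angles(structs[[s]])
    if (nrow(ta)) for (r in seq_len(nrow(ta))) {
      gi <- ta$i[r] + offs[s]; gj <- ta$j[r] + offs[s]
      gk <- ta$k[r] + offs[s]
      af <- angleForces(pos[gi, ], pos[gj, ], pos[gk, ],
                        ta$theta0[r], ta$ktheta[r])
      f[gi, ] <- f[gi, ] + af[1, ]
      f[gj, ] <- f[gj, ] + af[2, ]
      f[gk, ] <- f[gk, ] + af[3, ]
    }
  }
  radii <- unlist(lapply(structs, ballRadii))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% bondedKey) next
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r >= params@cutoff) next
    lf <- ljForces(pos[i, ], pos[j, ], radii[i] + radii[j],
                   params@epsilon, params@switchdist, params@cutoff)
    f[i, ] <- f[i, ] + lf$fi
    f[j, ] <- f[j, ] + lf$fj
  }
  f
}

# minimal PDB text with given coordinates (ATOM or HETATM records)
pdbText <- function(coords, record = "ATOM  ") {
  coords <- as.matrix(coords)
  vapply(seq_len(nrow(coords)), function(i) sprintf(
    "%s%5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    record, i, i, coords[i, 1], coords[i, 2], coords[i, 3]), "")
}

# three tight, well-separated point groups with known memberships
threeGroupCloud <- function(nPer = 100, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  pts <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(nPer * 3, sd = 3), nPer, 3) +
      matrix(centers[g, ], nPer, 3, byrow = TRUE)))
  list(cloud = AtomCloud(pts, "threegroups"),
       membership = rep(1:3, each = nPer), points = pts)
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x),
           1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
}

frobenius <- function(m) sqrt(sum(m^2))

# independent greedy-by-distance one-to-one matcher (plain loops)
bruteMatch <- function(peaks, truth) {
  nP <- nrow(peaks); nT <- nrow(truth)
  pairs <- NULL
  for (p in seq_len(nP)) for (t in seq_len(nT)) {
    d <- sqrt(sum((peaks[p, ] - c(truth$x[t], truth$y[t], truth$z[t]))^2))
    if (d <= truth$radius[t]) pairs <- rbind(pairs, c(p, t, d))
  }
  tp <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    usedP <- logical(nP); usedT <- logical(nT)
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, 1]; t <- pairs[r, 2]
      if (!usedP[p] && !usedT[t]) {
        usedP[p] <- TRUE; usedT[t] <- TRUE; tp <- tp + 1L
      }
    }
  }
  c(tp = tp, fp = nP - tp, fn = nT - tp)
}
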