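test_that("external field is centripetal, linear inside, saturated outside", {
  p <- forceFieldParams()
  expect_equal(externalForce(c(0, 0, 0), p), c(0, 0, 0))
  expect_equal(externalForce(c(100, 0, 0), p), c(-1000, 0, 0))
  expect_equal(externalForce(c(500, 0, 0), p), c(-3000, 0, 0))
  # continuity at the inner radius: both branches give 3000
  rIn <- externalForce(c(300 - 1e-9, 0, 0), p)
  rOut <- externalForce(c(300, 0, 0), p)
  expect_equal(sqrt(sum(rIn^2)), 3000, tolerance = 1e-8)
  expect_equal(sqrt(sum(rOut^2)), 3000)
  # direction always toward the configured center
  f <- externalForce(c(-50, 120, 10), p, center = c(10, 10, 10))
  expect_gt(sum(f * (c(10, 10, 10) - c(-50, 120, 10))), 0)
  expect_error(forceFieldParams(switchdist = 700, cutoff = 610))
})

test_that("bond potential and forces follow the harmonic spring", {
  expect_equal(bondEnergy(10, 10, 2000), 0)
  expect_equal(bondEnergy(11, 10, 2000), 2000)
  bf <- bondForces(c(0, 0, 0), c(10, 0, 0), r0 = 10)
  expect_equal(bf$fi, c(0, 0, 0))
  expect_equal(bf$fi, -bf$fj)
  expect_error(bondForces(c(1, 1, 1), c(1, 1, 1), r0 = 5), "coincident")
})

test_that("angle term vanishes at zero stiffness and at equilibrium", {
  expect_equal(angleEnergy(1.2, 1.2, 500), 0)
  af0 <- angleForces(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                     theta0 = 1, ktheta = 0)
  expect_true(all(af0 == 0))
  expect_error(angleForces(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                           theta0 = 1, ktheta = 2), "degenerate")
})

test_that("switched Lennard-Jones has its well, root and cutoff", {
  eps <- 1.3
  expect_equal(ljEnergy(60, rmin = 60, epsilon = eps), -eps)
  expect_equal(ljEnergy(60 * 2^(-1 / 6), rmin = 60, epsilon = eps), 0,
               tolerance = 1e-12)
  expect_equal(ljEnergy(610, rmin = 60), 0)
  expect_equal(ljEnergy(800, rmin = 60), 0)
  expect_equal(ljForceMag(650, rmin = 60), 0)
  # linear taper between S and C
  u605 <- ljEnergy(605, rmin = 200, switchdist = 600, cutoff = 610)
  raw <- 1 * ((200 / 605)^12 - 2 * (200 / 605)^6)
  expect_equal(u605, raw * 0.5)
  expect_error(ljEnergy(0, 60), "> 0")
})

test_that("analytic forces match central-difference gradients", {
  set.seed(101)
  for (rep in 1:100) {
    # bond
    xi <- rnorm(3, sd = 50); xj <- rnorm(3, sd = 50)
    while (sqrt(sum((xi - xj)^2)) < 1) xj <- xj + 1
    r0 <- runif(1, 20, 120); kb <- runif(1, 500, 4000)
    bf <- bondForces(xi, xj, r0, kb)
    gi <- numGradient(function(x)
      bondEnergy(sqrt(sum((x - xj)^2)), r0, kb), xi)
    expect_equal(bf$fi, -gi, tolerance = 1e-6)
    # angle (vertex at the middle ball)
    ktheta <- runif(1, 100, 2000); theta0 <- runif(1, 0.5, 2.5)
    xa <- rnorm(3, sd = 30); xv <- rnorm(3, sd = 30)
    xc <- rnorm(3, sd = 30)
    angOf <- function(a, v, c0) {
      u <- a - v; w <- c0 - v
      acos(max(-1, min(1, sum(u * w) /
                         sqrt(sum(u^2)) / sqrt(sum(w^2)))))
    }
    th <- angOf(xa, xv, xc)
    if (sqrt(sum((xa - xv)^2)) > 1 && sqrt(sum((xc - xv)^2)) > 1 &&
        th > 0.15 && th < pi - 0.15) {
      af <- angleForces(xa, xv, xc, theta0, ktheta)
      ga <- numGradient(function(x)
        angleEnergy(angOf(x, xv, xc), theta0, ktheta), xa)
      gv <- numGradient(function(x)
        angleEnergy(angOf(xa, x, xc), theta0, ktheta), xv)
      gc <- numGradient(function(x)
        angleEnergy(angOf(xa, xv, x), theta0, ktheta), xc)
      expect_equal(af[1, ], -ga, tolerance = 1e-5, ignore_attr = TRUE)
      expect_equal(af[2, ], -gv, tolerance = 1e-5, ignore_attr = TRUE)
      expect_equal(af[3, ], -gc, tolerance = 1e-5, ignore_attr = TRUE)
    }
    # switched LJ away from the taper kinks
    rmin <- runif(1, 40, 160)
    r <- sample(c(runif(1, 0.85 * rmin, 590), runif(1, 601, 609)), 1)
    lf <- ljForceMag(r, rmin)
    g <- numGradient(function(x) ljEnergy(x[1], rmin), r, h = 1e-4)
    expect_equal(lf, -g, tolerance = 1e-5)
  }
})

test_that("pair and triple forces obey Newton's third law", {
  set.seed(55)
  for (rep in 1:25) {
    xi <- rnorm(3, sd = 40); xj <- rnorm(3, sd = 40); xk <- rnorm(3, sd = 40)
    bf <- bondForces(xi, xj, r0 = 30)
    expect_equal(bf$fi + bf$fj, c(0, 0, 0), tolerance = 1e-9)
    lf <- ljForces(xi, xj, rmin = 50)
    expect_equal(lf$fi + lf$fj, c(0, 0, 0), tolerance = 1e-9)
    af <- angleForces(xi, xj, xk, theta0 = 1.5, ktheta = 800)
    expect_equal(colSums(af), c(0, 0, 0), tolerance = 1e-9)
    # zero net torque about the origin
    tq <- function(x, f) c(x[2] * f[3] - x[3] * f[2],
                           x[3] * f[1] - x[1] * f[3],
                           x[1] * f[2] - x[2] * f[1])
    expect_equal(tq(xi, af[1, ]) + tq(xj, af[2, ]) + tq(xk, af[3, ]),
                 c(0, 0, 0), tolerance = 1e-7)
  }
})

test_that("totalForces equals the brute-force all-pairs oracle", {
  set.seed(77)
  lib <- list(buildFilament(4, origin = c(150, 0, 0), axis = c(0, 1, 0)),
              coarseGrain(synthAtomCloud("globular", 5000, 120, seed = 2),
                          seed = 2),
              buildMembrane(2, 2, origin = c(-200, 50, 0)))
  scene <- placeStructures(lib, 1, box = 700, seed = 8)
  p <- forceFieldParams()
  expect_equal(totalForces(scene, p), bruteTotalForces(scene, p),
               tolerance = 1e-9)
  expect_equal(totalForces(scene, p, pairMethod = "all"),
               bruteTotalForces(scene, p), tolerance = 1e-9)
})

test_that("cell-list pair search equals the all-pairs set on sparse scenes", {
  set.seed(31)
  pos <- matrix(runif(150, -1500, 1500), 50, 3)
  pairs <- tomopack:::cellPairs(pos, 610)
  n <- nrow(pos)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((pos[idx[, 1], ] - pos[idx[, 2], ])^2))
  brute <- idx[d < 610, , drop = FALSE]
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]),
                                pmax(m[, 1], m[, 2])))
  expect_identical(key(pairs), key(brute))
})

test_that("a free structure outside the saturation radius moves 0.6 per step", {
  # two balls placed tangentially at equal radius: bond force is zero at
  # t = 0, so the first literal step is pure external field, 3000/5000
  fil <- buildFilament(2, origin = c(500, -20, 0), axis = c(0, 1, 0))
  sc <- newScene(list(fil), box = 2000)
  s1 <- packStep(sc, nSub = 1L)
  dx <- positions(s1) - positions(sc)
  expect_equal(sqrt(rowSums(dx^2)), c(0.6, 0.6), tolerance = 1e-12)
  # increments are deterministic
  s1b <- packStep(sc, nSub = 1L)
  expect_identical(positions(s1b), positions(s1))
})

test_that("a ball pinned at the scene center does not move", {
  tri <- coarseGrain(AtomCloud(rbind(c(0, 0, 0), c(40, 0, 0),
                                     c(0, 40, 0)), "tri"),
                     k = 3, seed = 1)
  sc <- newScene(list(tri), box = 1200,
                 center = colMeans(ballCenters(tri)))
  # total force on the centroid ball combination is symmetric; a single
  # step keeps the centroid fixed
  c0 <- colMeans(positions(sc))
  s1 <- packStep(sc)
  expect_equal(colMeans(positions(s1)), c0, tolerance = 1e-9)
})

test_that("placement is reproducible, disjoint, and validates the box", {
  lib <- fixtureStructureLibrary(3, seed = 2)
  expect_equal(nBalls(placeStructures(lib, 0, box = 800, seed = 1)), 0L)
  s1 <- placeStructures(lib, 2, box = 1200, seed = 9)
  s2 <- placeStructures(lib, 2, box = 1200, seed = 9)
  expect_identical(positions(s1), positions(s2))
  expect_equal(length(structures(s1)), 6L)
  ctr <- structureCentroids(s1, initial = TRUE)
  rad <- vapply(structures(s1), boundingRadius, numeric(1))
  for (i in 1:5) for (j in (i + 1):6)
    expect_gte(sqrt(sum((ctr[i, ] - ctr[j, ])^2)), rad[i] + rad[j])
  expect_error(placeStructures(lib, 20, box = 300, seed = 1),
               "box too small")
})

test_that("packing pulls structures together and preserves rigidity", {
  lib <- fixtureStructureLibrary(3, seed = 4)
  scene <- placeStructures(lib, 1, box = 520, seed = 4)
  traj <- runPacking(scene, maxSteps = 400, snapshotEvery = 200)
  expect_s4_class(traj, "Trajectory")
  expect_identical(frames(traj)[[1]], initialPositions(scene))
  expect_true(all(diff(frameSteps(traj)) > 0))
  packed <- setPositions(scene, finalFrame(traj))
  d0 <- dist(structureCentroids(packed, initial = TRUE))
  d1 <- dist(structureCentroids(packed))
  expect_true(all(d1 < d0))
  for (s in seq_along(lib)) {
    sel <- ballStructure(scene) == s
    i0 <- dist(initialPositions(scene)[sel, ])
    i1 <- dist(positions(packed)[sel, ])
    expect_lt(max(abs(i1 - i0) / i0), 0.01)
  }
  expect_error(runPacking(scene, maxSteps = 0), "maxSteps")
})

test_that("a single structure approaches the center monotonically", {
  st <- coarseGrain(synthAtomCloud("globular", 5000, 120, seed = 12),
                    seed = 12)
  st@centers <- st@centers -
    matrix(colMeans(st@centers) - c(420, 30, -50), nBalls(st), 3,
           byrow = TRUE)
  sc <- newScene(list(st), box = 1500)
  traj <- runPacking(sc, maxSteps = 300, snapshotEvery = 10)
  dists <- vapply(frames(traj),
                  function(x) sqrt(sum(colMeans(x)^2)), numeric(1))
  expect_true(all(diff(dists) <= 1e-9))
})

test_that("filament bonds stay near equilibrium in the quasi-static regime", {
  fil <- buildFilament(9, origin = c(200, -160, 0), axis = c(0, 1, 0))
  sc <- newScene(list(fil), box = 1200)
  traj <- runPacking(sc, maxSteps = 400, snapshotEvery = 400)
  x <- finalFrame(traj)
  b <- bonds(fil)
  dev <- abs(sqrt(rowSums((x[b$i, ] - x[b$j, ])^2)) - b$r0) / b$r0
  expect_lt(max(dev), 0.03)
  mem <- buildMembrane(5, 5, origin = c(200, -160, -160),
                       normal = c(1, 0, 0))
  sm <- newScene(list(mem), box = 1200)
  tm <- runPacking(sm, maxSteps = 400, snapshotEvery = 400)
  xm <- finalFrame(tm)
  bm <- bonds(mem)
  devm <- abs(sqrt(rowSums((xm[bm$i, ] - xm[bm$j, ])^2)) - bm$r0) / bm$r0
  expect_lt(max(devm), 0.01)
})
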