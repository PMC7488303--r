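test_that("rasterization conserves per-ball mass and peaks at centers", {
  st <- coarseGrain(synthAtomCloud("globular", 5000, 120, seed = 41),
                    seed = 41)
  v <- rasterizeStructure(st)
  expect_s4_class(v, "DensityVolume")
  expect_equal(sum(voxelData(v)) * voxelSize(v)^3, sum(ballMasses(st)),
               tolerance = 1e-6)
  # two distant identical balls: argmax voxel sits at a ball center and
  # the two local maxima are equal by symmetry
  single <- rasterizeStructure(
    buildFilament(2, origin = c(0, 0, 0), spacing = 400))
  arr <- voxelData(single)
  mid <- dim(arr)[1] %/% 2
  argmaxWorld <- function(a, xOff) {
    pk <- which(a == max(a), arr.ind = TRUE)[1, ]
    pk[1] <- pk[1] + xOff
    volumeOrigin(single) + (pk - 0.5) * voxelSize(single)
  }
  w1 <- argmaxWorld(arr[1:mid, , ], 0L)
  w2 <- argmaxWorld(arr[(mid + 1):dim(arr)[1], , ], mid)
  # one argmax voxel per ball center
  expect_lt(sqrt(sum(w1^2)), voxelSize(single) * sqrt(3))
  expect_lt(sqrt(sum((w2 - c(400, 0, 0))^2)),
            voxelSize(single) * sqrt(3))
  # two identical distant balls give two equal local maxima
  expect_equal(max(arr[1:mid, , ]), max(arr[(mid + 1):dim(arr)[1], , ]),
               tolerance = 1e-6)
})

test_that("random multi-ball structures integrate to their total mass", {
  set.seed(52)
  for (rep in 1:3) {
    centers <- matrix(runif(15, -100, 100), 5, 3)
    st <- coarseGrain(AtomCloud(centers, "pts"), k = 5, seed = rep)
    v <- rasterizeStructure(st, voxelSize = 5, resolution = 30)
    expect_equal(sum(voxelData(v)) * 5^3, sum(ballMasses(st)),
                 tolerance = 1e-6)
  }
})

test_that("rotating a map conserves its integral within interpolation loss", {
  st <- coarseGrain(synthAtomCloud("dumbbell", 9000, 140, seed = 17),
                    seed = 17)
  centers <- sweep(ballCenters(st), 2, colMeans(ballCenters(st)))
  # cubic grid covering the bounding sphere, so no density leaves the
  # grid under rotation and only interpolation loss remains
  reach <- max(sqrt(rowSums(centers^2))) + 3 * tomopack:::fwhmToSigma(40) + 20
  n <- ceiling(2 * reach / 10)
  arr <- tomopack:::splatBalls(array(0, c(n, n, n)), rep(-reach, 3), 10,
                               centers, ballMasses(st),
                               tomopack:::fwhmToSigma(40))
  ref <- DensityVolume(arr, 10, rep(-reach, 3))
  set.seed(4)
  R <- randomRotationMatrix()
  rot <- rotateVolume(ref, R, center = c(0, 0, 0))
  m0 <- sum(voxelData(ref)); m1 <- sum(voxelData(rot))
  expect_lt(abs(m1 - m0) / m0, 0.005)
})

test_that("scene composition matches direct rasterization of rotated balls", {
  st <- coarseGrain(synthAtomCloud("dumbbell", 12000, 150, seed = 23),
                    seed = 23)
  scene <- placeStructures(list(st), 1, box = 400, seed = 6)
  pos <- positions(scene)
  set.seed(9)
  R <- randomRotationMatrix()
  ctr <- colMeans(pos)
  pos2 <- t(R %*% t(sweep(pos, 2, ctr))) +
    matrix(ctr + c(30, -20, 10), nrow(pos), 3, byrow = TRUE)
  packed <- setPositions(scene, pos2)
  viaMap <- composeSceneMap(packed)
  # oracle path: rasterize the rotated balls directly on the same grid
  direct <- voxelData(viaMap) * 0
  direct <- tomopack:::splatBalls(direct, volumeOrigin(viaMap),
                                  voxelSize(viaMap), pos2,
                                  ballMasses(st),
                                  tomopack:::fwhmToSigma(40))
  num <- sqrt(mean((voxelData(viaMap) - direct)^2))
  den <- sqrt(mean(direct^2))
  expect_lt(num / den, 0.02)
})

test_that("scene maps are additive over structures", {
  lib <- fixtureStructureLibrary(2, seed = 3)
  scene <- placeStructures(lib, 1, box = 420, seed = 5)
  both <- composeSceneMap(scene)
  single <- lapply(1:2, function(s) {
    sub <- newScene(structures(scene)[s], box = sceneBox(scene))
    composeSceneMap(sub)
  })
  # identical grids by construction (same box); sum of singles = pair map
  expect_equal(dim(voxelData(both)), dim(voxelData(single[[1]])))
  expect_equal(voxelData(both),
               voxelData(single[[1]]) + voxelData(single[[2]]),
               tolerance = 1e-9)
})

test_that("empty scenes render to an all-zero volume", {
  empty <- placeStructures(fixtureStructureLibrary(1, seed = 1), 0,
                           box = 500, seed = 1)
  v <- composeSceneMap(empty)
  expect_true(all(voxelData(v) == 0))
})

test_that("addNoise hits the requested variance ratio and is seeded", {
  ctr <- blobLattice(12, 64, minSep = 15, seed = 3)
  vol <- synthBlobVolume(ctr, sigma = 2, gridDim = 64)$volume
  noisy1 <- addNoise(vol, snr = 1, seed = 7)
  noiseVar <- var(as.vector(voxelData(noisy1) - voxelData(vol)))
  expect_lt(abs(noiseVar / var(as.vector(voxelData(vol))) - 1), 0.05)
  noisy2 <- addNoise(vol, snr = 1, seed = 7)
  expect_identical(voxelData(noisy1), voxelData(noisy2))
  # snr -> infinity limit: output approaches the input
  faint <- addNoise(vol, snr = 1e12, seed = 1)
  expect_lt(max(abs(voxelData(faint) - voxelData(vol))),
            1e-4 * max(voxelData(vol)))
  flat <- DensityVolume(array(1, c(8, 8, 8)))
  expect_error(addNoise(flat, 100), "zero-variance")
})

test_that("measureSNR inverts addNoise and scales with noise power", {
  ctr <- blobLattice(12, 64, minSep = 15, seed = 5)
  vol <- synthBlobVolume(ctr, sigma = 2, gridDim = 64)$volume
  noisy <- addNoise(vol, snr = 200, seed = 11)
  m <- measureSNR(vol, noisy)
  expect_gt(m, 190); expect_lt(m, 210)
  expect_equal(measureSNR(vol, vol), Inf)
  # doubling the noise sd quarters the measured SNR
  delta <- voxelData(noisy) - voxelData(vol)
  noisy2 <- DensityVolume(voxelData(vol) + 2 * delta, voxelSize(vol),
                          volumeOrigin(vol))
  expect_equal(measureSNR(vol, noisy2), m / 4, tolerance = 1e-9)
  small <- DensityVolume(array(rnorm(27), c(3, 3, 3)))
  expect_error(measureSNR(vol, small), "shapes")
})

test_that("added noise is white at lag one voxel", {
  ctr <- blobLattice(12, 64, minSep = 15, seed = 9)
  vol <- synthBlobVolume(ctr, sigma = 2, gridDim = 64)$volume
  noise <- voxelData(addNoise(vol, snr = 200, seed = 2)) -
    voxelData(vol)
  for (d in 1:3) {
    n <- dim(noise)[d]
    a <- switch(d, noise[-n, , ], noise[, -n, ], noise[, , -n])
    b <- switch(d, noise[-1, , ], noise[, -1, ], noise[, , -1])
    expect_lt(abs(cor(as.vector(a), as.vector(b))), 0.05)
  }
})
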