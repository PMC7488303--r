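test_that("parsePdbAtoms extracts coordinates in file order", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  cloud <- parsePdbAtoms(pdbText(coords), "toy")
  expect_equal(unname(atomCoords(cloud)), unname(coords))
  expect_equal(nAtoms(cloud), 3L)
  expect_equal(sourceId(cloud), "toy")
})

test_that("parsePdbAtoms includes HETATM records and rejects empty input", {
  coords <- rbind(c(5, 6, 7), c(8, 9, 10))
  cloud <- parsePdbAtoms(pdbText(coords, record = "HETATM"), "het")
  expect_equal(nAtoms(cloud), 2L)
  expect_error(parsePdbAtoms("REMARK nothing here", "empty"),
               "no ATOM/HETATM.*empty")
  expect_error(parsePdbAtoms("", "blank"), "no ATOM/HETATM")
})

test_that("parsePdbAtoms keeps first altloc and first model only", {
  base <- sprintf(paste0("ATOM  %5d  CA %sALA A%4d    ",
                         "%8.3f%8.3f%8.3f  1.00  0.00           C"),
                  1:2, c("A", "B"), c(1, 1), c(1, 9), c(2, 9), c(3, 9))
  cloud <- parsePdbAtoms(paste(base, collapse = "\n"), "alt")
  expect_equal(nAtoms(cloud), 1L)
  expect_equal(unname(atomCoords(cloud)[1, ]), c(1, 2, 3))
  multi <- c(pdbText(rbind(c(1, 1, 1))), "ENDMDL",
             pdbText(rbind(c(2, 2, 2))))
  cloud2 <- parsePdbAtoms(multi, "models")
  expect_equal(nAtoms(cloud2), 1L)
})

test_that("parsePdbAtoms agrees with bio3d on a fixture file", {
  set.seed(7)
  coords <- matrix(round(rnorm(30 * 3, sd = 20), 3), 30, 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdbText(coords), "END"), path)
  mine <- atomCoords(readPdbAtoms(path))
  ref <- matrix(bio3d::read.pdb(path)$xyz, ncol = 3, byrow = TRUE)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
})

test_that("clusterCount applies the 5000-atom rule with floor 3", {
  expect_identical(clusterCount(4000), 3L)
  expect_identical(clusterCount(16000), 4L)
  expect_identical(clusterCount(15000), 3L)
  expect_error(clusterCount(0), "positive")
  ns <- c(1, 7, 4999, 5000, 5001, 10000, 14999, 15001,
          sample.int(30000, 50))
  for (n in ns)
    expect_identical(clusterCount(n),
                     max(3L, as.integer(ceiling(n / 5000))))
})

test_that("coarseGrain recovers well-separated groups exactly", {
  fx <- threeGroupCloud()
  st <- coarseGrain(fx$cloud, k = 3, seed = 11)
  expect_s4_class(st, "BallStructure")
  expect_equal(structureKind(st), "rigid")
  expect_equal(nBalls(st), 3L)
  expect_equal(nrow(bonds(st)), 3L)
  # map recovered balls to true groups by nearest true centroid
  trueCenters <- t(vapply(1:3, function(g)
    colMeans(fx$points[fx$membership == g, ]), numeric(3)))
  perm <- apply(ballCenters(st), 1, function(ctr)
    which.min(colSums((t(trueCenters) - ctr)^2)))
  expect_setequal(perm, 1:3)
  for (b in 1:3) {
    g <- perm[b]
    member <- fx$points[fx$membership == g, ]
    expect_equal(unname(ballCenters(st)[b, ]), colMeans(member),
                 tolerance = 1e-8)
    expectRad <- max(sqrt(rowSums(
      (member - matrix(colMeans(member), nrow(member), 3,
                       byrow = TRUE))^2)))
    expect_equal(ballRadii(st)[b], expectRad, tolerance = 1e-8)
  }
  expect_true(all(ballMasses(st) == 5000))
})

test_that("coarseGrain matches the stats::kmeans partition on separated data", {
  fx <- threeGroupCloud(nPer = 60, seed = 5)
  st <- coarseGrain(fx$cloud, k = 3, seed = 3)
  ref <- stats::kmeans(fx$points, centers = 3, nstart = 5,
                       algorithm = "Lloyd", iter.max = 100)
  ours <- structMetadata(st)$cluster
  # same partition up to label permutation
  expect_equal(length(unique(paste(ours, ref$cluster))), 3L)
})

test_that("coarse graining is a partition with covering radii", {
  cloud <- synthAtomCloud("dumbbell", 9000, extent = 150, seed = 21)
  st <- coarseGrain(cloud, seed = 2)
  cl <- structMetadata(st)$cluster
  expect_equal(length(cl), nAtoms(cloud))
  expect_equal(sum(table(cl)), nAtoms(cloud))
  pts <- atomCoords(cloud)
  slack <- 0
  for (b in seq_len(nBalls(st))) {
    member <- pts[cl == b, , drop = FALSE]
    d <- sqrt(rowSums((member - matrix(ballCenters(st)[b, ],
                                       nrow(member), 3, byrow = TRUE))^2))
    expect_lte(max(d), ballRadii(st)[b] + 1e-9)
    slack <- max(slack, ballRadii(st)[b] - max(d))
  }
  expect_lt(slack, 1e-9)  # radius attained by at least one atom per ball
})

test_that("coarseGrain is deterministic and validates its inputs", {
  cloud <- synthAtomCloud("globular", 4000, extent = 120, seed = 9)
  a <- coarseGrain(cloud, seed = 4)
  b <- coarseGrain(cloud, seed = 4)
  expect_identical(ballCenters(a), ballCenters(b))
  expect_identical(ballRadii(a), ballRadii(b))
  expect_error(coarseGrain(cloud, k = 5000), "exceeds")
  line <- AtomCloud(cbind(seq_len(100), 0, 0), "line")
  expect_error(coarseGrain(line, k = 3, seed = 1), "collinear")
  three <- AtomCloud(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), "tri")
  st3 <- coarseGrain(three, k = 3, seed = 1)
  expect_equal(sort(ballRadii(st3)), c(0, 0, 0))
  expect_equal(st3@centers[order(st3@centers[, 1], st3@centers[, 2]), ],
               rbind(c(0, 0, 0), c(0, 10, 0), c(10, 0, 0)),
               ignore_attr = TRUE)
})

test_that("buildFilament builds a chain with end degree 1", {
  f9 <- buildFilament(9)
  expect_equal(nBalls(f9), 9L)
  expect_equal(nrow(bonds(f9)), 8L)
  expect_equal(nrow(angles(f9)), 7L)
  f2 <- buildFilament(2)
  expect_equal(nrow(bonds(f2)), 1L)
  expect_equal(nrow(angles(f2)), 0L)
  f5 <- buildFilament(5)
  expect_equal(ballDegrees(f5), c(1L, 2L, 2L, 2L, 1L))
  expect_error(buildFilament(1), "at least 2")
  # collinear centers at the requested spacing
  d <- diff(ballCenters(f9)[, 1])
  expect_equal(d, rep(40, 8))
  expect_true(all(ballCenters(f9)[, 2:3] == 0))
})

test_that("buildMembrane builds the 8-neighbour mesh", {
  m33 <- buildMembrane(3, 3)
  expect_equal(nBalls(m33), 9L)
  expect_equal(nrow(bonds(m33)), 20L)  # 12 axial + 8 diagonal
  deg <- ballDegrees(m33)
  expect_equal(sort(deg), c(3L, 3L, 3L, 3L, 5L, 5L, 5L, 5L, 8L))
  m22 <- buildMembrane(2, 2)
  expect_equal(nrow(bonds(m22)), 6L)
  expect_equal(ballDegrees(m22), rep(3L, 4))
  expect_error(buildMembrane(1, 3), "m >= 2")
  # bond-count formula on assorted grids
  for (mn in list(c(2, 5), c(4, 4), c(3, 6))) {
    mem <- buildMembrane(mn[1], mn[2])
    m <- mn[1]; n <- mn[2]
    expect_equal(nrow(bonds(mem)),
                 m * (n - 1) + n * (m - 1) + 2 * (m - 1) * (n - 1))
  }
})

test_that("degree sums equal twice the bond count for any structure", {
  structs <- list(buildFilament(7), buildMembrane(4, 5),
                  coarseGrain(synthAtomCloud("globular", 16000, 150,
                                             seed = 3), seed = 3))
  for (st in structs)
    expect_equal(sum(ballDegrees(st)), 2L * nrow(bonds(st)))
})

test_that("ball models round-trip through the pseudo-atom PDB writer", {
  st <- coarseGrain(synthAtomCloud("globular", 5000, 120, seed = 6),
                    seed = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeBallPdb(st, path)
  back <- readPdbAtoms(path)
  expect_equal(unname(atomCoords(back)), unname(ballCenters(st)),
               tolerance = 1e-3)
  # radii live in the B-factor column
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  bfac <- as.numeric(substr(lines, 61, 66))
  expect_equal(bfac, ballRadii(st), tolerance = 0.01)
})

test_that("topology files carry bonds and angles with 0-based indices", {
  f <- buildFilament(4)
  path <- withr::local_tempfile(fileext = ".top")
  writeTopologyFile(f, path)
  lines <- readLines(path)
  bondLines <- strsplit(grep("^BOND", lines, value = TRUE), " ")
  expect_equal(length(bondLines), 3L)
  expect_equal(as.integer(bondLines[[1]][2:3]), c(0L, 1L))
  expect_equal(as.numeric(bondLines[[1]][4:5]), c(40, 2000))
  angleLines <- strsplit(grep("^ANGLE", lines, value = TRUE), " ")
  expect_equal(length(angleLines), 2L)
  expect_equal(as.numeric(angleLines[[1]][5]), pi, tolerance = 1e-5)
})
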