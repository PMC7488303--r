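#' @include AllClasses.R utils.R volume.R pose.R
NULL

#' Write a density volume as an MRC/CCP4 map (mode 2, float32)
#'
#' Little-endian 1024-byte header followed by float32 voxel data in
#' x-fastest order (the package's in-memory layout). Cell dimensions are
#' grid extent times voxel size; the world origin is stored in the
#' ORIGIN header words.
#'
#' @param volume a [DensityVolume-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMRC <- function(volume, path) {
  stopifnot(is(volume, "DensityVolume"))
  dims <- dim(volume@data)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  vals <- as.vector(volume@data)
  wInt(dims)                                  # NX NY NZ
  wInt(2L)                                    # MODE 2 = float32
  wInt(c(0L, 0L, 0L))                         # NXSTART..
  wInt(dims)                                  # MX MY MZ
  wFlt(dims * volume@voxelSize)               # CELLA
  wFlt(c(90, 90, 90))                         # CELLB
  wInt(c(1L, 2L, 3L))                         # MAPC MAPR MAPS
  wFlt(c(min(vals), max(vals), mean(vals)))   # DMIN DMAX DMEAN
  wInt(c(1L, 0L))                             # ISPG NSYMBT
  wInt(rep(0L, 25L))                          # EXTRA
  wFlt(volume@origin)                         # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST (LE)
  wFlt(stats::sd(vals))                       # RMS
  wInt(0L)                                    # NLABL
  wInt(rep(0L, 200L))                         # LABELS
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC/CCP4 map (mode 2)
#'
#' @param path path to an MRC file written by [writeMRC()] or another
#'   mode-2 writer with x-fastest axis order.
#' @return a [DensityVolume-class]; the voxel size is CELLA / MX and the
#'   origin comes from the ORIGIN words.
#' @export
readMRC <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("not an MRC file (", path, "): shorter than the 1024-byte ",
         "header")
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(n) readBin(con, "integer", n, size = 4L,
                              endian = "little")
  rFlt <- function(n) readBin(con, "numeric", n, size = 4L,
                              endian = "little")
  dims <- rInt(3L)
  mode <- rInt(1L)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " at byte offset 12 (",
         "only mode 2 float32 is handled)")
  rInt(3L)                  # NXSTART
  mxyz <- rInt(3L)
  cella <- rFlt(3L)
  rFlt(3L)                  # CELLB
  mapcrs <- rInt(3L)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order (MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","), ") at byte offset 64")
  rFlt(3L)                  # DMIN DMAX DMEAN
  rInt(2L)                  # ISPG NSYMBT
  rInt(25L)                 # EXTRA
  origin <- rFlt(3L)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "MAP "))
    stop("missing 'MAP ' magic at byte offset 208 in ", path)
  readBin(con, "raw", 4L)   # MACHST
  rFlt(1L)                  # RMS
  rInt(201L)                # NLABL + labels
  n <- prod(dims)
  expect <- 1024 + 4 * n
  if (sz < expect)
    stop("truncated MRC file ", path, ": expected ", expect,
         " bytes, found ", sz)
  vals <- rFlt(n)
  if (length(vals) != n)
    stop("truncated MRC data block in ", path)
  voxel <- if (all(mxyz > 0)) cella[1] / mxyz[1] else 1
  DensityVolume(array(vals, dims), voxel, origin)
}

.pdbAtomLine <- function(serial, pos, bfac, resSeq) {
  sprintf(
    "ATOM  %5d  CA  BAL A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    serial %% 100000L, resSeq %% 10000L, pos[1], pos[2], pos[3], 1,
    min(bfac, 999.99))
}

#' Write ball models as a pseudo-atom PDB file
#'
#' One ATOM record per ball, with the ball radius stored in the B-factor
#' column.
#'
#' @param structures a [BallStructure-class], a list of them, or a
#'   [Scene-class] (current positions are used).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBallPdb <- function(structures, path) {
  if (is(structures, "Scene")) {
    sc <- structures
    structures <- lapply(seq_along(sc@structures), function(s) {
      st <- sc@structures[[s]]
      st@centers <- sc@positions[sc@ballStructure == s, , drop = FALSE]
      st
    })
  }
  if (is(structures, "BallStructure")) structures <- list(structures)
  lines <- character(0)
  serial <- 0L
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    for (b in seq_len(nBalls(st))) {
      serial <- serial + 1L
      lines <- c(lines, .pdbAtomLine(serial, st@centers[b, ],
                                     st@radii[b], s))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a packing trajectory as a multi-model pseudo-atom PDB
#'
#' @param scene the [Scene-class] the trajectory belongs to.
#' @param trajectory a [Trajectory-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryPdb <- function(scene, trajectory, path) {
  stopifnot(is(scene, "Scene"), is(trajectory, "Trajectory"))
  radii <- unlist(lapply(scene@structures, ballRadii), use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(trajectory@frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    pos <- trajectory@frames[[f]]
    lines <- vapply(seq_len(nrow(pos)), function(b)
      .pdbAtomLine(b, pos[b, ], radii[b], scene@ballStructure[b]), "")
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a plain-text topology file
#'
#' One `BOND i j r0 kb` line per bond and one
#' `ANGLE i j k theta0 ktheta` line per angle, with 0-based ball
#' indices.
#'
#' @param structure a [BallStructure-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTopologyFile <- function(structure, path) {
  stopifnot(is(structure, "BallStructure"))
  b <- structure@topology@bonds
  a <- structure@topology@angles
  lines <- c(
    if (nrow(b)) sprintf("BOND %d %d %.6g %.6g", b$i - 1L, b$j - 1L,
                         b$r0, b$kb),
    if (nrow(a)) sprintf("ANGLE %d %d %d %.6g %.6g", a$i - 1L,
                         a$j - 1L, a$k - 1L, a$theta0, a$ktheta))
  writeLines(c(lines, character(0)), path)
  invisible(path)
}

#' Write the ground-truth table as CSV and JSON
#'
#' @param truth a [groundTruth()] data.frame.
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return invisibly, the written paths.
#' @export
writeGroundTruth <- function(truth, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is.data.frame(truth))
  if (!is.null(csvPath))
    utils::write.csv(truth, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(truth, jsonPath, dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
  invisible(c(csv = csvPath, json = jsonPath))
}

#' Read a ground-truth CSV
#'
#' @param path path to a CSV written by [writeGroundTruth()].
#' @return the truth data.frame.
#' @export
readGroundTruth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
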