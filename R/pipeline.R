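#' @include AllClasses.R structures.R dynamics.R pose.R volume.R
#' @include picking.R fixtures.R io.R
NULL

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()]. The
#' `preset` picks the structure library: "small-scene" is five rigid
#' synthetic macromolecules in a 500-unit box; "mixed-scene" adds a
#' 9-ball filament and a 5x5 membrane to six rigid structures in a
#' 900-unit box. Alternatively supply `pdbPaths` to coarse-grain real
#' structure files.
#'
#' @param preset "small-scene" or "mixed-scene".
#' @param seed master seed; every random stage derives its own sub-seed
#'   from it.
#' @return a named list of pipeline settings.
#' @export
defaultConfig <- function(preset = c("small-scene", "mixed-scene"),
                          seed = 1L) {
  preset <- match.arg(preset)
  list(
    preset = preset,
    pdbPaths = NULL,
    counts = NULL,            # per-type copies; default 1 each
    box = if (preset == "small-scene") 500 else 900,
    steps = 2000L,
    snapshotEvery = 200L,
    voxelSize = 10,
    resolution = 40,
    snr = c(1000, 200),
    picking = list(sigma1 = 4, ratio = 1.1, t = 5, topK = "truth"),
    forceField = list(),
    seed = as.integer(seed)
  )
}

.configLibrary <- function(config) {
  if (!is.null(config$pdbPaths)) {
    return(lapply(config$pdbPaths, function(p)
      coarseGrain(readPdbAtoms(p), seed = subSeed(config$seed, 3L))))
  }
  if (identical(config$preset, "small-scene")) {
    fixtureStructureLibrary(5L, seed = config$seed)
  } else if (identical(config$preset, "mixed-scene")) {
    c(fixtureStructureLibrary(6L, seed = config$seed),
      list(buildFilament(9L),
           buildMembrane(5L, 5L)))
  } else stop("unknown preset '", config$preset, "'")
}

#' Run the full simulation pipeline
#'
#' Executes coarse-grain (library building), placement, packing, pose
#' extraction, rendering, noise addition and (optionally) DoG picking
#' with evaluation, writing every artifact into `outDir`:
#' `clean.mrc`, one `tomogram_snr<S>.mrc` per requested SNR,
#' `ground_truth.csv` / `.json`, `trajectory.pdb`, `balls.pdb`,
#' `picking_report.json`, `config.yaml` and `run.log`.
#'
#' @param config a configuration list from [defaultConfig()] (fields may
#'   be overridden).
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the scene, trajectory, truth table,
#'   volumes and picking scores.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    writeLines(logLines, logPath)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  library <- stage("library", .configLibrary(config))
  note("stage=library structures=", length(library))

  counts <- if (is.null(config$counts)) 1L else config$counts
  scene <- stage("place", placeStructures(
    library, counts = counts, box = config$box,
    seed = subSeed(config$seed, 1L)))
  note("stage=place balls=", nBalls(scene))

  ffArgs <- config$forceField
  params <- do.call(forceFieldParams, if (is.null(ffArgs)) list()
                    else ffArgs)
  traj <- stage("pack", runPacking(scene, params,
                                   maxSteps = config$steps,
                                   snapshotEvery = config$snapshotEvery))
  packed <- setPositions(scene, finalFrame(traj))
  note("stage=pack steps=", traj@nSteps, " converged=", traj@converged)
  writeTrajectoryPdb(packed, traj, file.path(outDir, "trajectory.pdb"))
  writeBallPdb(packed, file.path(outDir, "balls.pdb"))

  truth <- stage("pose", groundTruth(packed))
  writeGroundTruth(truth, file.path(outDir, "ground_truth.csv"),
                   file.path(outDir, "ground_truth.json"))
  note("stage=pose structures=", nrow(truth))

  clean <- stage("render", composeSceneMap(packed, config$voxelSize,
                                           config$resolution))
  writeMRC(clean, file.path(outDir, "clean.mrc"))
  note("stage=render dims=", paste(dim(voxelData(clean)),
                                   collapse = "x"))

  volumes <- list(clean = clean)
  scores <- list()
  for (i in seq_along(config$snr)) {
    snr <- config$snr[i]
    noisy <- stage("noise", addNoise(clean, snr,
                                     seed = subSeed(config$seed,
                                                    10L + i)))
    key <- paste0("snr", format(snr, scientific = FALSE))
    volumes[[key]] <- noisy
    writeMRC(noisy, file.path(outDir,
                              paste0("tomogram_", key, ".mrc")))
    note("stage=noise snr=", snr, " measured=",
         signif(measureSNR(clean, noisy), 5))
    pk <- config$picking
    if (!is.null(pk)) {
      topK <- pk$topK
      if (identical(topK, "truth")) topK <- nrow(truth)
      picks <- stage("pick", pickParticles(noisy, sigma1 = pk$sigma1,
                                           ratio = pk$ratio, t = pk$t,
                                           topK = topK))
      score <- stage("evaluate", evaluatePicking(picks, truth))
      scores[[key]] <- list(
        snr = snr, sigma1 = pk$sigma1, ratio = pk$ratio, t = pk$t,
        nPeaks = nPeaks(picks),
        tp = score@tp, fp = score@fp, fn = score@fn,
        precision = score@precision, recall = score@recall,
        fscore = score@fscore,
        peaks = unname(split(peakCoords(picks),
                             seq_len(nPeaks(picks)))))
      note("stage=pick snr=", snr, " peaks=", nPeaks(picks),
           " fscore=", signif(score@fscore, 4))
    }
  }
  if (length(scores))
    jsonlite::write_json(scores,
                         file.path(outDir, "picking_report.json"),
                         digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  note("stage=done")
  invisible(list(outDir = outDir, scene = packed, trajectory = traj,
                 truth = truth, volumes = volumes, scores = scores,
                 params = params))
}
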