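#' @include AllClasses.R
NULL

#' Accessors for tomopack classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the tomopack S4 classes.
#' @param value replacement value.
#' @return the slot contents (see the individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setMethod("atomCoords", "AtomCloud", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setMethod("sourceId", "AtomCloud", function(x) x@sourceId)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomCloud", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setGeneric("ballCenters", function(x) standardGeneric("ballCenters"))
#' @rdname accessors
#' @export
setMethod("ballCenters", "BallStructure", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("ballRadii", function(x) standardGeneric("ballRadii"))
#' @rdname accessors
#' @export
setMethod("ballRadii", "BallStructure", function(x) x@radii)

#' @rdname accessors
#' @export
setGeneric("ballMasses", function(x) standardGeneric("ballMasses"))
#' @rdname accessors
#' @export
setMethod("ballMasses", "BallStructure", function(x) x@masses)

#' @rdname accessors
#' @export
setGeneric("nBalls", function(x) standardGeneric("nBalls"))
#' @rdname accessors
#' @export
setMethod("nBalls", "BallStructure", function(x) nrow(x@centers))
#' @rdname accessors
#' @export
setMethod("nBalls", "Scene", function(x) nrow(x@positions))

#' @rdname accessors
#' @export
setGeneric("structureKind", function(x) standardGeneric("structureKind"))
#' @rdname accessors
#' @export
setMethod("structureKind", "BallStructure", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))
#' @rdname accessors
#' @export
setMethod("structureLabel", "BallStructure", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setMethod("topology", "BallStructure", function(x) x@topology)

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setMethod("bonds", "Topology", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("bonds", "BallStructure", function(x) x@topology@bonds)

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setMethod("angles", "Topology", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("angles", "BallStructure", function(x) x@topology@angles)

#' @rdname accessors
#' @export
setGeneric("structMetadata", function(x) standardGeneric("structMetadata"))
#' @rdname accessors
#' @export
setMethod("structMetadata", "BallStructure", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))
#' @rdname accessors
#' @export
setMethod("structures", "Scene", function(x) x@structures)

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "Scene", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))
#' @rdname accessors
#' @export
setMethod("positions<-", "Scene", function(x, value) {
  stopifnot(identical(dim(value), dim(x@positions)))
  x@positions <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("initialPositions",
           function(x) standardGeneric("initialPositions"))
#' @rdname accessors
#' @export
setMethod("initialPositions", "Scene", function(x) x@initialPositions)

#' @rdname accessors
#' @export
setGeneric("sceneBox", function(x) standardGeneric("sceneBox"))
#' @rdname accessors
#' @export
setMethod("sceneBox", "Scene", function(x) x@box)

#' @rdname accessors
#' @export
setGeneric("sceneCenter", function(x) standardGeneric("sceneCenter"))
#' @rdname accessors
#' @export
setMethod("sceneCenter", "Scene", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("ballStructure", function(x) standardGeneric("ballStructure"))
#' @rdname accessors
#' @export
setMethod("ballStructure", "Scene", function(x) x@ballStructure)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("frameSteps", function(x) standardGeneric("frameSteps"))
#' @rdname accessors
#' @export
setMethod("frameSteps", "Trajectory", function(x) x@steps)

#' @rdname accessors
#' @export
setGeneric("finalFrame", function(x) standardGeneric("finalFrame"))
#' @rdname accessors
#' @export
setMethod("finalFrame", "Trajectory",
          function(x) x@frames[[length(x@frames)]])

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setMethod("converged", "Trajectory", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setMethod("voxelData", "DensityVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname accessors
#' @export
setMethod("volumeOrigin", "DensityVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("peakCoords", function(x) standardGeneric("peakCoords"))
#' @rdname accessors
#' @export
setMethod("peakCoords", "PickResult", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("peakVoxels", function(x) standardGeneric("peakVoxels"))
#' @rdname accessors
#' @export
setMethod("peakVoxels", "PickResult", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("peakIntensities",
           function(x) standardGeneric("peakIntensities"))
#' @rdname accessors
#' @export
setMethod("peakIntensities", "PickResult", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))
#' @rdname accessors
#' @export
setMethod("nPeaks", "PickResult", function(x) length(x@intensities))

#' @rdname accessors
#' @export
setGeneric("scoreCounts", function(x) standardGeneric("scoreCounts"))
#' @rdname accessors
#' @export
setMethod("scoreCounts", "PickScore",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn))

#' @rdname accessors
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))
#' @rdname accessors
#' @export
setMethod("precision", "PickScore", function(x) x@precision)

#' @rdname accessors
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))
#' @rdname accessors
#' @export
setMethod("recall", "PickScore", function(x) x@recall)

#' @rdname accessors
#' @export
setGeneric("fScore", function(x) standardGeneric("fScore"))
#' @rdname accessors
#' @export
setMethod("fScore", "PickScore", function(x) x@fscore)

setMethod("show", "AtomCloud", function(object) {
  cat("AtomCloud", object@sourceId, "with", nrow(object@coords),
      "atoms\n")
})

setMethod("show", "BallStructure", function(object) {
  cat(sprintf("BallStructure '%s' (%s): %d balls, %d bonds, %d angles\n",
              object@label, object@kind, nrow(object@centers),
              nrow(object@topology@bonds), nrow(object@topology@angles)))
  cat(sprintf("  radii %.1f-%.1f, total mass %g\n",
              min(object@radii), max(object@radii), sum(object@masses)))
})

setMethod("show", "Scene", function(object) {
  kinds <- table(vapply(object@structures, structureKind, ""))
  cat(sprintf("Scene: %d structures (%s), %d balls, box %s\n",
              length(object@structures),
              paste(names(kinds), kinds, sep = ":", collapse = ", "),
              nrow(object@positions),
              paste(object@box, collapse = " x ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames over %d steps (%sconverged)\n",
              length(object@frames), object@nSteps,
              if (object@converged) "" else "not "))
})

setMethod("show", "DensityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DensityVolume %dx%dx%d, voxel %g, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], object@voxelSize,
    object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "PickResult", function(object) {
  cat(sprintf("PickResult: %d peaks (sigma1 = %g, ratio = %g, T = %g)\n",
              length(object@intensities), object@sigma1,
              object@sigmaRatio, object@threshold))
})

setMethod("show", "PickScore", function(object) {
  cat(sprintf(
    "PickScore: TP %d FP %d FN %d | precision %.4f recall %.4f F %.4f\n",
    object@tp, object@fp, object@fn, object@precision, object@recall,
    object@fscore))
})
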