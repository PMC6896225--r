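#' @name ringweld-accessors
#' @title Accessors for ringweld classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x a ringweld object.
#' @param value replacement value.
#' @param i frame index.
NULL

#' @rdname ringweld-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname ringweld-accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname ringweld-accessors
#' @export
setGeneric("beadIds", function(x) standardGeneric("beadIds"))
#' @rdname ringweld-accessors
#' @export
setGeneric("beadKind", function(x) standardGeneric("beadKind"))
#' @rdname ringweld-accessors
#' @export
setGeneric("protomerIndex", function(x) standardGeneric("protomerIndex"))
#' @rdname ringweld-accessors
#' @export
setGeneric("moleculeIndex", function(x) standardGeneric("moleculeIndex"))
#' @rdname ringweld-accessors
#' @export
setGeneric("leafletTag", function(x) standardGeneric("leafletTag"))
#' @rdname ringweld-accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))
#' @rdname ringweld-accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname ringweld-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname ringweld-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname ringweld-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname ringweld-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname ringweld-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname ringweld-accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname ringweld-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname ringweld-accessors
#' @export
setMethod("coords", "BeadSystem", function(x) x@coords)

#' @rdname ringweld-accessors
#' @export
setReplaceMethod("coords", "BeadSystem", function(x, value) {
  stopifnot(is.matrix(value), all(dim(value) == dim(x@coords)))
  x@coords <- value
  x
})

#' @rdname ringweld-accessors
#' @export
setMethod("beadIds", "BeadSystem", function(x) x@beadId)
#' @rdname ringweld-accessors
#' @export
setMethod("beadKind", "BeadSystem", function(x) x@kind)
#' @rdname ringweld-accessors
#' @export
setMethod("protomerIndex", "BeadSystem", function(x) x@protomer)
#' @rdname ringweld-accessors
#' @export
setMethod("moleculeIndex", "BeadSystem", function(x) x@molecule)
#' @rdname ringweld-accessors
#' @export
setMethod("leafletTag", "BeadSystem", function(x) x@leaflet)
#' @rdname ringweld-accessors
#' @export
setMethod("boxDims", "BeadSystem", function(x) x@box)
#' @rdname ringweld-accessors
#' @export
setMethod("nBeads", "BeadSystem", function(x) length(x@beadId))

#' @rdname ringweld-accessors
#' @export
setMethod("nFrames", "BeadTrajectory", function(x) length(x@times))
#' @rdname ringweld-accessors
#' @export
setMethod("frameTimes", "BeadTrajectory", function(x) x@times)
#' @rdname ringweld-accessors
#' @export
setMethod("nBeads", "BeadTrajectory", function(x) length(x@system@beadId))
#' @rdname ringweld-accessors
#' @export
setMethod("coords", "BeadTrajectory", function(x) x@coords)

#' @rdname ringweld-accessors
#' @export
setMethod("getFrame", "BeadTrajectory", function(x, i) {
  if (i < 1 || i > length(x@times))
    rwStop("rw_size_error", sprintf("frame index %d out of range", i))
  s <- x@system
  s@coords <- x@coords[, , i, drop = TRUE]
  dim(s@coords) <- c(dim(x@coords)[1], 3)
  s@box <- x@boxes[i, ]
  s
})

#' @rdname ringweld-accessors
#' @export
setMethod("gridOrigin", "DensityGrid", function(x) x@origin)
#' @rdname ringweld-accessors
#' @export
setMethod("gridSpacing", "DensityGrid", function(x) x@spacing)
#' @rdname ringweld-accessors
#' @export
setMethod("gridDims", "DensityGrid", function(x) dim(x@values))
#' @rdname ringweld-accessors
#' @export
setMethod("gridValues", "DensityGrid", function(x) x@values)
#' @rdname ringweld-accessors
#' @export
setMethod("gridOrigin", "DensityMask", function(x) x@origin)
#' @rdname ringweld-accessors
#' @export
setMethod("gridSpacing", "DensityMask", function(x) x@spacing)
#' @rdname ringweld-accessors
#' @export
setMethod("gridDims", "DensityMask", function(x) dim(x@values))
#' @rdname ringweld-accessors
#' @export
setMethod("gridValues", "DensityMask", function(x) x@values)

setMethod("show", "BeadSystem", function(object) {
  tab <- table(object@kind)
  cat(sprintf("BeadSystem: %d beads (%s)\n", length(object@beadId),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  np <- length(unique(object@protomer[!is.na(object@protomer)]))
  cat(sprintf("  protomers: %d, molecules: %d\n", np,
              length(unique(object@molecule))))
  cat(sprintf("  box: %.2f x %.2f x %.2f nm, periodic x,y: %s\n",
              object@box[1], object@box[2], object@box[3], object@periodicXY))
})

setMethod("show", "BeadTrajectory", function(object) {
  nf <- length(object@times)
  cat(sprintf("BeadTrajectory: %d frames x %d beads\n", nf,
              length(object@system@beadId)))
  if (nf > 0)
    cat(sprintf("  time: %.1f .. %.1f ps\n", object@times[1],
                object@times[nf]))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels, spacing %.3f %.3f %.3f A\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A, range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "DensityMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityMask: %d x %d x %d voxels, %d selected\n",
              d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "AssemblyResult", function(object) {
  cat(sprintf("AssemblyResult: %s\n", object@outcome))
  cat(sprintf("  final RMSD %.3f A; convergence time %s ps\n",
              object@finalRmsd,
              if (is.na(object@convergenceTime)) "n.d."
              else sprintf("%.1f", object@convergenceTime)))
  cat(sprintf("  trapped lipids: %d loop side + %d NC side = %d\n",
              object@nLoop, object@nNC, object@nTotal))
})

setMethod("show", "RingRegion", function(object) {
  cat(sprintf("RingRegion: %d-gon, z midplane %.2f nm, half-extent %.2f nm\n",
              nrow(object@polygon), object@zMid, object@zExtent))
})
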