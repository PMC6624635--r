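#' Accessors for glandseg classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("densityMap", function(x, which = c("stromal", "epithelial"), ...)
  standardGeneric("densityMap"))

#' @rdname accessors
#' @export
setGeneric("referenceChromaticities", function(x, ...)
  standardGeneric("referenceChromaticities"))

#' @rdname accessors
#' @export
setGeneric("stainWeights", function(x, ...) standardGeneric("stainWeights"))

#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(x, ...) standardGeneric("mixingMatrix"))

#' @rdname accessors
#' @export
setGeneric("segLabels", function(x, ...) standardGeneric("segLabels"))

#' @rdname accessors
#' @export
setGeneric("seedMap", function(x, ...) standardGeneric("seedMap"))

#' @rdname accessors
#' @export
setGeneric("segMask", function(x, ...) standardGeneric("segMask"))

#' @rdname accessors
#' @export
setGeneric("rejectedObjects", function(x, ...) standardGeneric("rejectedObjects"))

#' @rdname accessors
#' @export
setGeneric("acceptedObjects", function(x, ...) standardGeneric("acceptedObjects"))

#' @rdname accessors
#' @export
setGeneric("instanceLabels", function(x, ...) standardGeneric("instanceLabels"))

#' @rdname accessors
#' @export
setGeneric("architectureTags", function(x, ...) standardGeneric("architectureTags"))

#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(x, ...) standardGeneric("nucleusMask"))

setMethod("densityMap", "DensityMaps", function(x, which = c("stromal", "epithelial"), ...) {
  which <- match.arg(which)
  slot(x, which)
})

setMethod("referenceChromaticities", "StainModel", function(x, ...) x@references)
setMethod("stainWeights", "StainModel", function(x, ...) x@weights)
setMethod("mixingMatrix", "StainModel", function(x, ...) x@mixingMatrix)
setMethod("segLabels", "GlandSegmentation", function(x, ...) x@labels)
setMethod("seedMap", "GlandSegmentation", function(x, ...) x@seeds)
setMethod("segMask", "GlandSegmentation", function(x, ...) x@mask)
setMethod("rejectedObjects", "GlandSegmentation", function(x, ...) x@rejected)
setMethod("acceptedObjects", "GlandSegmentation", function(x, ...) x@objects)
setMethod("instanceLabels", "GroundTruth", function(x, ...) x@instances)
setMethod("architectureTags", "GroundTruth", function(x, ...) x@architecture)
setMethod("nucleusMask", "GroundTruth", function(x, ...) x@nucleusMask)

setMethod("show", "RGBTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBTile: %d x %d px, %d-bit, background (%s)\n",
              d[1], d[2], object@bitDepth,
              paste(signif(object@background, 4), collapse = ", ")))
})

setMethod("show", "ChromaticityCloud", function(object) {
  cat(sprintf("ChromaticityCloud: %d points (of %d pixels, min total OD %.3g)\n",
              nrow(object@points), object@nPixels, object@minTotalOD))
})

setMethod("show", "StainModel", function(object) {
  cat(sprintf("StainModel: %d stains, EM %s in %d iterations (logLik %.4g)\n",
              object@nStains,
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@logLik))
  ref <- round(object@references, 4)
  rownames(ref) <- if (object@nStains == 2L) c("stromal", "epithelial")
                   else paste0("stain", seq_len(object@nStains))
  colnames(ref) <- c("R", "G", "B")
  print(cbind(ref, weight = round(object@weights, 4)))
})

setMethod("show", "DensityMaps", function(object) {
  cat(sprintf("DensityMaps: %d x %d, %s (odScale %s)\n",
              nrow(object@stromal), ncol(object@stromal),
              if (isTRUE(object@normalization$normalized)) "normalized to [0,1]"
              else "raw densities",
              format(object@normalization$odScale)))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf(paste0("ClusterReport: Mahalanobis %.4g, Calinski-Harabasz %.4g, ",
                     "weights (%s), n = %d\n"),
              object@mahalanobis, object@calinskiHarabasz,
              paste(round(object@weights, 3), collapse = ", "), object@nPoints))
})

setMethod("show", "GlandSegmentation", function(object) {
  cat(sprintf("GlandSegmentation: %d accepted glands, %d rejected (%s)\n",
              nrow(object@objects), nrow(object@rejected),
              if (nrow(object@rejected))
                paste(names(table(object@rejected$reason)),
                      table(object@rejected$reason), collapse = ", ")
              else "none"))
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@architecture)
  cat(sprintf("GroundTruth: %d instances (%s)\n", length(object@architecture),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
})

setMethod("show", "SummaryTable", function(object) {
  cat(sprintf("SummaryTable: %d objects, accuracy %g%% (glands %g%%, non-glands %g%%)\n",
              object@total, object@accuracy, object@glandShare,
              object@nonGlandShare))
  print(object@table, row.names = FALSE)
})
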