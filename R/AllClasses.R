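#' @import methods
NULL

#' RGB brightfield tile
#'
#' Container for a raw 3-channel brightfield histology tile together with the
#' per-channel background (unstained, "white") intensity used by the
#' Beer-Lambert transform. Pixel values are stored as doubles on the camera
#' count scale (0..2^bitDepth - 1); they need not be integers, which lets the
#' synthetic forward model render noise-free tiles without quantization loss.
#'
#' @slot pixels H x W x 3 array of non-negative intensities.
#' @slot background length-3 numeric, strictly positive background intensity
#'   per channel (I0).
#' @slot bitDepth integer scalar, 8 or 16.
#' @export
setClass("RGBTile",
  representation(pixels = "array", background = "numeric", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (any(object@pixels < 0))
      return("pixel intensities must be non-negative")
    if (!object@bitDepth %in% c(8L, 16L))
      return("bitDepth must be 8 or 16")
    if (any(object@pixels > 2^object@bitDepth - 1))
      return("pixel intensities exceed the bit depth")
    if (length(object@background) != 3L || any(object@background <= 0))
      return("background intensity must be strictly positive in every channel")
    TRUE
  })

#' Chromaticity cloud in the Beer-Lambert triangle
#'
#' Barycentric coordinates of the tissue pixels that pass the background
#' (total optical density) filter. Distances in this triangle reflect
#' chromaticity differences independent of staining intensity.
#'
#' @slot points N x 3 matrix of barycentric coordinates (rows sum to 1).
#' @slot totalOD numeric length N, total optical density of each retained pixel.
#' @slot nPixels total number of pixels in the source image (including the
#'   excluded near-white background).
#' @slot minTotalOD the background-exclusion threshold applied.
#' @export
setClass("ChromaticityCloud",
  representation(points = "matrix", totalOD = "numeric",
                 nPixels = "integer", minTotalOD = "numeric"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 3L) return("points must have 3 columns")
    if (nrow(p) != length(object@totalOD))
      return("totalOD length must match the number of points")
    if (nrow(p) > 0) {
      if (any(p < -1e-9)) return("barycentric coordinates must be non-negative")
      if (any(abs(rowSums(p) - 1) > 1e-9))
        return("barycentric coordinates must sum to 1")
    }
    TRUE
  })

#' Fitted stain model
#'
#' Reference chromaticities, mixing matrix, and Gaussian-mixture parameters
#' estimated from a chromaticity cloud by expectation maximization. For the
#' two-stain PSR-Htx case, stain 1 is the stromal (Picrosirius red) component
#' and stain 2 the epithelial (hematoxylin) component.
#'
#' @slot nStains integer, number of stain components.
#' @slot references nStains x 3 matrix of barycentric reference chromaticities.
#' @slot covariances list of 2 x 2 component covariances in planar triangle
#'   coordinates.
#' @slot weights mixture weights, non-negative, summing to 1.
#' @slot mixingMatrix 3 x nStains matrix whose columns are unit-sum optical
#'   density direction vectors (the reference chromaticities).
#' @slot logLik final mixture log-likelihood.
#' @slot iterations EM iterations used.
#' @slot converged logical.
#' @slot seed integer seed used for the deterministic initialization.
#' @export
setClass("StainModel",
  representation(nStains = "integer", references = "matrix",
                 covariances = "list", weights = "numeric",
                 mixingMatrix = "matrix", logLik = "numeric",
                 iterations = "integer", converged = "logical",
                 seed = "integer"),
  validity = function(object) {
    n <- object@nStains
    if (nrow(object@references) != n || ncol(object@references) != 3L)
      return("references must be nStains x 3")
    if (length(object@weights) != n || any(object@weights < -1e-9))
      return("weights must be non-negative, one per stain")
    if (abs(sum(object@weights) - 1) > 1e-9)
      return("weights must sum to 1")
    if (any(abs(rowSums(object@references) - 1) > 1e-6))
      return("reference chromaticities must be barycentric (rows sum to 1)")
    if (!all(dim(object@mixingMatrix) == c(3L, n)))
      return("mixingMatrix must be 3 x nStains")
    if (any(abs(colSums(object@mixingMatrix) - 1) > 1e-6))
      return("mixingMatrix columns must be unit-sum OD directions")
    TRUE
  })

#' Stromal and epithelial stain density maps
#'
#' The working representation of a decomposed tile: two aligned scalar maps,
#' one per stain/tissue type. When normalized (the default), both maps are
#' scaled by a fixed optical-density constant and clipped to [0, 1] so that
#' intensity thresholds (such as the 0.7 nucleus threshold) are comparable
#' across tiles.
#'
#' @slot stromal,epithelial H x W numeric matrices, non-negative.
#' @slot normalization list with elements \code{odScale} (the divisor applied;
#'   \code{NA} if the maps are raw densities) and \code{normalized} (logical).
#' @export
setClass("DensityMaps",
  representation(stromal = "matrix", epithelial = "matrix",
                 normalization = "list"),
  validity = function(object) {
    if (!all(dim(object@stromal) == dim(object@epithelial)))
      return("stromal and epithelial maps must have the same shape")
    if (any(object@stromal < 0) || any(object@epithelial < 0))
      return("density maps must be non-negative")
    TRUE
  })

#' Stain-quality cluster report
#'
#' Quantitative separability measures of the stain clusters in the
#' chromaticity triangle, as used to compare staining protocols.
#'
#' @slot mahalanobis Mahalanobis distance between the two cluster means under
#'   the weight-pooled covariance.
#' @slot calinskiHarabasz Calinski-Harabasz index of the hard-assigned cloud
#'   (\code{Inf} flags zero within-cluster scatter).
#' @slot weights normalized amount of color per cluster (EM mixture weights).
#' @slot nPoints number of points scored.
#' @export
setClass("ClusterReport",
  representation(mahalanobis = "numeric", calinskiHarabasz = "numeric",
                 weights = "numeric", nPoints = "integer"),
  validity = function(object) {
    if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
    if (object@mahalanobis < 0) return("mahalanobis must be non-negative")
    TRUE
  })

#' Gland segmentation result
#'
#' Final labeled gland objects together with the intermediate products needed
#' for inspection: the gland-candidate mask, the seed map, and the per-object
#' accept/reject provenance.
#'
#' @slot labels H x W integer instance map of accepted glands (0 = background).
#' @slot allLabels instance map before object filtering.
#' @slot seeds H x W integer seed map.
#' @slot mask H x W logical gland-candidate mask (TRUE = non-stromal).
#' @slot rejected data.frame with columns \code{id}, \code{reason}
#'   (\code{"too_small"} or \code{"no_nucleus"}) and \code{area}.
#' @slot objects data.frame of accepted objects (id, area, centroid).
#' @slot config the segmentation configuration used.
#' @export
setClass("GlandSegmentation",
  representation(labels = "matrix", allLabels = "matrix", seeds = "matrix",
                 mask = "matrix", rejected = "data.frame",
                 objects = "data.frame", config = "list"),
  validity = function(object) {
    if (!all(dim(object@labels) == dim(object@mask)))
      return("labels and mask must have the same shape")
    if (any(object@labels[!object@mask] != 0))
      return("labeled pixels must lie inside the mask")
    if (any(object@rejected$id %in% object@labels))
      return("rejected region ids must be absent from the final labels")
    TRUE
  })

#' Synthetic ground truth
#'
#' Per-pixel gland instance labels, per-instance architecture tags, and the
#' nucleus mask for a generated tile.
#'
#' @slot instances H x W integer instance map (0 = stroma/background).
#' @slot architecture named character vector mapping instance id to its
#'   architecture tag (e.g. \code{"well_formed"}, \code{"cribriform"},
#'   \code{"nucleus_free_trap"}).
#' @slot nucleusMask H x W logical.
#' @export
setClass("GroundTruth",
  representation(instances = "matrix", architecture = "character",
                 nucleusMask = "matrix"),
  validity = function(object) {
    ids <- setdiff(unique(as.integer(object@instances)), 0L)
    if (!all(as.character(ids) %in% names(object@architecture)))
      return("every instance id must have an architecture tag")
    if (!all(dim(object@instances) == dim(object@nucleusMask)))
      return("instances and nucleusMask must have the same shape")
    TRUE
  })

#' Object-level categorization of a segmentation
#'
#' Matches predicted objects against ground-truth objects and assigns each
#' prediction exactly one category (gland correct, non-gland correct,
#' over-segmented, under-segmented) and each truth object one status
#' (found or missed).
#'
#' @slot predicted data.frame: id, category, bestTruth, intersection, iou,
#'   coverage.
#' @slot truth data.frame: id, architecture, status.
#' @slot thresholds list echoing iouMatch, coverageLow, coverageHigh.
#' @export
setClass("ObjectCategorization",
  representation(predicted = "data.frame", truth = "data.frame",
                 thresholds = "list"))

#' Segmentation summary table
#'
#' Category counts and percentages plus the headline accuracy (share of
#' objects neither over- nor under-segmented) and the gland / non-gland split
#' among the accurately segmented objects.
#'
#' @slot table data.frame with columns category, count, percent.
#' @slot total total object count.
#' @slot accuracy headline accuracy in percent, rounded to the integer.
#' @slot glandShare,nonGlandShare percent of accurate objects that are glands /
#'   non-glandular, rounded to the integer.
#' @export
setClass("SummaryTable",
  representation(table = "data.frame", total = "numeric", accuracy = "numeric",
                 glandShare = "numeric", nonGlandShare = "numeric"),
  validity = function(object) {
    if (!all(c("category", "count", "percent") %in% colnames(object@table)))
      return("table must have category, count, percent columns")
    if (abs(sum(object@table$count) - object@total) > 1e-9)
      return("counts must sum to the total")
    TRUE
  })
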