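# Object-level scoring of a segmentation against ground truth, using the
# four-way taxonomy: correctly segmented glands, correctly segmented
# non-glandular objects, over-segmentation (more than one true object merged
# into a prediction), under-segmentation (only part of a true object found).

.glandArchitectures <- c("benign", "well_formed", "poorly_formed",
                         "cribriform", "fused", "single_cells")

#' Categorize predicted objects against ground truth
#'
#' Each predicted object receives exactly one category:
#' \itemize{
#'   \item over_segmented - it spans >= 2 truth objects, each covering at
#'     least `coverageLow` of the prediction, or it includes more than
#'     `1/coverageHigh` times its best-matching truth object's area;
#'   \item gland_correct / non_gland_correct - IoU with its best truth object
#'     >= `iouMatch` and it covers at least `coverageHigh` of that object
#'     (the label follows the truth object's architecture tag);
#'   \item under_segmented - otherwise (only part of a truth object found).
#' }
#' Predictions overlapping no truth object are non-glandular objects and are
#' counted non_gland_correct. Truth objects matched by a correct prediction
#' are `found`, the rest `missed`. The published categorization was done
#' visually by an expert; these numeric thresholds are the automated proxy.
#'
#' @param predicted integer label map (e.g. [segLabels()] of a
#'   [GlandSegmentation-class]).
#' @param truth a [GroundTruth-class] or integer truth label map.
#' @param iouMatch IoU required for a correct match.
#' @param coverageLow minimum fraction of the prediction a truth object must
#'   occupy to count toward over-segmentation.
#' @param coverageHigh fraction of the truth object a correct prediction must
#'   cover.
#' @return an [ObjectCategorization-class].
#' @export
categorizeObjects <- function(predicted, truth, iouMatch = 0.5,
                              coverageLow = 0.2, coverageHigh = 0.7) {
  if (!(coverageLow > 0 && coverageLow < coverageHigh && coverageHigh <= 1))
    invalidConfig("need 0 < coverageLow < coverageHigh <= 1")
  truthMap <- if (is(truth, "GroundTruth")) truth@instances else truth
  arch <- if (is(truth, "GroundTruth")) truth@architecture else NULL
  if (!all(dim(predicted) == dim(truthMap)))
    invalidInput("predicted and truth maps must have the same shape")
  p <- as.integer(predicted); t <- as.integer(truthMap)
  pIds <- setdiff(sort(unique(p)), 0L)
  tIds <- setdiff(sort(unique(t)), 0L)
  pArea <- stats::setNames(tabulate(p)[pIds], pIds)
  tArea <- stats::setNames(tabulate(t)[tIds], tIds)
  both <- p > 0L & t > 0L
  inter <- if (any(both)) {
    as.data.frame(table(pred = p[both], truth = t[both]),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(pred = character(0), truth = character(0), Freq = integer(0))
  }
  inter <- inter[inter$Freq > 0, , drop = FALSE]

  isGland <- function(id) {
    if (is.null(arch)) TRUE
    else arch[[as.character(id)]] %in% .glandArchitectures
  }
  category <- character(length(pIds))
  bestTruth <- rep(NA_integer_, length(pIds))
  bestIoU <- rep(0, length(pIds))
  bestCov <- rep(0, length(pIds))
  matchedTruth <- integer(0)
  for (i in seq_along(pIds)) {
    id <- pIds[i]
    ov <- inter[inter$pred == as.character(id), , drop = FALSE]
    if (nrow(ov) == 0) {
      category[i] <- "non_gland_correct"
      next
    }
    tids <- as.integer(ov$truth)
    b <- which.max(ov$Freq)
    bt <- tids[b]
    ia <- ov$Freq[b]
    bestTruth[i] <- bt
    bestIoU[i] <- ia / (pArea[[as.character(id)]] + tArea[[as.character(bt)]] - ia)
    bestCov[i] <- ia / tArea[[as.character(bt)]]
    spanning <- sum(ov$Freq >= coverageLow * pArea[[as.character(id)]])
    if (spanning >= 2) {
      category[i] <- "over_segmented"
    } else if (bestIoU[i] >= iouMatch && bestCov[i] >= coverageHigh) {
      category[i] <- if (isGland(bt)) "gland_correct" else "non_gland_correct"
      matchedTruth <- c(matchedTruth, bt)
    } else if (pArea[[as.character(id)]] > tArea[[as.character(bt)]] / coverageHigh) {
      category[i] <- "over_segmented"
    } else {
      category[i] <- "under_segmented"
    }
  }
  predictedDf <- data.frame(id = pIds, category = category,
                            bestTruth = bestTruth, iou = bestIoU,
                            coverage = bestCov)
  truthDf <- data.frame(
    id = tIds,
    architecture = if (is.null(arch)) NA_character_
                   else unname(arch[as.character(tIds)]),
    status = ifelse(tIds %in% matchedTruth, "found", "missed"))
  new("ObjectCategorization", predicted = predictedDf, truth = truthDf,
      thresholds = list(iouMatch = iouMatch, coverageLow = coverageLow,
                        coverageHigh = coverageHigh))
}

#' Summarize category counts into the standard results table
#'
#' Computes, for each category, its percentage of the total (two decimals),
#' the headline accuracy - the percent of objects neither over- nor
#' under-segmented, rounded to the integer - and the gland / non-gland split
#' among those accurately segmented objects.
#'
#' Input is either an [ObjectCategorization-class] or a data.frame with
#' columns `category` (free-form label), `count`, and `class`, where `class`
#' is one of `"gland"`, `"non_gland"`, `"over"`, `"under"` and says how the
#' row enters the headline arithmetic. Percentages use dot decimals.
#'
#' @param x categorization or counts data.frame.
#' @return a [SummaryTable-class].
#' @examples
#' counts <- data.frame(
#'   category = c("Glands", "Over-segmentation", "Under-segmentation",
#'                "Non-glandular objects"),
#'   count = c(7769, 397, 494, 2787),
#'   class = c("gland", "over", "under", "non_gland"))
#' summarizeCategories(counts)
#' @export
summarizeCategories <- function(x) {
  if (is(x, "ObjectCategorization")) {
    cat4 <- factor(x@predicted$category,
                   levels = c("gland_correct", "non_gland_correct",
                              "over_segmented", "under_segmented"))
    counts <- as.integer(table(cat4))
    x <- data.frame(
      category = levels(cat4), count = counts,
      class = c("gland", "non_gland", "over", "under"))
  }
  if (!all(c("category", "count", "class") %in% colnames(x)))
    invalidInput("need columns category, count, class")
  if (!all(x$class %in% c("gland", "non_gland", "over", "under")))
    invalidInput("class must be gland, non_gland, over or under")
  total <- sum(x$count)
  if (total <= 0) degenerateInput("zero objects to summarize")
  over <- sum(x$count[x$class == "over"])
  under <- sum(x$count[x$class == "under"])
  glands <- sum(x$count[x$class == "gland"])
  nong <- sum(x$count[x$class == "non_gland"])
  accurate <- total - over - under
  tab <- data.frame(category = x$category, count = x$count,
                    percent = round(100 * x$count / total, 2))
  new("SummaryTable", table = tab, total = total,
      accuracy = round(100 * accurate / total),
      glandShare = if (accurate > 0) round(100 * glands / accurate) else NA_real_,
      nonGlandShare = if (accurate > 0) round(100 * nong / accurate) else NA_real_)
}
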