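makeTruth <- function(instances, arch) {
  new("GroundTruth", instances = instances,
      architecture = arch,
      nucleusMask = matrix(FALSE, nrow(instances), ncol(instances)))
}

test_that("exact predictions are all correct, partial ones categorized", {
  H <- 40; W <- 80
  truthMap <- matrix(0L, H, W)
  truthMap[diskMat(H, W, c(20, 20), 10)] <- 1L
  truthMap[diskMat(H, W, c(20, 60), 10)] <- 2L
  truth <- makeTruth(truthMap, c("1" = "well_formed", "2" = "benign"))
  # predicted == truth
  cats <- categorizeObjects(truthMap, truth)
  expect_true(all(cats@predicted$category == "gland_correct"))
  expect_true(all(cats@truth$status == "found"))
  # one prediction = union of the two glands -> over-segmented
  merged <- ifelse(truthMap > 0L, 1L, 0L)
  catsM <- categorizeObjects(merged, truth)
  expect_equal(catsM@predicted$category, "over_segmented")
  expect_true(all(catsM@truth$status == "missed"))
  # left half of one gland -> under-segmented (coverage 0.5 < 0.7)
  half <- truthMap
  half[half == 2L] <- 0L
  half[, 21:40] <- 0L
  catsH <- categorizeObjects(half, truth)
  expect_equal(catsH@predicted$category, "under_segmented")
  cov <- catsH@predicted$coverage
  expect_equal(cov, sum(half > 0) / sum(truthMap == 1L), tolerance = 1e-12)
  expect_lt(cov, 0.7)
})

test_that("oversized and unmatched predictions get the right categories", {
  H <- 60; W <- 60
  truthMap <- matrix(0L, H, W)
  truthMap[diskMat(H, W, c(30, 30), 8)] <- 1L
  truth <- makeTruth(truthMap, c("1" = "well_formed"))
  # prediction including far more than the truth object
  big <- matrix(0L, H, W)
  big[diskMat(H, W, c(30, 30), 16)] <- 1L
  expect_equal(categorizeObjects(big, truth)@predicted$category,
               "over_segmented")
  # prediction overlapping nothing: a correctly segmented non-glandular object
  off <- matrix(0L, H, W)
  off[diskMat(H, W, c(10, 50), 5)] <- 1L
  expect_equal(categorizeObjects(off, truth)@predicted$category,
               "non_gland_correct")
  # non-gland truth tags propagate to matched predictions
  trap <- makeTruth(truthMap, c("1" = "nucleus_free_trap"))
  expect_equal(categorizeObjects(truthMap, trap)@predicted$category,
               "non_gland_correct")
})

test_that("categorization is exhaustive, exclusive, and label-invariant", {
  set.seed(6)
  H <- 48; W <- 48
  truthMap <- matrix(0L, H, W)
  truthMap[diskMat(H, W, c(14, 14), 8)] <- 1L
  truthMap[diskMat(H, W, c(34, 32), 9)] <- 2L
  truth <- makeTruth(truthMap, c("1" = "well_formed", "2" = "cribriform"))
  pred <- matrix(0L, H, W)
  pred[diskMat(H, W, c(15, 15), 7)] <- 3L
  pred[diskMat(H, W, c(33, 31), 12)] <- 1L
  pred[diskMat(H, W, c(44, 10), 3)] <- 2L
  cats <- categorizeObjects(pred, truth)
  expect_equal(nrow(cats@predicted), 3L)
  expect_true(all(cats@predicted$category %in%
    c("gland_correct", "non_gland_correct", "over_segmented", "under_segmented")))
  expect_true(all(cats@truth$status %in% c("found", "missed")))
  # permuting predicted ids changes nothing but the ids
  perm <- pred
  perm[pred == 1L] <- 5L; perm[pred == 2L] <- 9L; perm[pred == 3L] <- 4L
  catsP <- categorizeObjects(perm, truth)
  o1 <- cats@predicted[order(cats@predicted$bestTruth, cats@predicted$iou), ]
  o2 <- catsP@predicted[order(catsP@predicted$bestTruth, catsP@predicted$iou), ]
  expect_equal(o1$category, o2$category)
  expect_equal(o1$iou, o2$iou)
  expect_error(categorizeObjects(pred[1:10, ], truth),
               class = "glandseg_invalid_input")
  expect_error(categorizeObjects(pred, truth, coverageLow = 0.8),
               class = "glandseg_invalid_config")
})

test_that("summaries reproduce the headline arithmetic", {
  counts <- data.frame(
    category = c("Glands", "Over", "Under", "Non-glandular"),
    count = c(7769, 397, 494, 2787),
    class = c("gland", "over", "under", "non_gland"))
  s <- summarizeCategories(counts)
  expect_equal(s@total, 11447)
  expect_equal(s@accuracy, 92)
  expect_equal(s@glandShare, 74)
  expect_equal(s@nonGlandShare, 26)
  # all-gland trivial case
  s2 <- summarizeCategories(data.frame(category = "g", count = 10,
                                       class = "gland"))
  expect_equal(s2@accuracy, 100)
  expect_equal(s2@glandShare, 100)
  # percent formatting to two decimals
  s3 <- summarizeCategories(data.frame(
    category = c("Benign glands", "rest"), count = c(1198, 11447 - 1198),
    class = c("gland", "gland")))
  expect_equal(s3@table$percent[1], 10.47)
  expect_error(summarizeCategories(data.frame(category = "x", count = 0,
                                              class = "gland")),
               class = "glandseg_degenerate_input")
})

test_that("summary percentages are scale invariant", {
  base <- data.frame(category = c("a", "b", "c"),
                     count = c(50, 30, 20),
                     class = c("gland", "non_gland", "under"))
  s1 <- summarizeCategories(base)
  base$count <- base$count * 7
  s2 <- summarizeCategories(base)
  expect_equal(s1@table$percent, s2@table$percent)
  expect_equal(s1@accuracy, s2@accuracy)
  expect_equal(s1@glandShare, s2@glandShare)
})

test_that("summaries are computed from categorizations too", {
  H <- 40; W <- 40
  truthMap <- matrix(0L, H, W)
  truthMap[diskMat(H, W, c(20, 20), 10)] <- 1L
  truth <- makeTruth(truthMap, c("1" = "well_formed"))
  s <- summarizeCategories(categorizeObjects(truthMap, truth))
  expect_equal(s@total, 1)
  expect_equal(s@accuracy, 100)
  expect_equal(sum(s@table$count), 1)
})
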