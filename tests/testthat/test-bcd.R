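test_that("optical density follows the Beer-Lambert definition", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)          # no absorption
  px[1, 2, ] <- 255 * exp(-1)             # one OD unit in every channel
  px[1, 3, ] <- c(128, 128, 128)
  tile <- RGBTile(px, background = c(255, 255, 255))
  od <- rgbToOD(tile)
  expect_equal(od[1, 1, ], c(0, 0, 0))
  expect_equal(od[1, 2, ], c(1, 1, 1), tolerance = 1e-12)
  expect_equal(od[1, 3, ], rep(log(255 / 128), 3), tolerance = 1e-12)
  expect_equal(dim(od), dim(px))
  # zero intensities are clipped to one count before the ratio
  px0 <- array(0, dim = c(1, 1, 3))
  t0 <- RGBTile(px0, background = c(255, 255, 255))
  expect_equal(rgbToOD(t0)[1, 1, ], rep(log(255), 3))
  expect_error(RGBTile(px, background = c(0, 255, 255)),
               class = "glandseg_invalid_input")
})

test_that("chromaticity mapping normalizes OD vectors and excludes background", {
  od <- array(0, dim = c(2, 2, 3))
  od[1, 1, ] <- c(1, 1, 1)
  od[1, 2, ] <- c(2, 0, 0)
  od[2, 1, ] <- c(1, 1, 0)
  od[2, 2, ] <- c(0.01, 0.01, 0.01)  # near-white, below the default threshold
  cloud <- odToChromaticity(od, minTotalOD = 0.10)
  expect_equal(nrow(cloud@points), 3L)
  expect_equal(cloud@nPixels, 4L)
  pts <- cloud@points[order(cloud@points[, 1]), ]
  expect_equal(pts[1, ], c(1, 1, 1) / 3, tolerance = 1e-12)
  expect_equal(pts[2, ], c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(pts[3, ], c(1, 0, 0), tolerance = 1e-12)
  expect_error(odToChromaticity(array(0, dim = c(2, 2, 3))),
               class = "glandseg_degenerate_input")
  expect_error(odToChromaticity(od, minTotalOD = -1),
               class = "glandseg_invalid_input")
})

test_that("chromaticity is invariant to intensity scaling", {
  set.seed(42)
  px <- array(runif(20 * 20 * 3, 40, 220), dim = c(20, 20, 3))
  I0 <- c(255, 250, 245)
  tile1 <- RGBTile(px, background = I0)
  for (k in c(0.5, 2)) {
    px2 <- array(0, dim = dim(px))
    for (ch in 1:3) px2[, , ch] <- I0[ch] * (px[, , ch] / I0[ch])^k
    tile2 <- RGBTile(px2, background = I0)
    od1 <- rgbToOD(tile1); od2 <- rgbToOD(tile2)
    expect_equal(od2, k * od1, tolerance = 1e-12)
    c1 <- odToChromaticity(od1, 0.05)
    c2 <- odToChromaticity(od2, 0.05 * k)
    expect_equal(c2@points, c1@points, tolerance = 1e-9)
  }
})

test_that("EM recovers a simulated two-component mixture", {
  m1 <- c(-0.15, 0.05); m2 <- c(0.15, -0.05)
  cloud <- twoGaussianCloud(5000, m1, m2, sigma = 0.02, seed = 11)
  model <- fitStainModel(cloud, seed = 3)
  mu <- toPlanar(referenceChromaticities(model))
  # label-permutation invariant comparison
  d1 <- sqrt(sum((mu[1, ] - m1)^2)) + sqrt(sum((mu[2, ] - m2)^2))
  d2 <- sqrt(sum((mu[1, ] - m2)^2)) + sqrt(sum((mu[2, ] - m1)^2))
  expect_lt(min(d1, d2) / 2, 0.01)
  expect_equal(unname(stainWeights(model)), c(0.5, 0.5), tolerance = 0.02)
  # deterministic given the seed, invariant to point shuffling
  again <- fitStainModel(cloud, seed = 3)
  expect_identical(referenceChromaticities(again), referenceChromaticities(model))
  set.seed(99)
  perm <- sample(nrow(cloud@points))
  shuffled <- new("ChromaticityCloud", points = cloud@points[perm, ],
                  totalOD = cloud@totalOD[perm], nPixels = cloud@nPixels,
                  minTotalOD = cloud@minTotalOD)
  ms <- fitStainModel(shuffled, seed = 3)
  expect_equal(referenceChromaticities(ms), referenceChromaticities(model),
               tolerance = 1e-3)
})

test_that("EM agrees with an independent mixture fit and flags degeneracies", {
  cloud <- twoGaussianCloud(3000, c(-0.12, 0), c(0.12, 0), sigma = 0.02,
                            w1 = 0.4, seed = 5)
  model <- fitStainModel(cloud, seed = 2)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this symbol unqualified
  mc <- mclust::Mclust(toPlanar(cloud@points), G = 2, modelNames = "VVV",
                       verbose = FALSE)
  muRef <- t(mc$parameters$mean)
  mu <- toPlanar(referenceChromaticities(model))
  err <- min(sqrt(sum((mu[1, ] - muRef[1, ])^2)) + sqrt(sum((mu[2, ] - muRef[2, ])^2)),
             sqrt(sum((mu[1, ] - muRef[2, ])^2)) + sqrt(sum((mu[2, ] - muRef[1, ])^2)))
  expect_lt(err / 2, 0.01)
  # identical points: zero-variance cloud is a degenerate stain
  same <- cloudFromPlanar(matrix(0.01, 100, 2))
  expect_error(fitStainModel(same, seed = 1), class = "glandseg_degenerate_stain")
  expect_error(fitStainModel(cloud, nStains = 1), class = "glandseg_invalid_input")
})

test_that("the stromal component is the redder reference", {
  cloud <- twoGaussianCloud(2000, c(-0.1, 0), c(0.1, 0), sigma = 0.015, seed = 8)
  model <- fitStainModel(cloud, seed = 1)
  refs <- referenceChromaticities(model)
  expect_gt(refs[1, 1], refs[2, 1])
})

test_that("unmixing solves the per-pixel NNLS problem", {
  sr <- c(0.60, 0.25, 0.15); er <- c(0.30, 0.30, 0.40)
  model <- modelFromPlanar(toPlanar(rbind(sr, er)),
                           list(diag(2) * 1e-4, diag(2) * 1e-4))
  # forward round trip: od = M (a, b) recovered exactly
  set.seed(21)
  ab <- cbind(runif(50, 0, 2), runif(50, 0, 2))
  od <- array(ab %*% rbind(sr, er), dim = c(1, 50, 3))
  maps <- unmixStains(od, model, normalize = FALSE)
  expect_equal(as.numeric(densityMap(maps, "stromal")), ab[, 1], tolerance = 1e-6)
  expect_equal(as.numeric(densityMap(maps, "epithelial")), ab[, 2], tolerance = 1e-6)
  # pure-stain pixel and zero OD
  od2 <- array(0, dim = c(1, 2, 3))
  od2[1, 1, ] <- 1.3 * sr
  maps2 <- unmixStains(od2, model, normalize = FALSE)
  expect_equal(densityMap(maps2, "stromal")[1, 1], 1.3, tolerance = 1e-9)
  expect_equal(densityMap(maps2, "epithelial")[1, 1], 0, tolerance = 1e-9)
  expect_equal(densityMap(maps2, "stromal")[1, 2], 0)
  # (near-)coincident references make the mixing matrix singular
  bad <- modelFromPlanar(rbind(c(0.1, 0.1), c(0.105, 0.105)),
                         list(diag(2), diag(2)))
  expect_error(unmixStains(od, bad), class = "glandseg_degenerate_stain")
})

test_that("unmixing matches a reference NNLS solver on general pixels", {
  sr <- c(0.60, 0.25, 0.15); er <- c(0.30, 0.30, 0.40)
  model <- modelFromPlanar(toPlanar(rbind(sr, er)),
                           list(diag(2) * 1e-4, diag(2) * 1e-4))
  M <- mixingMatrix(model)
  set.seed(33)
  # random OD vectors, including ones off the stain plane (negative LS parts)
  V <- matrix(runif(3 * 40, 0, 1.5), ncol = 3)
  od <- array(V, dim = c(1, 40, 3))
  maps <- unmixStains(od, model, normalize = FALSE)
  got <- cbind(as.numeric(densityMap(maps, "stromal")),
               as.numeric(densityMap(maps, "epithelial")))
  want <- t(apply(V, 1, function(v) pracma::lsqnonneg(M, v)$x))
  expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("decomposition recovers the generating references of synthetic tiles", {
  spec <- pureTileSpec(seed = 7L)
  g <- generateTile(spec)
  dec <- decomposeStains(g$tile, seed = 3L)
  refs <- referenceChromaticities(dec$model)
  expect_lt(sqrt(sum((refs[1, ] - spec$stromalReference)^2)), 0.02)
  expect_lt(sqrt(sum((refs[2, ] - spec$epithelialReference)^2)), 0.02)
  expect_true(all(densityMap(dec$maps, "stromal") >= 0))
  expect_equal(dim(densityMap(dec$maps, "stromal")), c(128L, 128L))
})

test_that("degenerate tiles raise the documented errors", {
  white <- RGBTile(array(255, dim = c(16, 16, 3)), background = c(255, 255, 255))
  expect_error(decomposeStains(white), class = "glandseg_degenerate_input")
  # stroma-only tile: one color cluster
  spec <- tissueSpec(c(64L, 64L), list(), ccdSigma = 0, stainIntensityCV = 0,
                     boundarySigma = 0, rngSeed = 2L)
  g <- generateTile(spec)
  expect_error(decomposeStains(g$tile, seed = 1L),
               class = "glandseg_degenerate_stain")
  cfg <- glandSegConfig(bcd = list(fallbackSingleStain = TRUE))
  dec <- decomposeStains(g$tile, seed = 1L, config = cfg)
  expect_equal(dec$model@nStains, 1L)
  expect_true(all(densityMap(dec$maps, "epithelial") == 0))
  expect_gt(mean(densityMap(dec$maps, "stromal")), 0.2)
})
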