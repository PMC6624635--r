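# Blind color decomposition: Beer-Lambert optical density, chromaticity
# triangle mapping, EM mixture fit of the stain clusters, linear unmixing.

#' Construct an RGB tile
#'
#' @param pixels H x W x 3 array of non-negative intensities on the camera
#'   count scale, or an H x W x 3 array in [0, 1] which is rescaled by
#'   `2^bitDepth - 1`.
#' @param background per-channel background (white) intensity I0. If `NULL`,
#'   estimated as the per-channel `backgroundQuantile` quantile of the pixel
#'   intensities - the unstained-background estimate.
#' @param bitDepth 8 or 16.
#' @param backgroundQuantile quantile for the I0 estimate.
#' @return an [RGBTile-class] object.
#' @export
RGBTile <- function(pixels, background = NULL, bitDepth = 8L,
                    backgroundQuantile = 0.99) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    invalidInput("pixels must be an H x W x 3 array")
  storage.mode(pixels) <- "double"
  if (max(pixels) <= 1) pixels <- pixels * (2^bitDepth - 1)
  if (is.null(background))
    background <- apply(pixels, 3, stats::quantile, probs = backgroundQuantile,
                        names = FALSE)
  if (any(background <= 0))
    invalidInput("background intensity must be strictly positive in every channel")
  new("RGBTile", pixels = pixels, background = as.numeric(background),
      bitDepth = as.integer(bitDepth))
}

#' Beer-Lambert optical density transform
#'
#' Converts transmitted intensities to optical densities,
#' `od = ln(I0 / max(I, 1))`, clipped below at zero. The one-count floor
#' bounds the OD of fully absorbing pixels; the clip removes the (physically
#' meaningless) negative ODs of pixels brighter than the background estimate.
#'
#' @param tile an [RGBTile-class].
#' @return H x W x 3 array of optical densities (natural-log scale).
#' @export
rgbToOD <- function(tile) {
  stopifnot(is(tile, "RGBTile"))
  od <- array(0, dim = dim(tile@pixels))
  for (ch in 1:3)
    od[, , ch] <- pmax(0, log(tile@background[ch] / pmax(tile@pixels[, , ch], 1)))
  od
}

#' Map optical densities to the Beer-Lambert chromaticity triangle
#'
#' Each pixel's OD vector is normalized to barycentric coordinates
#' `od / sum(od)`; distance in this triangle reflects chromaticity alone,
#' independent of staining intensity. Near-white background pixels whose total
#' OD falls below `minTotalOD` carry essentially no color information (their
#' chromaticity is noise-dominated) and are excluded from the cloud.
#'
#' @param od H x W x 3 OD array from [rgbToOD()].
#' @param minTotalOD background-exclusion threshold (>= 0).
#' @return a [ChromaticityCloud-class].
#' @export
odToChromaticity <- function(od, minTotalOD = 0.10) {
  if (minTotalOD < 0) invalidInput("minTotalOD must be >= 0")
  v <- matrix(od, ncol = 3)
  total <- rowSums(v)
  keep <- total > minTotalOD
  if (!any(keep))
    degenerateInput("no pixels above the background OD threshold (all-white tile?)")
  pts <- v[keep, , drop = FALSE] / total[keep]
  new("ChromaticityCloud", points = pts, totalOD = total[keep],
      nPixels = length(total), minTotalOD = minTotalOD)
}

# log-density of N(mu, S) in 2-D, closed form.
.logdnorm2 <- function(P, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (det <= 0) return(rep(-Inf, nrow(P)))
  i11 <- S[2, 2] / det; i22 <- S[1, 1] / det; i12 <- -S[1, 2] / det
  dx <- P[, 1] - mu[1]; dy <- P[, 2] - mu[2]
  q <- i11 * dx^2 + 2 * i12 * dx * dy + i22 * dy^2
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# k-means++ seeding in 2-D, deterministic given the current RNG state.
.kmeansppCenters <- function(P, k) {
  n <- nrow(P)
  centers <- matrix(NA_real_, k, 2)
  centers[1, ] <- P[sample.int(n, 1), ]
  d2 <- rowSums(sweep(P, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      centers[j, ] <- P[sample.int(n, 1), ]
    } else {
      centers[j, ] <- P[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(P, 2, centers[j, ])^2))
  }
  centers
}

#' Fit the stain mixture model by expectation maximization
#'
#' Fits an `nStains`-component Gaussian mixture (full covariances) to the
#' chromaticity cloud in planar triangle coordinates. Initialization is
#' k-means++ followed by a k-means refinement, all under the supplied seed, so
#' the fit is deterministic. Component means mapped back to barycentric
#' coordinates are the reference chromaticities; the mixing matrix columns are
#' those references read as unit-sum OD directions. For two stains the
#' components are ordered stromal first: the reference with the larger red
#' barycentric coordinate (Picrosirius red stains stroma), ties broken by the
#' larger mixture weight.
#'
#' @param cloud a [ChromaticityCloud-class] with at least `10 * nStains` points.
#' @param nStains number of stains (>= 2).
#' @param seed integer seed for the deterministic initialization.
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @param ridge diagonal regularization added to component covariances.
#' @param maxPoints deterministic subsample cap (EM cost is linear in points;
#'   beyond this size the fit no longer changes meaningfully).
#' @param minSeparation minimum planar distance between component means; two
#'   chromaticities closer than this are not distinguishable stains and the
#'   fit is reported as degenerate.
#' @return a [StainModel-class].
#' @export
fitStainModel <- function(cloud, nStains = 2L, seed = 1L, maxIter = 500L,
                          tol = 1e-8, ridge = 1e-6, maxPoints = 20000L,
                          minSeparation = 0.02) {
  stopifnot(is(cloud, "ChromaticityCloud"))
  nStains <- as.integer(nStains)
  if (nStains < 2L) invalidInput("nStains must be >= 2")
  P <- toPlanar(cloud@points)
  if (nrow(P) < 10L * nStains)
    invalidInput(sprintf("need at least %d cloud points", 10L * nStains))
  init <- withSeed(seed, {
    if (nrow(P) > maxPoints)
      P <- P[sample.int(nrow(P), maxPoints), , drop = FALSE]
    if (sum(apply(P, 2, stats::var)) < 1e-12)
      degenerateStain("chromaticity cloud has zero variance (identical points)")
    centers <- .kmeansppCenters(P, nStains)
    km <- tryCatch(stats::kmeans(P, centers = centers, iter.max = 100L),
                   error = function(e) NULL)
    if (!is.null(km)) centers <- km$centers
    list(P = P, centers = centers)
  })
  P <- init$P
  centers <- init$centers
  n <- nrow(P)
  mu <- lapply(seq_len(nStains), function(j) centers[j, ])
  Sg <- rep(list(diag(2) * max(1e-4, sum(apply(P, 2, stats::var)) / nStains)),
            nStains)
  w <- rep(1 / nStains, nStains)

  ll <- -Inf; iter <- 0L; converged <- FALSE
  R <- matrix(0, n, nStains)
  while (iter < maxIter) {
    iter <- iter + 1L
    for (j in seq_len(nStains))
      R[, j] <- log(w[j]) + .logdnorm2(P, mu[[j]], Sg[[j]])
    m <- apply(R, 1, max)
    lse <- m + log(rowSums(exp(R - m)))
    llNew <- sum(lse)
    R <- exp(R - lse)
    nk <- colSums(R)
    if (any(nk < 1e-8))
      degenerateStain("a mixture component lost all its support")
    w <- nk / n
    for (j in seq_len(nStains)) {
      mu[[j]] <- colSums(R[, j] * P) / nk[j]
      dx <- sweep(P, 2, mu[[j]])
      S <- crossprod(dx * sqrt(R[, j])) / nk[j]
      Sg[[j]] <- S + diag(2) * ridge
    }
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew; converged <- TRUE; break
    }
    ll <- llNew
  }
  if (!converged)
    convergenceError(sprintf("EM did not converge within %d iterations", iter),
                     iterations = iter)
  mus <- do.call(rbind, mu)
  dmin <- min(stats::dist(mus))
  if (dmin < minSeparation)
    degenerateStain(sprintf(
      "mixture components collapsed (mean separation %.2g)", dmin))

  refs <- fromPlanar(mus)
  refs[refs < 0] <- 0
  refs <- refs / rowSums(refs)
  ord <- seq_len(nStains)
  if (nStains == 2L) {
    # stromal = redder reference; tie broken by larger weight
    if (abs(refs[1, 1] - refs[2, 1]) < 1e-12) {
      ord <- order(-w)
    } else {
      ord <- order(-refs[, 1])
    }
  }
  refs <- refs[ord, , drop = FALSE]
  new("StainModel", nStains = nStains, references = refs,
      covariances = Sg[ord], weights = w[ord] / sum(w),
      mixingMatrix = t(refs), logLik = ll, iterations = iter,
      converged = converged, seed = as.integer(seed))
}

#' Linear unmixing of optical densities into stain density maps
#'
#' Per-pixel non-negative least squares of the OD vector against the mixing
#' matrix columns. With two stains the NNLS solution has a closed form: if
#' the unconstrained solution is feasible it is optimal; otherwise the optimum
#' lies on a single-stain axis and the better of the two clamped projections
#' is taken. By default the maps are normalized by `odScale` and clipped to
#' [0, 1] so downstream intensity thresholds are comparable across tiles.
#'
#' @param od H x W x 3 OD array.
#' @param model a fitted [StainModel-class] with exactly 2 stains.
#' @param normalize scale maps to [0, 1]?
#' @param odScale normalization divisor (optical density units).
#' @return a [DensityMaps-class]; stain 1 (stromal) and stain 2 (epithelial).
#' @export
unmixStains <- function(od, model, normalize = TRUE, odScale = 2.5) {
  stopifnot(is(model, "StainModel"))
  if (model@nStains != 2L)
    invalidInput("unmixStains requires a 2-stain model")
  d <- dim(od)
  V <- matrix(od, ncol = 3)
  M <- model@mixingMatrix
  m1 <- M[, 1]; m2 <- M[, 2]
  # unit-sum OD directions are collinear iff the chromaticities coincide
  if (sqrt(sum((m1 - m2)^2)) < 0.02)
    degenerateStain("mixing matrix is singular (collinear stain references)")
  G <- crossprod(M)
  A <- V %*% M %*% solve(G)   # unconstrained least squares, N x 2
  bad <- A[, 1] < 0 | A[, 2] < 0
  if (any(bad)) {
    Vb <- V[bad, , drop = FALSE]
    a1 <- pmax(0, (Vb %*% m1) / sum(m1^2))
    a2 <- pmax(0, (Vb %*% m2) / sum(m2^2))
    # larger explained norm = smaller residual
    use1 <- a1^2 * sum(m1^2) >= a2^2 * sum(m2^2)
    A[bad, 1] <- ifelse(use1, a1, 0)
    A[bad, 2] <- ifelse(use1, 0, a2)
  }
  stromal <- matrix(A[, 1], d[1], d[2])
  epithelial <- matrix(A[, 2], d[1], d[2])
  if (normalize) {
    stromal <- pmin(pmax(stromal / odScale, 0), 1)
    epithelial <- pmin(pmax(epithelial / odScale, 0), 1)
    norm <- list(odScale = odScale, normalized = TRUE)
  } else {
    norm <- list(odScale = NA_real_, normalized = FALSE)
  }
  new("DensityMaps", stromal = stromal, epithelial = epithelial,
      normalization = norm)
}

#' Blind color decomposition of a tile
#'
#' Full decomposition: Beer-Lambert OD transform, chromaticity-triangle
#' mapping with background exclusion, EM stain-model fit, and non-negative
#' unmixing into normalized stromal and epithelial density maps.
#'
#' @param tile an [RGBTile-class].
#' @param seed integer seed (EM initialization).
#' @param config a [glandSegConfig()] list.
#' @return list with elements `maps` ([DensityMaps-class]), `model`
#'   ([StainModel-class]) and `cloud` ([ChromaticityCloud-class]).
#' @export
decomposeStains <- function(tile, seed = 1L, config = glandSegConfig()) {
  bc <- config$bcd
  od <- rgbToOD(tile)
  cloud <- odToChromaticity(od, minTotalOD = bc$minTotalOD)
  model <- tryCatch(
    fitStainModel(cloud, nStains = bc$nStains, seed = seed,
                  maxIter = bc$emMaxIter, tol = bc$emTol,
                  ridge = bc$emRidge, maxPoints = bc$emMaxPoints),
    glandseg_degenerate_stain = function(e) {
      if (!isTRUE(bc$fallbackSingleStain)) stop(e)
      .singleStainModel(cloud, seed)
    })
  if (model@nStains == 1L) {
    maps <- .unmixSingle(od, model, odScale = bc$odScale)
  } else {
    maps <- unmixStains(od, model, normalize = TRUE, odScale = bc$odScale)
  }
  list(maps = maps, model = model, cloud = cloud)
}

# Single-component fallback for tiles carrying only one stain: the reference
# is the OD-weighted mean chromaticity; the map is assigned stromal or
# epithelial by its red coordinate.
.singleStainModel <- function(cloud, seed) {
  ref <- colSums(cloud@points * cloud@totalOD) / sum(cloud@totalOD)
  ref <- ref / sum(ref)
  new("StainModel", nStains = 1L, references = rbind(ref),
      covariances = list(diag(2) * 1e-6), weights = 1,
      mixingMatrix = cbind(ref), logLik = NA_real_, iterations = 0L,
      converged = TRUE, seed = as.integer(seed))
}

.unmixSingle <- function(od, model, odScale) {
  d <- dim(od)
  m <- model@mixingMatrix[, 1]
  a <- pmax(0, (matrix(od, ncol = 3) %*% m) / sum(m^2))
  dens <- pmin(matrix(a, d[1], d[2]) / odScale, 1)
  zero <- matrix(0, d[1], d[2])
  stromal <- if (model@references[1, 1] >= 1 / 3) dens else zero
  epithelial <- if (model@references[1, 1] >= 1 / 3) zero else dens
  new("DensityMaps", stromal = stromal, epithelial = epithelial,
      normalization = list(odScale = odScale, normalized = TRUE))
}
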