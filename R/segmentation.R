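# Gland segmentation: opening, gradient-maximization thresholding, adaptive
# elliptical erosion for seed extraction, marker-controlled watershed, and
# nucleus-presence filtering of the resulting objects.

#' Grayscale morphological opening with a flat rectangular kernel
#'
#' Erosion followed by dilation with the reflected structuring element, so the
#' result is a true opening (idempotent, anti-extensive) also for even kernel
#' sizes such as the default 6 x 6.
#'
#' @param map numeric matrix.
#' @param kernel integer pair (rows, cols).
#' @return opened matrix.
#' @export
morphOpen <- function(map, kernel = c(6L, 6L)) {
  .checkMatrix(map)
  kernel <- as.integer(kernel)
  if (length(kernel) != 2L || any(kernel < 1L))
    invalidConfig("kernel must be two positive sizes")
  if (any(kernel > dim(map)))
    invalidConfig("opening kernel larger than the image")
  off <- .rectOffsets(kernel[1], kernel[2])
  cpp_flat_dilate(cpp_flat_erode(map, off), .reflectOffsets(off))
}

#' Smooth the stromal density map
#'
#' Morphological opening with the configured rectangular kernel; smooths the
#' gland boundaries and removes stromal specks thinner than the kernel before
#' mask construction. The kernel size is the compromise between separating
#' distinct glands (large kernel) and grouping them (small kernel); 6 x 6 px
#' is the default.
#'
#' @param stromal stromal density map in [0, 1].
#' @param config a [glandSegConfig()] list (its `segmentation` part is used).
#' @return smoothed map, same shape.
#' @export
smoothStroma <- function(stromal, config = glandSegConfig()) {
  sc <- .checkSegConfig(config$segmentation)
  .checkMatrix(stromal, "stromal")
  if (any(stromal < 0) || any(stromal > 1))
    invalidInput("stromal map must lie in [0, 1]")
  morphOpen(stromal, sc$openingKernel)
}

#' Gradient-maximization thresholding
#'
#' Selects, among `nLevels` uniformly spaced candidate thresholds on the map's
#' range, the one maximizing the mean Sobel gradient magnitude over the
#' boundary pixels of the thresholded image (pixels 8-adjacent to the opposite
#' class). This places the threshold where the image content changes fastest,
#' using local structure rather than the global histogram alone. Ties are
#' broken toward the lower threshold.
#'
#' @param map non-constant numeric matrix.
#' @param polarity which side of the threshold is the foreground of the
#'   returned mask: `"below"` (default; gland candidates are low-stromal
#'   pixels) or `"above"`.
#' @param nLevels number of candidate levels (256 emulates 8-bit gray levels).
#' @return logical mask with attributes `threshold` (selected level) and
#'   `polarity`.
#' @export
gradientThreshold <- function(map, polarity = c("below", "above"),
                              nLevels = 256L) {
  polarity <- match.arg(polarity)
  .checkMatrix(map)
  if (diff(range(map)) == 0)
    degenerateInput("cannot threshold a constant map")
  grad <- sobelGradient(map)$magnitude
  res <- cpp_gradient_threshold(map, grad, as.integer(nLevels))
  mask <- if (polarity == "below") map <= res$threshold else map > res$threshold
  attr(mask, "threshold") <- res$threshold
  attr(mask, "polarity") <- polarity
  mask
}

#' Local structure tensor and adaptive elliptical structuring element
#'
#' The structure tensor (Gaussian-smoothed outer product of the Sobel
#' gradients) encodes local orientation and anisotropy. Its eigenvector for
#' the smaller eigenvalue points along the direction of least gray-value
#' variation (along edges/lines); the anisotropy `(l1 - l2)/(l1 + l2)`
#' interpolates the structuring element between a disk (isotropic tissue) and
#' a line-like ellipse aligned with that direction. The full axis is bounded
#' by `erosionMaxAxis`; flat regions (zero tensor) yield the maximal disk.
#'
#' @param map numeric matrix.
#' @param position optional `c(row, col)`; if given, the ellipse parameters at
#'   that pixel are returned, otherwise the whole parameter fields.
#' @param config a [glandSegConfig()] list (`tensorSigma`, `erosionMaxAxis`).
#' @return for a position: list with `orientation` (radians, major axis),
#'   `semiMajor`, `semiMinor` (px) and `anisotropy`; otherwise a list of the
#'   corresponding matrices `theta`, `a`, `b`, `anisotropy`.
#' @export
localStructureTensorSE <- function(map, position = NULL,
                                   config = glandSegConfig()) {
  sc <- .checkSegConfig(config$segmentation)
  .checkMatrix(map)
  g <- sobelGradient(map)
  sig <- sc$tensorSigma
  jxx <- as.matrix(EBImage::gblur(g$gx^2, sigma = sig))
  jxy <- as.matrix(EBImage::gblur(g$gx * g$gy, sigma = sig))
  jyy <- as.matrix(EBImage::gblur(g$gy^2, sigma = sig))
  tr <- jxx + jyy
  disc <- sqrt(pmax(0, (jxx - jyy)^2 + 4 * jxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  flat <- tr < 1e-12
  A <- ifelse(flat, 0, (l1 - l2) / pmax(tr, 1e-300))
  # eigenvector of the smaller eigenvalue: (jxy, l2 - jxx); on the diagonal
  # the axes themselves are the eigenvectors
  offdiag <- abs(jxy) > 1e-14
  vx <- ifelse(offdiag, jxy, as.numeric(jxx <= jyy))
  vy <- ifelse(offdiag, l2 - jxx, as.numeric(jxx > jyy))
  theta <- atan2(vy, vx)
  semiMajor <- sc$erosionMaxAxis / 2
  a <- matrix(semiMajor, nrow(map), ncol(map))
  b <- matrix(pmax(semiMajor * (1 - A), 1), nrow(map), ncol(map))
  b[flat] <- semiMajor
  theta[flat] <- 0
  if (!is.null(position)) {
    r <- position[1]; c <- position[2]
    return(list(orientation = theta[r, c], semiMajor = a[r, c],
                semiMinor = b[r, c], anisotropy = A[r, c]))
  }
  list(theta = theta, a = a, b = b, anisotropy = A)
}

#' Extract one seed per gland by adaptive erosion
#'
#' Erodes the gland-candidate foreground (the inverted stromal map) with
#' per-pixel elliptical structuring elements derived from the local structure
#' tensor, then binarizes the eroded map by gradient-maximization
#' thresholding. The erosion severs thin bridges between weakly connected
#' glands while the adaptive ellipse - elongated along linear structures,
#' disk-like elsewhere - avoids erasing small glands. Connected components of
#' the binarized image inside the mask become the seeds.
#'
#' @param stromal (smoothed) stromal density map in [0, 1].
#' @param mask logical gland-candidate mask from [gradientThreshold()].
#' @param config a [glandSegConfig()] list.
#' @return integer seed map (0 = background, 1..K = seed identity).
#' @export
extractSeeds <- function(stromal, mask, config = glandSegConfig()) {
  sc <- .checkSegConfig(config$segmentation)
  .checkMatrix(stromal, "stromal")
  if (!all(dim(mask) == dim(stromal)))
    invalidInput("mask and stromal map must have the same shape")
  fg <- 1 - stromal
  se <- localStructureTensorSE(fg, config = config)
  eroded <- cpp_adaptive_erode(fg, se$theta, se$a, se$b)
  seedBin <- if (diff(range(eroded)) == 0) {
    matrix(FALSE, nrow(eroded), ncol(eroded))
  } else {
    gradientThreshold(eroded, polarity = "above")
  }
  seedBin <- seedBin & mask
  seeds <- cpp_label(matrix(as.integer(seedBin), nrow(seedBin)),
                     sc$connectivity)
  if (max(seeds) == 0L)
    warning("no seeds found", call. = FALSE)
  seeds
}

#' Marker-controlled watershed of the gland clusters
#'
#' Floods the Sobel gradient magnitude of the stromal map from the seeds,
#' restricted to the gland-candidate mask: region growing stops where the
#' stromal gradient ridges (the gland boundaries) are met or where the mask
#' ends. Flooding order is by gradient value, then by insertion order, so the
#' result is deterministic.
#'
#' @param stromal (smoothed) stromal density map.
#' @param seeds integer seed map; every seed must lie inside the mask.
#' @param mask logical gland-candidate mask.
#' @param connectivity 4 or 8.
#' @return integer label map; every region contains exactly its seed, pixels
#'   outside the mask are 0.
#' @export
watershedGlands <- function(stromal, seeds, mask, connectivity = 8L) {
  .checkMatrix(stromal, "stromal")
  if (!all(dim(seeds) == dim(stromal)) || !all(dim(mask) == dim(stromal)))
    invalidInput("seeds, mask and stromal map must share one shape")
  outside <- seeds > 0 & !mask
  if (any(outside)) {
    bad <- sort(unique(seeds[outside]))
    invalidSeed(sprintf("seed(s) %s lie outside the mask",
                        paste(bad, collapse = ", ")), seedId = bad)
  }
  surface <- sobelGradient(stromal)$magnitude
  cpp_watershed(surface, seeds, mask, as.integer(connectivity))
}

#' Filter segmented objects by size and nucleus presence
#'
#' Every gland contains at least one epithelial nucleus, so regions smaller
#' than the mean nucleus size (`minObjectSize`, default 90 px) are removed as
#' `too_small`, and regions lacking a connected cluster of at least
#' `minNucleusPixels` pixels with epithelial density >=
#' `minNucleusIntensity` (default 0.7) are removed as `no_nucleus`. Each
#' removal is recorded with its reason.
#'
#' @param labels integer instance map from [watershedGlands()].
#' @param epithelial epithelial density map in [0, 1], aligned with `labels`.
#' @param config a [glandSegConfig()] list.
#' @param mask,seeds optional provenance to carry into the result (default:
#'   derived from `labels`).
#' @return a [GlandSegmentation-class].
#' @export
filterObjects <- function(labels, epithelial, config = glandSegConfig(),
                          mask = NULL, seeds = NULL) {
  sc <- .checkSegConfig(config$segmentation)
  .checkMatrix(epithelial, "epithelial")
  if (!all(dim(labels) == dim(epithelial)))
    invalidInput("labels and epithelial map must have the same shape")
  if (any(epithelial < 0) || any(epithelial > 1))
    invalidInput("epithelial map must lie in [0, 1]")
  if (is.null(mask)) mask <- labels > 0
  if (is.null(seeds)) seeds <- matrix(0L, nrow(labels), ncol(labels))
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  keep <- logical(length(ids))
  reason <- character(length(ids))
  area <- integer(length(ids))
  hot <- epithelial >= sc$minNucleusIntensity
  for (i in seq_along(ids)) {
    id <- ids[i]
    inReg <- labels == id
    area[i] <- sum(inReg)
    if (area[i] < sc$minObjectSize) {
      reason[i] <- "too_small"
      next
    }
    nuc <- inReg & hot
    if (!any(nuc)) {
      reason[i] <- "no_nucleus"
      next
    }
    # crop to the region's bounding box before labeling nucleus clusters
    rc <- which(nuc, arr.ind = TRUE)
    rr <- range(rc[, 1]); cc <- range(rc[, 2])
    sub <- matrix(as.integer(nuc[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]),
                  rr[2] - rr[1] + 1L)
    comp <- cpp_label(sub, sc$connectivity)
    if (max(tabulate(comp[comp > 0])) >= sc$minNucleusPixels) {
      keep[i] <- TRUE
    } else {
      reason[i] <- "no_nucleus"
    }
  }
  out <- labels
  out[out %in% ids[!keep]] <- 0L
  kept <- ids[keep]
  objects <- if (length(kept)) {
    cent <- lapply(kept, function(id) {
      rc <- which(labels == id, arr.ind = TRUE)
      c(mean(rc[, 1]), mean(rc[, 2]))
    })
    data.frame(id = kept, area = area[keep],
               centroidRow = vapply(cent, `[`, 0, 1),
               centroidCol = vapply(cent, `[`, 0, 2))
  } else {
    data.frame(id = integer(), area = integer(),
               centroidRow = numeric(), centroidCol = numeric())
  }
  rejected <- data.frame(id = ids[!keep], reason = reason[!keep],
                         area = area[!keep])
  new("GlandSegmentation", labels = out, allLabels = labels,
      seeds = seeds, mask = mask, rejected = rejected, objects = objects,
      config = config$segmentation)
}

#' Segment the glands of a tissue tile
#'
#' The full pipeline: blind color decomposition, morphological opening of the
#' stromal map, gradient-maximization mask, adaptive-erosion seed extraction,
#' marker-controlled watershed, and nucleus-presence filtering. Fully
#' deterministic given the seed.
#'
#' @param tile an [RGBTile-class].
#' @param config a [glandSegConfig()] list.
#' @param seed integer seed (used by the EM stain fit).
#' @return a [GlandSegmentation-class].
#' @export
segmentGlands <- function(tile, config = glandSegConfig(), seed = 1L) {
  sc <- .checkSegConfig(config$segmentation)
  dec <- decomposeStains(tile, seed = seed, config = config)
  stromal <- smoothStroma(densityMap(dec$maps, "stromal"), config)
  mask <- gradientThreshold(stromal, polarity = "below")
  seeds <- extractSeeds(stromal, mask, config)
  labels <- watershedGlands(stromal, seeds, mask, sc$connectivity)
  filterObjects(labels, densityMap(dec$maps, "epithelial"), config,
                mask = mask, seeds = seeds)
}
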