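# Shared fixtures and independent oracles.

# Cloud with points at given planar coordinates (kept near the triangle
# centroid so the barycentric coordinates stay valid).
cloudFromPlanar <- function(P) {
  pts <- fromPlanar(P)
  new("ChromaticityCloud", points = pts, totalOD = rep(1, nrow(pts)),
      nPixels = nrow(pts), minTotalOD = 0)
}

# Two-component Gaussian cloud in planar coordinates.
twoGaussianCloud <- function(n, m1, m2, sigma, w1 = 0.5, seed = 1) {
  set.seed(seed)
  n1 <- round(n * w1)
  P <- rbind(
    cbind(rnorm(n1, m1[1], sigma), rnorm(n1, m1[2], sigma)),
    cbind(rnorm(n - n1, m2[1], sigma), rnorm(n - n1, m2[2], sigma)))
  cloudFromPlanar(P)
}

# Build a StainModel directly from planar means (bypasses EM).
modelFromPlanar <- function(mu, covs, weights = c(0.5, 0.5)) {
  refs <- fromPlanar(mu)
  new("StainModel", nStains = nrow(mu), references = refs, covariances = covs,
      weights = weights / sum(weights), mixingMatrix = t(refs),
      logLik = 0, iterations = 1L, converged = TRUE, seed = 1L)
}

diskMat <- function(H, W, center, r) {
  dy <- row(matrix(0, H, W)) - center[1]
  dx <- col(matrix(0, H, W)) - center[2]
  dy^2 + dx^2 <= r^2
}

# Independent exhaustive gradient-maximization threshold search (the oracle
# for gradientThreshold): same contract, separately written.
oracleGradientThreshold <- function(map, nLevels = 256L) {
  H <- nrow(map); W <- ncol(map)
  P <- map[c(1, 1:H, H), c(1, 1:W, W)]
  at <- function(dr, dc) P[1:H + 1 + dr, 1:W + 1 + dc]
  gx <- (at(-1, 1) + 2 * at(0, 1) + at(1, 1)) -
        (at(-1, -1) + 2 * at(0, -1) + at(1, -1))
  gy <- (at(1, -1) + 2 * at(1, 0) + at(1, 1)) -
        (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1))
  grad <- sqrt(gx^2 + gy^2)
  lo <- min(map); hi <- max(map)
  best <- -Inf; bestT <- NA_real_
  for (i in seq_len(nLevels) - 1L) {
    t <- lo + (hi - lo) * (i + 0.5) / nLevels
    ab <- map > t
    A <- ab[c(1, 1:H, H), c(1, 1:W, W)]
    opp <- matrix(FALSE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      opp <- opp | (A[1:H + 1 + dr, 1:W + 1 + dc] != ab)
    }
    if (!any(opp)) next
    m <- sum(grad[opp]) / sum(opp)
    if (m > best) { best <- m; bestT <- t }
  }
  bestT
}

# Brute-force Calinski-Harabasz via the full scatter matrices.
oracleCalinskiHarabasz <- function(P, labels) {
  n <- nrow(P); ids <- unique(labels); k <- length(ids)
  grand <- colMeans(P)
  B <- matrix(0, ncol(P), ncol(P)); W <- matrix(0, ncol(P), ncol(P))
  for (g in ids) {
    Pg <- P[labels == g, , drop = FALSE]
    cg <- colMeans(Pg)
    W <- W + crossprod(sweep(Pg, 2, cg))
    B <- B + nrow(Pg) * tcrossprod(cg - grand)
  }
  (sum(diag(B)) / (k - 1)) / (sum(diag(W)) / (n - k))
}

# Smooth random map in [0, 1], 8-bit quantized.
randomQuantizedMap <- function(H, W, seed) {
  set.seed(seed)
  z <- matrix(rnorm(H * W), H, W)
  s <- as.matrix(EBImage::gblur(z, sigma = 4))
  s <- (s - min(s)) / diff(range(s))
  round(s * 255) / 255
}

# A quick noise-free one-gland tissue spec.
pureTileSpec <- function(seed = 7L, size = 128L) {
  tissueSpec(c(size, size),
             list(glandSpec("well_formed", c(size / 2, size / 2), size * 0.23,
                            nNuclei = 8L)),
             ccdSigma = 0, stainIntensityCV = 0, boundarySigma = 0,
             rngSeed = seed)
}
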