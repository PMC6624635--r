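# Forward-model generator of PSR-Htx-like tiles with per-pixel ground truth.
# Densities are painted per tissue type (stroma field, epithelial cytoplasm,
# high-density nuclei, empty lumina) and rendered through the Beer-Lambert
# relation I = I0 * exp(-M d), with smooth multiplicative stain-intensity
# variation and additive Gaussian camera noise.

#' Describe one gland for the tile generator
#'
#' @param architecture one of `"benign"`, `"well_formed"`, `"poorly_formed"`,
#'   `"cribriform"`, `"fused"`, `"single_cells"`, `"nucleus_free_trap"`,
#'   `"bare_nuclei"`.
#' @param center `c(row, col)` of the gland center.
#' @param size characteristic radius in px.
#' @param lumenFrac lumen radius as a fraction of the gland radius (0 = none).
#' @param nLumina number of internal lumina (cribriform uses >= 2).
#' @param nNuclei number of nuclei to place.
#' @param nucleusRadius nucleus disk radius in px.
#' @param irregularity relative amplitude of the random-radius star boundary.
#' @return a `glandseg_glandspec` list.
#' @export
glandSpec <- function(architecture, center, size, lumenFrac = 0.4,
                      nLumina = 1L, nNuclei = 10L, nucleusRadius = 5,
                      irregularity = 0.12) {
  archs <- c("benign", "well_formed", "poorly_formed", "cribriform", "fused",
             "single_cells", "nucleus_free_trap", "bare_nuclei")
  if (!architecture %in% archs)
    invalidInput(sprintf("unknown architecture '%s'", architecture))
  structure(list(architecture = architecture, center = center, size = size,
                 lumenFrac = lumenFrac, nLumina = as.integer(nLumina),
                 nNuclei = as.integer(nNuclei), nucleusRadius = nucleusRadius,
                 irregularity = irregularity),
            class = "glandseg_glandspec")
}

#' Describe a synthetic tissue tile
#'
#' @param imageSize `c(H, W)` in px.
#' @param glands list of [glandSpec()] objects.
#' @param stromalReference,epithelialReference barycentric reference
#'   chromaticities of the two stains (must be non-collinear).
#' @param stromaAmplitude,cytoplasmAmplitude,nucleusAmplitude painted optical
#'   densities of the tissue compartments.
#' @param ccdSigma additive Gaussian camera noise, in counts.
#' @param stainIntensityCV coefficient of variation of the smooth
#'   multiplicative stain-intensity field.
#' @param boundarySigma Gaussian blur (px) applied to the painted density
#'   fields; emulates the soft tissue boundaries of real sections.
#' @param rngSeed integer seed; generation is deterministic given it.
#' @return a `glandseg_tissuespec` list.
#' @export
tissueSpec <- function(imageSize = c(320L, 320L), glands = list(),
                       stromalReference = c(0.60, 0.25, 0.15),
                       epithelialReference = c(0.30, 0.30, 0.40),
                       stromaAmplitude = 1.4, cytoplasmAmplitude = 0.9,
                       nucleusAmplitude = 2.3, ccdSigma = 2,
                       stainIntensityCV = 0.08, boundarySigma = 1,
                       rngSeed = 1L) {
  sr <- stromalReference / sum(stromalReference)
  er <- epithelialReference / sum(epithelialReference)
  cr <- sr / sqrt(sum(sr^2)) - er / sqrt(sum(er^2))
  if (sqrt(sum(cr^2)) < 1e-6)
    invalidInput("stain references must be non-collinear")
  for (g in glands) {
    if (g$center[1] - g$size < 1 || g$center[2] - g$size < 1 ||
        g$center[1] + g$size > imageSize[1] || g$center[2] + g$size > imageSize[2])
      invalidInput("glands must fit within the image bounds")
  }
  structure(list(imageSize = as.integer(imageSize), glands = glands,
                 stromalReference = sr, epithelialReference = er,
                 stromaAmplitude = stromaAmplitude,
                 cytoplasmAmplitude = cytoplasmAmplitude,
                 nucleusAmplitude = nucleusAmplitude, ccdSigma = ccdSigma,
                 stainIntensityCV = stainIntensityCV,
                 boundarySigma = boundarySigma, rngSeed = as.integer(rngSeed)),
            class = "glandseg_tissuespec")
}

.smoothField <- function(H, W, sigma) {
  sigma <- min(sigma, min(H, W) %/% 7)  # keep the Gaussian brush inside the tile
  z <- matrix(stats::rnorm(H * W), H, W)
  s <- as.matrix(EBImage::gblur(z, sigma = sigma))
  s / stats::sd(s)
}

# Star-convex random-radius polygon mask: K control radii interpolated by a
# periodic spline over the polar angle.
.starMask <- function(H, W, center, size, irregularity, K = 10L) {
  ang <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  radii <- size * (1 + irregularity * (2 * stats::runif(K) - 1))
  rfun <- stats::splinefun(c(ang, 2 * pi), c(radii, radii[1]),
                           method = "periodic")
  dy <- row(matrix(0, H, W)) - center[1]
  dx <- col(matrix(0, H, W)) - center[2]
  phi <- atan2(dy, dx) %% (2 * pi)
  sqrt(dy^2 + dx^2) <= rfun(phi)
}

.diskMask <- function(H, W, center, radius) {
  dy <- row(matrix(0, H, W)) - center[1]
  dx <- col(matrix(0, H, W)) - center[2]
  dy^2 + dx^2 <= radius^2
}

# Paint one gland; returns updated fields. Nuclei go on a ring near the
# boundary for benign/well-formed (basally located), at random interior
# positions otherwise.
.paintGland <- function(g, id, st) {
  H <- nrow(st$stroma); W <- ncol(st$stroma)
  arch <- g$architecture
  lumen <- matrix(FALSE, H, W)
  if (arch == "fused") {
    off <- g$size * 0.55
    phi <- stats::runif(1, 0, 2 * pi)
    c1 <- g$center + off * c(sin(phi), cos(phi))
    c2 <- g$center - off * c(sin(phi), cos(phi))
    m1 <- .starMask(H, W, c1, g$size * 0.85, g$irregularity)
    m2 <- .starMask(H, W, c2, g$size * 0.85, g$irregularity)
    glandMask <- m1 | m2
    if (g$lumenFrac > 0) {
      lumen <- .diskMask(H, W, c1, g$size * 0.85 * g$lumenFrac) |
               .diskMask(H, W, c2, g$size * 0.85 * g$lumenFrac)
    }
    nucCenters <- lapply(seq_len(g$nNuclei), function(i) {
      base <- if (i %% 2 == 0) c1 else c2
      a <- stats::runif(1, 0, 2 * pi)
      base + 0.78 * g$size * 0.85 * c(sin(a), cos(a))
    })
  } else if (arch == "bare_nuclei") {
    glandMask <- .diskMask(H, W, g$center, g$nucleusRadius)
    nucCenters <- list(g$center)
  } else if (arch == "single_cells") {
    glandMask <- .diskMask(H, W, g$center, g$size)
    nucCenters <- list(g$center)
  } else {
    glandMask <- .starMask(H, W, g$center, g$size, g$irregularity)
    if (arch == "cribriform") {
      n <- max(2L, g$nLumina)
      ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
      rad <- stats::runif(n, 0.25, 0.5) * g$size
      for (k in seq_len(n))
        lumen <- lumen | .diskMask(H, W, g$center + rad[k] * c(sin(ang[k]), cos(ang[k])),
                                   0.16 * g$size)
    } else if (g$lumenFrac > 0 && g$nLumina > 0) {
      lumen <- .diskMask(H, W, g$center, g$size * g$lumenFrac)
    }
    ring <- arch %in% c("benign", "well_formed")
    nucCenters <- lapply(seq_len(g$nNuclei), function(i) {
      if (ring) {
        a <- 2 * pi * (i - 1) / g$nNuclei + stats::runif(1, -0.15, 0.15)
        g$center + 0.76 * g$size * c(sin(a), cos(a))
      } else {
        a <- stats::runif(1, 0, 2 * pi)
        g$center + stats::runif(1, 0.15, 0.6) * g$size * c(sin(a), cos(a))
      }
    })
  }
  lumen <- lumen & glandMask
  if (any(st$instances[glandMask] != 0))
    invalidInput("glands overlap beyond the declared fusion")
  cyto <- glandMask & !lumen
  st$stroma[glandMask] <- 0
  st$epi[cyto] <- st$spec$cytoplasmAmplitude
  st$epi[lumen] <- 0
  if (arch != "nucleus_free_trap") {
    for (nc in nucCenters) {
      nd <- .diskMask(H, W, nc, g$nucleusRadius) & glandMask & !lumen
      st$epi[nd] <- st$spec$nucleusAmplitude
      st$nucleus[nd] <- TRUE
    }
  }
  st$instances[glandMask] <- id
  st$arch[as.character(id)] <- arch
  st
}

#' Generate one synthetic tile with ground truth
#'
#' @param spec a [tissueSpec()].
#' @return list with `tile` (an [RGBTile-class], 8-bit scale, background 255)
#'   and `truth` (a [GroundTruth-class]).
#' @export
generateTile <- function(spec) {
  stopifnot(inherits(spec, "glandseg_tissuespec"))
  withSeed(spec$rngSeed, {
    H <- spec$imageSize[1]; W <- spec$imageSize[2]
    st <- list(
      stroma = spec$stromaAmplitude * (1 + 0.1 * .smoothField(H, W, 25)),
      epi = matrix(0, H, W),
      instances = matrix(0L, H, W),
      nucleus = matrix(FALSE, H, W),
      arch = stats::setNames(character(0), character(0)),
      spec = spec)
    st$stroma <- pmax(st$stroma, 0.5 * spec$stromaAmplitude)
    for (i in seq_along(spec$glands))
      st <- .paintGland(spec$glands[[i]], i, st)
    if (spec$stainIntensityCV > 0) {
      st$stroma <- st$stroma * pmax(0.2, 1 + spec$stainIntensityCV * .smoothField(H, W, 40))
      st$epi <- st$epi * pmax(0.2, 1 + spec$stainIntensityCV * .smoothField(H, W, 40))
    }
    if (spec$boundarySigma > 0) {
      st$stroma <- pmax(as.matrix(EBImage::gblur(st$stroma, sigma = spec$boundarySigma)), 0)
      st$epi <- pmax(as.matrix(EBImage::gblur(st$epi, sigma = spec$boundarySigma)), 0)
    }
    I0 <- 255
    pixels <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      od <- st$stroma * spec$stromalReference[ch] + st$epi * spec$epithelialReference[ch]
      I <- I0 * exp(-od)
      if (spec$ccdSigma > 0) I <- I + stats::rnorm(H * W, sd = spec$ccdSigma)
      pixels[, , ch] <- pmin(I0, pmax(0, I))
    }
    tile <- RGBTile(pixels, background = rep(I0, 3), bitDepth = 8L)
    truth <- new("GroundTruth", instances = st$instances,
                 architecture = st$arch, nucleusMask = st$nucleus)
    list(tile = tile, truth = truth)
  })
}

.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 97 + i * 1009) %% 2147483647)
}

#' Generate a fixed catalog of challenge tiles
#'
#' Small named suites reproducing the gland architectures and failure-mode
#' traps the segmentation must handle: benign glands, well-formed (grade 3),
#' poorly formed / cribriform / fused (grade 4), single cells (grade 5), and
#' nucleus-free structures (epithelium-free rings and bare nuclei) that a
#' correct pipeline must reject. `"mixed"` concatenates all of them.
#'
#' @param catalog one of `"benign"`, `"grade3"`, `"grade4_cribriform"`,
#'   `"grade4_fused"`, `"grade5_cells"`, `"nucleus_free_traps"`, `"mixed"`.
#' @param seed integer master seed; the suite is byte-identical given it.
#' @return list of elements `name`, `tile`, `truth`.
#' @export
generateSuite <- function(catalog = "mixed", seed = 1L) {
  catalogs <- c("benign", "grade3", "grade4_cribriform", "grade4_fused",
                "grade5_cells", "nucleus_free_traps", "poorly_formed", "mixed")
  if (!catalog %in% catalogs)
    invalidInput(sprintf("unknown catalog '%s'", catalog))
  if (catalog == "mixed") {
    parts <- c("benign", "grade3", "grade4_cribriform", "grade4_fused",
               "grade5_cells", "poorly_formed", "nucleus_free_traps")
    out <- list()
    for (i in seq_along(parts))
      out <- c(out, generateSuite(parts[i], seed = .deriveSeed(seed, i * 131)))
    return(out)
  }
  specs <- switch(catalog,
    benign = tissueSpec(c(320L, 320L), list(
      glandSpec("benign", c(92, 90), 46, lumenFrac = 0.45, nNuclei = 14L),
      glandSpec("benign", c(226, 218), 44, lumenFrac = 0.45, nNuclei = 14L)),
      rngSeed = .deriveSeed(seed, 1)),
    grade3 = tissueSpec(c(352L, 352L), {
      centers <- expand.grid(r = c(64, 176, 288), c = c(64, 176, 288))
      lapply(seq_len(8), function(i)
        glandSpec("well_formed", c(centers$r[i], centers$c[i]) +
                    round(6 * sin(i * c(2, 3))), 27, lumenFrac = 0.4,
                  nNuclei = 10L))
    }, rngSeed = .deriveSeed(seed, 2)),
    grade4_cribriform = tissueSpec(c(320L, 320L), list(
      glandSpec("cribriform", c(86, 86), 56, nLumina = 3L, nNuclei = 20L,
                irregularity = 0.1),
      glandSpec("cribriform", c(230, 226), 56, nLumina = 4L, nNuclei = 20L,
                irregularity = 0.1)),
      rngSeed = .deriveSeed(seed, 3)),
    grade4_fused = tissueSpec(c(320L, 320L), list(
      glandSpec("fused", c(88, 88), 42, lumenFrac = 0.35, nNuclei = 16L),
      glandSpec("fused", c(228, 224), 42, lumenFrac = 0.35, nNuclei = 16L)),
      rngSeed = .deriveSeed(seed, 4)),
    grade5_cells = tissueSpec(c(256L, 256L), {
      centers <- list(c(52, 54), c(58, 160), c(126, 104), c(122, 210),
                      c(196, 58), c(202, 172))
      lapply(centers, function(cc)
        glandSpec("single_cells", cc, 6.8, lumenFrac = 0, nNuclei = 1L,
                  nucleusRadius = 4))
    }, rngSeed = .deriveSeed(seed, 5)),
    poorly_formed = tissueSpec(c(288L, 288L), {
      centers <- list(c(66, 70), c(76, 198), c(190, 74), c(204, 206))
      lapply(centers, function(cc)
        glandSpec("poorly_formed", cc, 17, lumenFrac = 0.25, nNuclei = 5L,
                  irregularity = 0.3))
    }, rngSeed = .deriveSeed(seed, 6)),
    nucleus_free_traps = tissueSpec(c(256L, 256L), list(
      glandSpec("nucleus_free_trap", c(70, 72), 22, lumenFrac = 0.55),
      glandSpec("nucleus_free_trap", c(182, 168), 24, lumenFrac = 0.55),
      glandSpec("bare_nuclei", c(196, 62), 5, nucleusRadius = 5)),
      rngSeed = .deriveSeed(seed, 7))
  )
  res <- generateTile(specs)
  list(list(name = catalog, tile = res$tile, truth = res$truth))
}
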