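#' Pipeline configuration
#'
#' Builds the nested configuration record shared by all stages. Every entry
#' can be overridden by name; unknown names are an error, so typos in config
#' files surface immediately.
#'
#' @param ... named overrides, e.g. `segmentation = list(minObjectSize = 120)`.
#'   Nested lists are merged field-by-field into the defaults.
#' @return a list of class `glandseg_config` with components `bcd`,
#'   `segmentation`, `evaluation`, `synthetic`, `seed`, `verbosity`.
#' @details Defaults follow the published pipeline: a 6 x 6 px opening kernel,
#'   a 90 px minimum object size (the mean epithelial nucleus size), and a 0.7
#'   minimum nucleus intensity in the normalized epithelial density map.
#' @examples
#' cfg <- glandSegConfig(segmentation = list(minObjectSize = 120))
#' cfg$segmentation$minObjectSize
#' @export
glandSegConfig <- function(...) {
  defaults <- list(
    bcd = list(
      backgroundQuantile = 0.99,  # I0 estimate: per-channel upper quantile
      minTotalOD = 0.10,          # background exclusion threshold
      odScale = 2.5,              # density normalization divisor
      nStains = 2L,
      emMaxIter = 500L,
      emTol = 1e-8,
      emRidge = 1e-6,
      emMaxPoints = 20000L,       # deterministic subsample cap for EM
      fallbackSingleStain = FALSE
    ),
    segmentation = list(
      openingKernel = c(6L, 6L),
      minObjectSize = 90L,
      minNucleusIntensity = 0.7,
      minNucleusPixels = 10L,
      erosionMaxAxis = 9,         # max FULL axis of the elliptical SE, px
      tensorSigma = 3,
      connectivity = 8L
    ),
    evaluation = list(
      iouMatch = 0.5,
      coverageLow = 0.2,
      coverageHigh = 0.7
    ),
    synthetic = list(
      stromalReference = c(0.60, 0.25, 0.15),
      epithelialReference = c(0.30, 0.30, 0.40),
      stromaAmplitude = 1.4,
      cytoplasmAmplitude = 0.9,
      nucleusAmplitude = 2.3,
      ccdSigma = 2,               # additive camera noise, counts
      stainIntensityCV = 0.08,    # smooth multiplicative stain variation
      boundarySigma = 1
    ),
    seed = 1L,
    verbosity = 1L
  )
  cfg <- .mergeConfig(defaults, list(...))
  class(cfg) <- c("glandseg_config", "list")
  cfg
}

.mergeConfig <- function(base, over) {
  if (length(over) == 0) return(base)
  if (is.null(names(over)) || any(!nzchar(names(over))))
    invalidConfig("configuration overrides must be named")
  for (nm in names(over)) {
    if (!nm %in% names(base))
      invalidConfig(sprintf("unknown configuration field '%s'", nm))
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else
      base[[nm]] <- over[[nm]]
  }
  base
}

.checkSegConfig <- function(sc) {
  if (any(sc$openingKernel < 1) || length(sc$openingKernel) != 2L)
    invalidConfig("openingKernel must be two positive sizes")
  if (sc$minObjectSize < 1) invalidConfig("minObjectSize must be positive")
  if (sc$minNucleusIntensity <= 0 || sc$minNucleusIntensity > 1)
    invalidConfig("minNucleusIntensity must be in (0, 1]")
  if (sc$minNucleusPixels < 1) invalidConfig("minNucleusPixels must be positive")
  if (sc$erosionMaxAxis <= 0 || sc$tensorSigma <= 0)
    invalidConfig("erosionMaxAxis and tensorSigma must be positive")
  if (!sc$connectivity %in% c(4L, 8L))
    invalidConfig("connectivity must be 4 or 8")
  invisible(sc)
}

#' Read or write a pipeline configuration as YAML
#'
#' The on-disk format mirrors [glandSegConfig()] field-for-field; reading
#' merges the file over the package defaults so partial files are valid.
#'
#' @param path file path.
#' @param config a `glandseg_config` list.
#' @return `readPipelineConfig` returns a `glandseg_config`;
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) invalidInput(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(glandSegConfig, raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
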