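# Shared I/O: reading RGB tiles, writing segmentation artifacts
# (label TIFF, object table CSV, boundary GeoJSON, run manifest).

#' Read an RGB tile from TIFF or PNG
#'
#' @param path path to an 8- or 16-bit, 3-channel TIFF or PNG.
#' @param background optional per-channel I0; estimated from the tile
#'   (`backgroundQuantile`) when `NULL`.
#' @param backgroundQuantile quantile for the I0 estimate.
#' @return an [RGBTile-class].
#' @export
readImageTile <- function(path, background = NULL, backgroundQuantile = 0.99) {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    bits <- 8L
  } else {
    invalidInput(sprintf("unsupported image format '%s'", ext))
  }
  d <- dim(img)
  if (length(d) < 3L || d[3] < 3L)
    invalidInput("input is not a 3-channel RGB image")
  img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  RGBTile(img * (2^bits - 1), background = background,
          bitDepth = as.integer(bits),
          backgroundQuantile = backgroundQuantile)
}

#' Write / read an instance label map as 16-bit TIFF
#'
#' @param labels integer matrix (values < 65536).
#' @param path output path.
#' @return `writeLabelMap`: the path, invisibly; `readLabelMap`: the integer
#'   matrix.
#' @export
writeLabelMap <- function(labels, path) {
  if (max(labels) > 65535) invalidInput("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# CCW boundary polygon of one region mask, in 0-based (x = col, y = row)
# pixel coordinates, via the 0.5-level contour of the padded indicator.
.regionPolygon <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- as.numeric(mask)
  cl <- grDevices::contourLines(x = seq_len(H + 2L) - 2L,  # 0-based rows
                                y = seq_len(W + 2L) - 2L,  # 0-based cols
                                z = pad, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  # keep the longest ring as the exterior
  cl <- cl[[which.max(vapply(cl, function(u) length(u$x), 0))]]
  xy <- cbind(x = cl$y, y = cl$x)  # contourLines' x follows dim 1 = rows
  if (any(xy[1, ] != xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  # signed area; exterior rings are CCW in x-right / y-down pixel coords
  a <- sum(xy[-nrow(xy), 1] * xy[-1, 2] - xy[-1, 1] * xy[-nrow(xy), 2]) / 2
  if (a < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  xy
}

#' Write segmentation artifacts
#'
#' Writes the accepted-object label map (16-bit TIFF), the per-object table
#' (CSV: id, area, centroid, bounding box, accepted flag and reject reason),
#' the object boundary polygons (GeoJSON, pixel coordinates, CCW exteriors),
#' and a JSON run manifest listing every artifact with its md5 checksum plus
#' the configuration echo.
#'
#' @param result a [GlandSegmentation-class].
#' @param outDir output directory (created if missing).
#' @param seed seed to echo into the manifest.
#' @return the manifest, invisibly (list).
#' @export
writeSegmentationResult <- function(result, outDir, seed = NA_integer_) {
  stopifnot(is(result, "GlandSegmentation"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  labPath <- file.path(outDir, "labels.tif")
  writeLabelMap(result@labels, labPath)

  all <- result@allLabels
  ids <- setdiff(sort(unique(as.integer(all))), 0L)
  rej <- result@rejected
  rows <- lapply(ids, function(id) {
    rc <- which(all == id, arr.ind = TRUE)
    rejected <- id %in% rej$id
    data.frame(id = id, area = nrow(rc),
               centroidRow = mean(rc[, 1]) - 1, centroidCol = mean(rc[, 2]) - 1,
               bboxRowMin = min(rc[, 1]) - 1L, bboxRowMax = max(rc[, 1]) - 1L,
               bboxColMin = min(rc[, 2]) - 1L, bboxColMax = max(rc[, 2]) - 1L,
               accepted = !rejected,
               reason = if (rejected) rej$reason[rej$id == id] else "")
  })
  objTab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), area = integer(), centroidRow = numeric(),
               centroidCol = numeric(), bboxRowMin = integer(),
               bboxRowMax = integer(), bboxColMin = integer(),
               bboxColMax = integer(), accepted = logical(),
               reason = character())
  csvPath <- file.path(outDir, "objects.csv")
  utils::write.csv(objTab, csvPath, row.names = FALSE)

  keptIds <- setdiff(sort(unique(as.integer(result@labels))), 0L)
  features <- lapply(keptIds, function(id) {
    xy <- .regionPolygon(result@labels == id)
    if (is.null(xy)) return(NULL)
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(xy)),
                                            function(i) unname(xy[i, ])))))
  })
  features <- Filter(Negate(is.null), features)
  geo <- list(type = "FeatureCollection", features = features)
  geoPath <- file.path(outDir, "objects.geojson")
  jsonlite::write_json(geo, geoPath, auto_unbox = TRUE, digits = NA)

  files <- c(labPath, csvPath, geoPath)
  manifest <- list(
    seed = seed,
    config = result@config,
    artifacts = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write an RGB tile to 8-bit TIFF
#'
#' Quantizes the tile to its bit depth and writes a 3-channel TIFF.
#'
#' @param tile an [RGBTile-class].
#' @param path output path.
#' @export
writeImageTile <- function(tile, path) {
  stopifnot(is(tile, "RGBTile"))
  maxv <- 2^tile@bitDepth - 1
  tiff::writeTIFF(round(tile@pixels) / maxv, path,
                  bits.per.sample = tile@bitDepth)
  invisible(path)
}
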