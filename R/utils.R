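# Internal helpers: classed conditions, triangle-plane geometry, gradients.

stopCondition <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "glandseg_error")))
}

invalidInput   <- function(msg, ...) stopCondition("glandseg_invalid_input", msg, ...)
invalidConfig  <- function(msg, ...) stopCondition("glandseg_invalid_config", msg, ...)
degenerateInput   <- function(msg, ...) stopCondition("glandseg_degenerate_input", msg, ...)
degenerateStain   <- function(msg, ...) stopCondition("glandseg_degenerate_stain", msg, ...)
degenerateCluster <- function(msg, ...) stopCondition("glandseg_degenerate_cluster", msg, ...)
convergenceError  <- function(msg, iterations) {
  stopCondition("glandseg_convergence", msg, iterations = iterations)
}
invalidSeed <- function(msg, seedId) {
  stopCondition("glandseg_invalid_seed", msg, seedId = seedId)
}

# Orthonormal basis of the plane {x : sum(x) = 1}; barycentric points are
# rank-2, so EM and the cluster metrics work in these planar coordinates.
.triCenter <- c(1, 1, 1) / 3
.triBasis <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))

#' Planar triangle coordinates
#'
#' Maps barycentric chromaticity points to an orthonormal 2-D coordinate
#' system in the triangle plane (and back). Euclidean distance in these
#' coordinates equals Euclidean distance between the barycentric vectors.
#'
#' @param points N x 3 barycentric matrix (rows sum to 1).
#' @param xy N x 2 planar matrix.
#' @return `toPlanar`: N x 2 matrix; `fromPlanar`: N x 3 barycentric matrix.
#' @export
toPlanar <- function(points) {
  points <- rbind(points)
  sweep(points, 2, .triCenter) %*% .triBasis
}

#' @rdname toPlanar
#' @export
fromPlanar <- function(xy) {
  xy <- rbind(xy)
  p <- xy %*% t(.triBasis)
  sweep(p, 2, .triCenter, "+")
}

# Replicate-padded shift: value of m at (r + dr, c + dc), edges clamped.
.shift <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) + dr, 1L), H), pmin(pmax(seq_len(W) + dc, 1L), W)]
}

#' Sobel gradient magnitude
#'
#' 3 x 3 Sobel operator with replicate boundary handling; x is the column
#' direction, y the row direction.
#'
#' @param map numeric matrix.
#' @return list with `gx`, `gy` and `magnitude` matrices.
#' @export
sobelGradient <- function(map) {
  gx <- (.shift(map, -1L, 1L) + 2 * .shift(map, 0L, 1L) + .shift(map, 1L, 1L)) -
        (.shift(map, -1L, -1L) + 2 * .shift(map, 0L, -1L) + .shift(map, 1L, -1L))
  gy <- (.shift(map, 1L, -1L) + 2 * .shift(map, 1L, 0L) + .shift(map, 1L, 1L)) -
        (.shift(map, -1L, -1L) + 2 * .shift(map, -1L, 0L) + .shift(map, -1L, 1L))
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# Offsets (dr, dc) of a flat rectangular SE of size (ky, kx), anchored at
# floor(size / 2) (0-based), matching the usual image-processing convention.
.rectOffsets <- function(ky, kx) {
  ay <- ky %/% 2L; ax <- kx %/% 2L
  as.matrix(expand.grid(dr = seq_len(ky) - 1L - ay, dc = seq_len(kx) - 1L - ax))
}

# Reflection of an offset set about the origin (for the dilation in an
# opening, so that erode/dilate use properly mirrored structuring elements).
.reflectOffsets <- function(off) -off

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.checkMatrix <- function(map, name = "map") {
  if (!is.matrix(map) || !is.numeric(map))
    invalidInput(sprintf("%s must be a numeric matrix", name))
}
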