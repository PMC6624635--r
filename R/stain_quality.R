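# Stain-protocol quality metrics: cluster separability of the stain clouds
# in the chromaticity triangle. Used to compare staining protocols - a good
# protocol yields compact, well-separated stain clusters.

#' Mahalanobis separation of the two stain clusters
#'
#' Distance between the two component means under the weight-pooled
#' covariance, `sqrt((m1 - m2)' S^-1 (m1 - m2))` with
#' `S = w1 S1 + w2 S2`, computed in planar triangle coordinates. Pooling uses
#' the mixture weights rather than hard-assignment counts, since the fitted
#' mixture (not any particular labeling) is the object being scored.
#'
#' @param model a 2-stain [StainModel-class].
#' @return non-negative scalar.
#' @export
mahalanobisSeparation <- function(model) {
  stopifnot(is(model, "StainModel"))
  if (model@nStains != 2L)
    invalidInput("mahalanobisSeparation requires exactly 2 components")
  mu <- toPlanar(model@references)
  S <- model@weights[1] * model@covariances[[1]] +
       model@weights[2] * model@covariances[[2]]
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det) || det <= 1e-300)
    degenerateCluster("pooled covariance is singular")
  d <- mu[1, ] - mu[2, ]
  q <- (S[2, 2] * d[1]^2 - 2 * S[1, 2] * d[1] * d[2] + S[1, 1] * d[2]^2) / det
  sqrt(max(0, q))
}

#' Calinski-Harabasz index of a labeled chromaticity cloud
#'
#' `[tr(B)/(k - 1)] / [tr(W)/(n - k)]` with B and W the between- and
#' within-cluster scatter matrices in planar triangle coordinates. A zero
#' within-scatter with distinct centers yields `Inf` (flagged with a warning):
#' perfectly compact, separated clusters.
#'
#' @param cloud a [ChromaticityCloud-class] (or an N x 2 planar matrix).
#' @param labels integer cluster assignment per point, >= 2 clusters with
#'   >= 2 points each.
#' @return scalar index (possibly `Inf`).
#' @export
calinskiHarabasz <- function(cloud, labels) {
  P <- if (is(cloud, "ChromaticityCloud")) toPlanar(cloud@points) else as.matrix(cloud)
  labels <- as.integer(labels)
  if (length(labels) != nrow(P))
    invalidInput("labels must have one entry per point")
  tab <- table(labels)
  k <- length(tab)
  n <- nrow(P)
  if (k < 2L || any(tab < 2L))
    degenerateCluster("need >= 2 clusters with >= 2 points each")
  grand <- colMeans(P)
  trW <- 0; trB <- 0
  for (g in names(tab)) {
    Pg <- P[labels == as.integer(g), , drop = FALSE]
    cg <- colMeans(Pg)
    trW <- trW + sum(sweep(Pg, 2, cg)^2)
    trB <- trB + nrow(Pg) * sum((cg - grand)^2)
  }
  if (trW <= 0) {
    warning("zero within-cluster scatter; Calinski-Harabasz index is infinite")
    return(Inf)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' Stain-quality report
#'
#' Hard-assigns the cloud points to their most probable mixture component,
#' then bundles the Mahalanobis cluster separation, the Calinski-Harabasz
#' index, and the EM mixture weights (the normalized amount of color per
#' cluster) into one report.
#'
#' @param cloud a [ChromaticityCloud-class].
#' @param model the [StainModel-class] fitted to that cloud.
#' @return a [ClusterReport-class].
#' @export
stainQualityReport <- function(cloud, model) {
  stopifnot(is(cloud, "ChromaticityCloud"), is(model, "StainModel"))
  if (model@nStains < 2L)
    degenerateCluster("stain-quality metrics require >= 2 components")
  P <- toPlanar(cloud@points)
  mu <- toPlanar(model@references)
  lp <- vapply(seq_len(model@nStains), function(j)
    log(model@weights[j]) + .logdnorm2(P, mu[j, ], model@covariances[[j]]),
    numeric(nrow(P)))
  labels <- max.col(lp, ties.method = "first")
  if (length(unique(labels)) < 2L || any(table(labels) < 2L))
    degenerateCluster("hard assignment produced a degenerate clustering")
  new("ClusterReport",
      mahalanobis = mahalanobisSeparation(model),
      calinskiHarabasz = calinskiHarabasz(P, labels),
      weights = model@weights,
      nPoints = nrow(P))
}
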