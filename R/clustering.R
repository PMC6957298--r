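#' Density-based clustering of labeled cells (deterministic DBSCAN)
#'
#' Size-and-shape-invariant density clustering of cell centroids in
#' physical micrometers. A point is a core point when its
#' eps-neighborhood contains at least \code{minDensity} points (including
#' the point itself under the default inclusive convention). Clusters are
#' connected components of core points under eps-reachability; a non-core
#' point within eps of one or more core points joins the cluster of the
#' nearest core (ties broken toward the lowest point index), making the
#' assignment independent of input order, unlike classic DBSCAN. All other
#' points are noise (label 0). Cluster labels are assigned in order of each
#' cluster's lowest member index, so relabeling is permutation-stable.
#'
#' @param points data.frame with columns \code{x_um}, \code{y_um} (a column
#'   \code{id} is carried through when present), or a 2-column matrix.
#' @param params from [clusteringParams()]; defaults to the published
#'   operating point eps = 136 um, minimum density 4.
#' @return a [ClusterAssignment-class].
#' @examples
#' # a "+" of 5 points spaced 100 um: the center is core (5 neighbors),
#' # so all 5 form one cluster at eps = 136, minDensity = 4
#' pts <- data.frame(x_um = c(0, 100, -100, 0, 0),
#'                   y_um = c(0, 0, 0, 100, -100))
#' table(clusterLabels(sidcCluster(pts)))
#' @export
sidcCluster <- function(points, params = clusteringParams()) {
  if (is.matrix(points))
    points <- data.frame(x_um = points[, 1], y_um = points[, 2])
  if (is.null(points$id)) points$id <- seq_len(nrow(points))
  n <- nrow(points)
  emptyAssign <- function() new("ClusterAssignment",
    points = data.frame(id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), cluster = integer(0)),
    clusters = data.frame(cluster = integer(0), size = integer(0),
                          centroid_x_um = numeric(0),
                          centroid_y_um = numeric(0)),
    params = params)
  if (n == 0) return(emptyAssign())
  if (any(!is.finite(points$x_um)) || any(!is.finite(points$y_um)))
    stop("coordinates must be finite")

  eps <- params$epsUm
  minPts <- if (isTRUE(params$inclusive)) params$minDensity
            else params$minDensity + 1

  xy <- as.matrix(points[, c("x_um", "y_um")])
  d <- crossDist(xy, xy)
  within <- d <= eps
  nbCount <- rowSums(within)            # includes the point itself
  core <- nbCount >= minPts

  labels <- integer(n)
  if (any(core)) {
    coreIdx <- which(core)
    pairs <- which(within & outer(core, core, "&") & upper.tri(d),
                   arr.ind = TRUE)
    comp <- unionFind(n, pairs)
    coreComp <- comp[coreIdx]
    # relabel components by lowest core-member index
    first <- tapply(coreIdx, coreComp, min)
    ord <- order(first)
    relab <- stats::setNames(seq_along(ord), names(first)[ord])
    labels[coreIdx] <- relab[as.character(coreComp)]

    border <- which(!core)
    for (p in border) {
      near <- coreIdx[d[p, coreIdx] <= eps]
      if (!length(near)) next
      dd <- d[p, near]
      best <- near[order(dd, near)][1]   # nearest core, lowest index on ties
      labels[p] <- labels[best]
    }
  }

  clTab <- if (any(labels > 0)) {
    ids <- sort(unique(labels[labels > 0]))
    data.frame(cluster = ids,
               size = vapply(ids, function(k) sum(labels == k), integer(1)),
               centroid_x_um = vapply(ids, function(k)
                 mean(xy[labels == k, 1]), numeric(1)),
               centroid_y_um = vapply(ids, function(k)
                 mean(xy[labels == k, 2]), numeric(1)))
  } else data.frame(cluster = integer(0), size = integer(0),
                    centroid_x_um = numeric(0), centroid_y_um = numeric(0))

  new("ClusterAssignment",
      points = data.frame(id = points$id, x_um = xy[, 1], y_um = xy[, 2],
                          cluster = labels),
      clusters = clTab, params = params)
}

#' Percent of points found in clusters
#'
#' The dispersion readout: 100 x (points assigned to any cluster) / (all
#' points), per color. Undefined (NA) when there are no points.
#'
#' @param assignment a [ClusterAssignment-class].
#' @return percentage in [0, 100], or NA.
#' @export
percentInClusters <- function(assignment) {
  stopifnot(is(assignment, "ClusterAssignment"))
  n <- nrow(assignment@points)
  if (n == 0) return(NA_real_)
  100 * sum(assignment@points$cluster > 0) / n
}

#' Cluster each single-labeled color separately
#'
#' Red and green cells are clustered independently (the dispersion of each
#' genotype is reported per color); yellow cells are excluded.
#'
#' @param cellSet a [LabeledCellSet-class].
#' @param params from [clusteringParams()].
#' @param colors which classes to cluster.
#' @return named list of [ClusterAssignment-class] objects plus
#'   \code{percentInClusters}, a named numeric (NA for absent colors).
#' @export
clusterByColor <- function(cellSet, params = clusteringParams(),
                           colors = c("red", "green")) {
  stopifnot(is(cellSet, "LabeledCellSet"))
  det <- cellSet@detections
  out <- list()
  pct <- stats::setNames(rep(NA_real_, length(colors)), colors)
  for (cc in colors) {
    sub <- det[det$class == cc, c("id", "x_um", "y_um"), drop = FALSE]
    a <- sidcCluster(sub, params)
    out[[cc]] <- a
    pct[[cc]] <- percentInClusters(a)
  }
  out$percentInClusters <- pct
  out
}
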