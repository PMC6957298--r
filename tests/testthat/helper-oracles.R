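# Independent by-definition oracles used to cross-check the package's own
# implementations on small instances.

# Brute-force DBSCAN straight from the definition: dense distance matrix,
# core points, igraph connected components over core-core eps-edges,
# border points to the nearest core (lowest index on ties), labels
# canonicalized by lowest member index.
oracleDbscan <- function(xy, eps, minPts) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(xy))
  within <- d <= eps
  core <- rowSums(within) >= minPts   # diagonal counts the point itself
  labels <- integer(n)
  if (any(core)) {
    ci <- which(core)
    A <- within[ci, ci, drop = FALSE]
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(g)$membership
    first <- tapply(ci, comp, min)
    relab <- rank(first)
    labels[ci] <- relab[comp]
    for (p in which(!core)) {
      nearCores <- ci[within[p, ci]]
      if (length(nearCores)) {
        dd <- d[p, nearCores]
        best <- nearCores[order(dd, nearCores)][1]
        labels[p] <- labels[best]
      }
    }
  }
  as.integer(labels)
}

# Brute-force twin-spot grouping: igraph components over the
# "distance <= radius" graph on single-labeled cells; keep components with
# both colors that satisfy the isolation rule. Returns a list of sorted
# member-id vectors, ordered for comparison.
oracleTwinSpots <- function(det, groupRadius, isolation) {
  singles <- det[det$class %in% c("red", "green"), , drop = FALSE]
  n <- nrow(singles)
  if (n == 0) return(list())
  d <- as.matrix(stats::dist(singles[, c("x_um", "y_um")]))
  A <- d <= groupRadius
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (!any(singles$class[idx] == "red")) next
    if (!any(singles$class[idx] == "green")) next
    rest <- setdiff(seq_len(n), idx)
    if (length(rest) && min(d[idx, rest]) <= isolation) next
    out[[length(out) + 1]] <- sort(singles$id[idx])
  }
  out[order(vapply(out, min, numeric(1)))]
}

# Monte-Carlo oracle for the pooled green/red ratio of the clone-size law
# (size = 1 + Poisson(base*fold - 1)) over a run with nTot events of which
# each is G2-X with probability pG2x. Returns mean and sd of the pooled
# ratio and of the green fraction.
oracleRatioMC <- function(nTot, pG2x, foldG, foldR, base = 1.6,
                          nrep = 4000) {
  ratio <- gfrac <- numeric(nrep)
  for (i in seq_len(nrep)) {
    k <- stats::rbinom(1, nTot, pG2x)
    if (k == 0) { ratio[i] <- NA; gfrac[i] <- NA; next }
    g <- sum(1 + stats::rpois(k, base * foldG - 1))
    r <- sum(1 + stats::rpois(k, base * foldR - 1))
    ratio[i] <- g / r
    gfrac[i] <- g / (g + r)
  }
  list(ratioMean = mean(ratio, na.rm = TRUE),
       ratioSd = stats::sd(ratio, na.rm = TRUE),
       gfracMean = mean(gfrac, na.rm = TRUE),
       gfracSd = stats::sd(gfrac, na.rm = TRUE))
}

# Small LabeledCellSet constructor for hand-laid layouts.
makeCellSet <- function(x, y, class, pixelScale = 248 / 82) {
  det <- data.frame(id = seq_along(x), x_um = x, y_um = y,
                    red_int = as.numeric(class %in% c("red", "yellow")),
                    green_int = as.numeric(class %in% c("green", "yellow")),
                    class = class, stringsAsFactors = FALSE)
  new("LabeledCellSet", detections = det, pixelScale = pixelScale,
      thresholds = c(red = 0.5, green = 0.5), source = "test")
}
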