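# Internal geometry helpers shared across modules.

# Shoelace area of a polygon given as an n x 2 matrix (vertices in order,
# not closed). Positive regardless of orientation.
polygonArea <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

polygonPerimeter <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((p[i2, 1] - p[, 1])^2 + (p[i2, 2] - p[, 2])^2))
}

polygonCentroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

# Pairwise euclidean distances between rows of a and rows of b.
crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Union-find with path compression; merges is a 2-column index matrix.
unionFind <- function(n, merges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(merges)) {
    for (r in seq_len(nrow(merges))) {
      a <- find(merges[r, 1]); b <- find(merges[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Reflect points falling outside the disc of radius R (centred at origin)
# back across the boundary circle.
reflectIntoDisc <- function(xy, R) {
  r <- sqrt(rowSums(xy^2))
  out <- r > R
  if (any(out)) {
    rn <- 2 * R - r[out]
    rn <- pmax(pmin(rn, R), 0)         # clip pathological double-crossers
    xy[out, ] <- xy[out, , drop = FALSE] * (rn / r[out])
  }
  xy
}

# Stage seeds: every stage of a simulation draws from its own stream derived
# from the config seed, in a fixed documented order, so stages are
# individually and jointly reproducible.
stageSeed <- function(config, stage) {
  offs <- c(positions = 0L, madm = 1L, channels = 2L, junctions = 3L)
  s <- as.integer(config@seed) + offs[[stage]]
  s %% .Machine$integer.max
}
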