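test_that("hand-computable layouts cluster by definition", {
  # 4 collinear points spaced 100 um: max neighborhood size 3 -> all noise
  line <- data.frame(x_um = c(0, 100, 200, 300), y_um = rep(0, 4))
  a <- sidcCluster(line)
  expect_equal(clusterLabels(a), rep(0L, 4))

  # 5 points in a "+" at spacing 100: center is core (neighborhood 5)
  plus <- data.frame(x_um = c(0, 100, -100, 0, 0),
                     y_um = c(0, 0, 0, 100, -100))
  b <- sidcCluster(plus)
  expect_equal(sort(unique(clusterLabels(b))), 1L)
  expect_equal(nrow(b@clusters), 1)
  expect_equal(b@clusters$size, 5)

  # empty input
  expect_equal(nrow(sidcCluster(data.frame(x_um = numeric(0),
                                           y_um = numeric(0)))@points), 0)
  expect_error(sidcCluster(data.frame(x_um = NaN, y_um = 0)), "finite")
})

test_that("membership agrees exactly with the by-definition oracle", {
  prm <- clusteringParams()
  set.seed(71)
  for (rep in 1:120) {
    n <- sample(1:100, 1)
    xy <- cbind(runif(n, 0, 800), runif(n, 0, 800))
    mine <- clusterLabels(sidcCluster(xy, prm))
    orc <- oracleDbscan(xy, prm$epsUm, prm$minDensity)
    expect_identical(mine, orc)
  }
})

test_that("assignment is equivariant under rescaling of space and eps", {
  set.seed(72)
  xy <- cbind(runif(60, 0, 600), runif(60, 0, 600))
  a <- clusterLabels(sidcCluster(xy, clusteringParams(epsUm = 136)))
  b <- clusterLabels(sidcCluster(xy * 3.7,
                                 clusteringParams(epsUm = 136 * 3.7)))
  expect_identical(a, b)
})

test_that("assignment is invariant under input permutation", {
  set.seed(73)
  n <- 80
  xy <- data.frame(id = 1:n, x_um = runif(n, 0, 500),
                   y_um = runif(n, 0, 500))
  a <- sidcCluster(xy)@points
  perm <- sample.int(n)
  b <- sidcCluster(xy[perm, ])@points
  b <- b[order(b$id), ]
  a <- a[order(a$id), ]
  expect_equal(a$cluster, b$cluster)
})

test_that("percent in clusters is monotone in eps and minDensity", {
  set.seed(74)
  xy <- cbind(runif(120, 0, 900), runif(120, 0, 900))
  pctEps <- vapply(c(60, 100, 136, 200, 300), function(e)
    percentInClusters(sidcCluster(xy, clusteringParams(epsUm = e))),
    numeric(1))
  expect_true(all(diff(pctEps) >= 0))
  pctMin <- vapply(c(2, 3, 4, 6, 8), function(m)
    percentInClusters(sidcCluster(xy, clusteringParams(minDensity = m))),
    numeric(1))
  expect_true(all(diff(pctMin) <= 0))
})

test_that("percent in clusters matches planted layouts", {
  # two tight clusters of 10 plus 5 isolated points -> 80%
  set.seed(75)
  c1 <- cbind(rnorm(10, 0, 15), rnorm(10, 0, 15))
  c2 <- cbind(rnorm(10, 3000, 15), rnorm(10, 3000, 15))
  iso <- cbind(seq(8000, 12000, length.out = 5), rep(0, 5))
  a <- sidcCluster(rbind(c1, c2, iso))
  expect_equal(percentInClusters(a), 80)
  expect_equal(nrow(a@clusters), 2)

  allNoise <- sidcCluster(cbind(seq(0, 4000, by = 500), rep(0, 9)))
  expect_equal(percentInClusters(allNoise), 0)
  oneCluster <- sidcCluster(cbind(rnorm(12, 0, 20), rnorm(12, 0, 20)))
  expect_equal(percentInClusters(oneCluster), 100)
  expect_true(is.na(percentInClusters(sidcCluster(
    data.frame(x_um = numeric(0), y_um = numeric(0))))))
})

test_that("every cluster is anchored on core points", {
  set.seed(76)
  for (rep in 1:20) {
    xy <- cbind(runif(150, 0, 1200), runif(150, 0, 1200))
    a <- sidcCluster(xy)
    if (nrow(a@clusters)) {
      lab <- a@points$cluster
      d <- as.matrix(dist(xy))
      nb <- rowSums(d <= a@params$epsUm)
      core <- nb >= a@params$minDensity
      # each cluster contains a core point, whose eps-neighborhood has at
      # least minDensity points by definition
      for (k in a@clusters$cluster)
        expect_true(any(core[lab == k]))
      # every clustered non-core point is within eps of a core of its cluster
      for (p in which(lab > 0 & !core)) {
        cores <- which(core & lab == lab[p])
        expect_true(min(d[p, cores]) <= a@params$epsUm)
      }
      # noise points are not within eps of any core
      for (p in which(lab == 0))
        expect_true(!any(core & d[p, ] <= a@params$epsUm))
    }
  }
})

test_that("inclusive and exclusive density conventions differ by one", {
  # 4 points mutually within eps: inclusive minDensity 4 clusters them,
  # exclusive does not
  sq <- cbind(c(0, 50, 0, 50), c(0, 0, 50, 50))
  incl <- sidcCluster(sq, clusteringParams(minDensity = 4, inclusive = TRUE))
  excl <- sidcCluster(sq, clusteringParams(minDensity = 4, inclusive = FALSE))
  expect_equal(sum(clusterLabels(incl) > 0), 4)
  expect_equal(sum(clusterLabels(excl) > 0), 0)
})

test_that("low-dispersal clones cluster more than high-dispersal ones", {
  # percent-in-clusters decreases with the dispersal scale at matched
  # event number and expansion fold
  pct <- function(sigma, s) {
    cfg <- madmPreset("KO", seed = s, corneaRadius = 900,
                      targetDensity = 2000, nEvents = 15,
                      eventMinSpacing = 250,
                      dispersalSigma = c(WT = 25, MUT = sigma))
    m <- simulateMadm(cfg, generatePositions(cfg))
    clusterByColor(asLabeledCellSet(m))$percentInClusters[["green"]]
  }
  wins <- 0
  for (s in 81:92) if (pct(14, s) > pct(300, s)) wins <- wins + 1
  expect_gte(wins / 12, 0.95)
})
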