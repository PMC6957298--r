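test_that("a red-green pair forms a minimal twin spot", {
  cs <- makeCellSet(c(0, 50), c(0, 0), c("red", "green"))
  ts <- spots(findTwinSpots(cs))
  expect_equal(nrow(ts), 1)
  expect_equal(ts$size, 2)
  expect_equal(ts$n_red, 1)
  expect_equal(ts$n_green, 1)
  expect_false(ts$flagged)
})

test_that("a lone distant cell is excluded from the twin spot", {
  cs <- makeCellSet(c(0, 50, 350), c(0, 0, 0), c("red", "green", "green"))
  found <- findTwinSpots(cs)
  ts <- spots(found)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$size, 2)
  expect_setequal(found@members[[1]], c(1, 2))
  # matches the brute-force component oracle at radius 248
  orc <- oracleTwinSpots(detections(cs), pxToUm(82), 200)
  expect_equal(length(orc), 1)
  expect_equal(orc[[1]], c(1, 2))
})

test_that("nearby events merge into one component; wide ones are flagged", {
  # two tight events 100 um apart: a single merged component (they are
  # within one grouping radius of each other)
  near <- makeCellSet(c(0, 20, 100, 120), c(0, 0, 0, 0),
                      c("red", "green", "red", "green"))
  tsNear <- spots(findTwinSpots(near))
  expect_equal(nrow(tsNear), 1)
  expect_equal(tsNear$size, 4)
  # a merged chain wider than twice the grouping radius carries the
  # overlap flag
  wide <- makeCellSet(c(0, 200, 400, 600), c(0, 0, 0, 0),
                      c("red", "green", "red", "green"))
  ts <- spots(findTwinSpots(wide))
  expect_equal(nrow(ts), 1)
  expect_true(ts$flagged)          # diameter 600 > 2 * 248 = 496
  expect_equal(ts$size, 4)
})

test_that("yellow cells never join twin spots", {
  cs <- makeCellSet(c(0, 50, 25), c(0, 0, 10), c("red", "green", "yellow"))
  found <- findTwinSpots(cs)
  expect_equal(spots(found)$size, 2)
  expect_false(3 %in% found@members[[1]])
})

test_that("grouping equals the brute-force oracle on random instances", {
  prm <- twinSpotParams()
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(5:60, 1)
    cls <- sample(c("red", "green", "yellow"), n, replace = TRUE)
    cs <- makeCellSet(runif(n, 0, 1500), runif(n, 0, 1500), cls)
    found <- findTwinSpots(cs)
    mine <- lapply(found@members, sort)
    mine <- mine[order(vapply(mine, min, numeric(1)))]
    orc <- oracleTwinSpots(detections(cs), prm$groupRadiusUm, prm$isolationUm)
    expect_equal(mine, orc)
  }
})

test_that("spot count is non-increasing in the isolation distance", {
  set.seed(42)
  n <- 80
  cs <- makeCellSet(runif(n, 0, 2000), runif(n, 0, 2000),
                    sample(c("red", "green"), n, replace = TRUE))
  counts <- vapply(c(100, 200, 300, 248 * 2, 1000), function(iso)
    nrow(spots(findTwinSpots(cs, twinSpotParams(isolationUm = iso)))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summary statistics follow their definitions", {
  # five spots with sizes 2, 2, 3, 4, 8
  xs <- c(0, 10,  1000, 1010,  2000, 2010, 2020,  3000, 3010, 3020, 3030,
          5000, 5010, 5020, 5030, 5040, 5050, 5060, 5070)
  ys <- rep(0, 19)
  cls <- c("red", "green", "red", "green", "red", "green", "green",
           "red", "red", "green", "green",
           "red", "green", "green", "green", "green", "green", "green",
           "green")
  st <- twinSpotStats(findTwinSpots(makeCellSet(xs, ys, cls)))
  expect_equal(st$nSpots, 5)
  expect_equal(st$frac2to4, 0.8)
  expect_equal(st$pooledRatio, sum(cls == "green") / sum(cls == "red"))

  one <- twinSpotStats(findTwinSpots(makeCellSet(
    c(0, 10, 20, 30), rep(0, 4), c("red", "green", "green", "green"))))
  expect_equal(one$perSpotRatio, 3)
  expect_equal(twinSpotStats(findTwinSpots(makeCellSet(
    numeric(0), numeric(0), character(0))))$nSpots, 0)
})

test_that("planted isolated events are recovered perfectly", {
  for (s in 51:58) {
    cfg <- simulationConfig(corneaRadius = 1200, targetDensity = 2000,
                            nEvents = 4, eventMinSpacing = 900,
                            segProbs = c(g2x = 1, g2z = 0, g0g1 = 0),
                            expansionFold = c(WT = 1, MUT = 1),
                            dispersalSigma = c(WT = 30, MUT = 30), seed = s)
    mono <- simulateMadm(cfg, generatePositions(cfg))
    found <- findTwinSpots(asLabeledCellSet(mono))
    cl <- cells(mono)
    lab <- cl[cl$color %in% c("red", "green"), ]
    expect_equal(nrow(spots(found)), 4)
    truthIds <- lapply(split(lab$id, lab$event_id), sort)
    mineIds <- lapply(found@members, sort)
    mineIds <- mineIds[order(vapply(mineIds, min, numeric(1)))]
    truthIds <- truthIds[order(vapply(truthIds, min, numeric(1)))]
    expect_equal(unname(mineIds), unname(truthIds))
  }
})

test_that("WT-like pooled green fraction is symmetric", {
  nG <- nR <- 0; nEv <- 0
  for (s in 61:64) {
    cfg <- madmPreset("WT", seed = s, corneaRadius = 1000,
                      targetDensity = 2000, nEvents = 30,
                      eventMinSpacing = 250,
                      segProbs = c(g2x = 1, g2z = 0, g0g1 = 0))
    cl <- cells(simulateMadm(cfg, generatePositions(cfg)))
    nG <- nG + sum(cl$color == "green")
    nR <- nR + sum(cl$color == "red")
    nEv <- nEv + 30
  }
  set.seed(66)
  mc <- oracleRatioMC(nEv, 1, 1, 1)
  expect_lt(abs(nG / (nG + nR) - 0.5), 3 * mc$gfracSd)
})
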