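test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(segProbs = c(g2x = 0.5, g2z = 0.5, g0g1 = 0.1)),
               "sum to 1")
  expect_error(simulationConfig(corneaRadius = -1), "corneaRadius")
  expect_error(simulationConfig(expansionFold = c(WT = -1, MUT = 1)))
  expect_error(simulationConfig(pixelScale = 0), "pixelScale")
  cfg <- simulationConfig(seed = 1)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(sum(cfg@segProbs), 1)
})

test_that("pixel scale fixes the published radii", {
  expect_equal(pxToUm(82), 248)
  expect_equal(umToPx(248), 82)
  expect_equal(pxToUm(45), 45 * 248 / 82)
})

test_that("position generation hits the target count and spacing", {
  cfg <- simulationConfig(targetDensity = 2500, seed = 1)
  pts <- generatePositions(cfg, shape = "rect", width = 1000, height = 1000)
  expect_equal(nrow(pts), 2500)            # exact by construction
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 1000))
  d <- as.matrix(dist(pts[sample.int(nrow(pts), 600), ]))
  diag(d) <- Inf
  meanSpacing <- 1 / sqrt(2500e-6)
  expect_gt(min(d), 0.4 * meanSpacing)     # blue-noise packing

  # disc geometry
  cfgd <- simulationConfig(corneaRadius = 400, targetDensity = 2000, seed = 2)
  ptsd <- generatePositions(cfgd)
  expect_equal(nrow(ptsd), round(2000e-6 * pi * 400^2))
  expect_true(all(sqrt(rowSums(ptsd^2)) <= 400 + 1e-9))
})

test_that("zero expected count yields an empty set; bad config errors", {
  cfg <- simulationConfig(targetDensity = 0, seed = 1)
  pts <- generatePositions(cfg, shape = "rect", width = 10, height = 10)
  expect_equal(nrow(pts), 0)
  expect_error(generatePositions(simulationConfig(corneaRadius = 400),
                                 shape = "rect"),
               "width and height")
})

test_that("position generation is deterministic given the seed", {
  cfg <- simulationConfig(corneaRadius = 300, targetDensity = 2000, seed = 7)
  expect_identical(generatePositions(cfg), generatePositions(cfg))
  cfg2 <- simulationConfig(corneaRadius = 300, targetDensity = 2000, seed = 8)
  expect_false(identical(generatePositions(cfg), generatePositions(cfg2)))
})

test_that("forced G2-X events produce exact red/green sibling pairs", {
  cfg <- simulationConfig(corneaRadius = 800, targetDensity = 2000,
                          nEvents = 10, eventMinSpacing = 300,
                          segProbs = c(g2x = 1, g2z = 0, g0g1 = 0),
                          expansionFold = c(WT = 1, MUT = 1),
                          cloneBaseMean = 1,          # degenerate: size 1
                          dispersalSigma = c(WT = 0, MUT = 0), seed = 3)
  mono <- simulateMadm(cfg, generatePositions(cfg))
  cl <- cells(mono)
  expect_equal(sum(cl$color == "red"), 10)
  expect_equal(sum(cl$color == "green"), 10)
  meanDiam <- 2 / sqrt(pi * 2000e-6)
  for (e in 1:10) {
    ev <- cl[!is.na(cl$event_id) & cl$event_id == e, ]
    expect_setequal(ev$color, c("red", "green"))
    d <- dist(ev[, c("x_um", "y_um")])
    expect_lt(max(d), 2 * meanDiam)        # siblings adjacent
  }
})

test_that("G2-Z-only simulations contain no single-labeled cells", {
  cfg <- simulationConfig(corneaRadius = 600, targetDensity = 1500,
                          nEvents = 8, eventMinSpacing = 250,
                          segProbs = c(g2x = 0, g2z = 1, g0g1 = 0), seed = 4)
  cl <- cells(simulateMadm(cfg, generatePositions(cfg)))
  expect_equal(sum(cl$color %in% c("red", "green")), 0)
  expect_equal(sum(cl$color == "yellow"), 8)
  expect_equal(sum(!is.na(cl$event_id) & cl$color == "colorless"), 8)
})

test_that("color-genotype bookkeeping follows the MADM mode", {
  for (s in 1:3) {
    cfgGR <- madmPreset("KO", seed = s, corneaRadius = 600,
                        targetDensity = 1500, nEvents = 10,
                        eventMinSpacing = 200)
    cl <- cells(simulateMadm(cfgGR, generatePositions(cfgGR)))
    expect_true(all(cl$genotype[cl$color == "green"] == "MUT"))
    expect_true(all(cl$genotype[cl$color == "red"] == "WT"))
    expect_true(all(cl$genotype[cl$color == "yellow"] == "HET"))

    cfgWT <- madmPreset("WT", seed = s, corneaRadius = 600,
                        targetDensity = 1500, nEvents = 10,
                        eventMinSpacing = 200)
    clw <- cells(simulateMadm(cfgWT, generatePositions(cfgWT)))
    expect_true(all(clw$genotype[clw$color %in% c("red", "green")] == "WT"))
  }
})

test_that("zero dispersal keeps clones on their founders", {
  cfg <- simulationConfig(corneaRadius = 600, targetDensity = 1500,
                          nEvents = 6, eventMinSpacing = 300,
                          segProbs = c(g2x = 1, g2z = 0, g0g1 = 0),
                          expansionFold = c(WT = 2, MUT = 2),
                          dispersalSigma = c(WT = 0, MUT = 0), seed = 5)
  cl <- cells(simulateMadm(cfg, generatePositions(cfg)))
  meanDiam <- 2 / sqrt(pi * 1500e-6)
  for (k in unique(na.omit(cl$clone_id))) {
    cc <- cl[!is.na(cl$clone_id) & cl$clone_id == k, ]
    if (nrow(cc) > 1)
      expect_lt(max(dist(cc[, c("x_um", "y_um")])), 2 * meanDiam)
  }
})

test_that("aggregate green/red ratio converges to the expansion fold", {
  # pool enough G2-X events that the pooled ratio is tight, then compare
  # with the Monte-Carlo expectation of the clone-size law
  nG <- 0; nR <- 0; nEv <- 0
  for (s in 1:7) {
    cfg <- simulationConfig(corneaRadius = 1000, targetDensity = 2000,
                            nEvents = 30, eventMinSpacing = 220, mode = "GR",
                            segProbs = c(g2x = 1, g2z = 0, g0g1 = 0),
                            expansionFold = c(WT = 1, MUT = 6),
                            dispersalSigma = c(WT = 25, MUT = 25), seed = s)
    cl <- cells(simulateMadm(cfg, generatePositions(cfg)))
    nG <- nG + sum(cl$color == "green")
    nR <- nR + sum(cl$color == "red")
    nEv <- nEv + 30
  }
  set.seed(99)
  mc <- oracleRatioMC(nEv, 1, 6, 1)
  expect_lt(abs(nG / nR - 6), 3 * mc$ratioSd)
})

test_that("monolayer generation is bit-identical across runs", {
  cfg <- madmPreset("CK", seed = 11, corneaRadius = 600,
                    targetDensity = 1500, nEvents = 8, eventMinSpacing = 250)
  m1 <- simulateMadm(cfg, generatePositions(cfg))
  m2 <- simulateMadm(cfg, generatePositions(cfg))
  expect_identical(cells(m1), cells(m2))
})

test_that("channel rendering maps coordinates and colors exactly", {
  cfg <- simulationConfig(corneaRadius = 150, targetDensity = 1500,
                          pixelScale = 3, spotSigma = 6,
                          noise = list(background = 0, poisson = FALSE,
                                       streaks = FALSE), seed = 1)
  tab <- data.frame(x_um = 100, y_um = 100, color = "red")
  ch <- renderChannels(tab, cfg, window = c(0, 300, 0, 300))
  am <- which(ch$red == max(ch$red), arr.ind = TRUE)
  expect_equal(unname(am[1, ] - 1L), c(33L, 33L))   # 0-based pixel (33, 33)
  expect_equal(max(ch$green), 0)

  tab2 <- data.frame(x_um = 151, y_um = 200, color = "yellow")
  ch2 <- renderChannels(tab2, cfg, window = c(0, 300, 0, 300))
  expect_equal(which.max(ch2$red), which.max(ch2$green))

  # truth positions map to spot maxima within 1 px when noise is off
  cfg3 <- madmPreset("WT", seed = 6, corneaRadius = 400, targetDensity = 1500,
                     nEvents = 6, eventMinSpacing = 150,
                     noise = list(background = 0, poisson = FALSE,
                                  streaks = FALSE))
  mono <- simulateMadm(cfg3, generatePositions(cfg3))
  ch3 <- renderChannels(mono)
  lab <- cells(mono)
  reds <- lab[lab$color == "red", ]
  if (nrow(reds)) {
    for (i in seq_len(nrow(reds))) {
      ixy <- c(floor((reds$x_um[i] - ch3$window[1]) / cfg3@pixelScale),
               floor((reds$y_um[i] - ch3$window[3]) / cfg3@pixelScale)) + 1
      patch <- ch3$red[(ixy[1] - 2):(ixy[1] + 2), (ixy[2] - 2):(ixy[2] + 2)]
      am <- which(patch == max(patch), arr.ind = TRUE)[1, ]
      expect_lte(max(abs(am - 3)), 1)
    }
  }
  expect_error(renderChannels(tab, cfg, window = c(0, 50, 0, 50)),
               "field too small")
})

test_that("junction rendering encloses one face per cell", {
  cfg <- simulationConfig(junctionPixelScale = 1,
                          noise = list(background = 0, poisson = FALSE,
                                       streaks = FALSE), seed = 1)
  # regular hexagonal lattice
  sp <- 24
  g <- expand.grid(i = 0:9, j = 0:9)
  pts <- cbind(g$i * sp + (g$j %% 2) * sp / 2 + 20, g$j * sp * sqrt(3) / 2 + 20)
  img <- renderJunctions(pts, cfg, window = c(0, max(pts[, 1]) + 20,
                                              0, max(pts[, 2]) + 20))
  tess <- detectCells(img)
  expect_equal(nrow(cells(tess)), 100)

  # minimal 3-point tessellation
  tri <- cbind(c(30, 90, 60), c(30, 30, 90))
  img3 <- renderJunctions(tri, cfg, window = c(0, 120, 0, 120))
  expect_equal(nrow(cells(detectCells(img3))), 3)
  expect_error(renderJunctions(tri[1:2, ], cfg), "at least 3")

  # determinism
  imgA <- renderJunctions(tri, cfg, window = c(0, 120, 0, 120))
  expect_identical(img3, imgA)
})
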