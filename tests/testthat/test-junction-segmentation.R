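noiseOff <- list(background = 0, poisson = FALSE, streaks = FALSE)

test_that("segmentation recovers planted cells on a rendered field", {
  cfg <- simulationConfig(targetDensity = 2500, junctionPixelScale = 1,
                          noise = noiseOff, seed = 21)
  pts <- generatePositions(cfg, shape = "rect", width = 300, height = 300)
  img <- renderJunctions(pts, cfg)
  tess <- detectCells(img)
  tc <- cells(tess)
  expect_lt(abs(nrow(tc) - nrow(pts)) / nrow(pts), 0.02)

  # matched per-cell area error against the generator's tile areas
  truthA <- attr(img, "truthAreas")
  seeds <- attr(img, "truthSeeds")
  dmat <- sqrt(outer(seeds[, 1], tc$centroid_x_um, "-")^2 +
               outer(seeds[, 2], tc$centroid_y_um, "-")^2)
  nn <- apply(dmat, 1, which.min)
  relErr <- abs(tc$area_um2[nn] - truthA) / truthA
  expect_lt(median(relErr[!tc$is_border[nn]]), 0.05)
})

test_that("blank images give an empty tessellation with a warning", {
  img <- matrix(0.5, 50, 50)
  attr(img, "pixelScale") <- 1
  expect_warning(tess <- detectCells(img), "blank|constant")
  expect_equal(nrow(cells(tess)), 0)
  expect_error(detectCells(matrix(runif(100), 10, 10)), "pixelScale")
})

test_that("tessellation satisfies partition and symmetry invariants", {
  cfg <- simulationConfig(targetDensity = 2000, junctionPixelScale = 1,
                          noise = noiseOff, seed = 22)
  pts <- generatePositions(cfg, shape = "rect", width = 250, height = 250)
  tess <- detectCells(renderJunctions(pts, cfg))
  tc <- cells(tess)
  # interior + border tiles tile the window (deldir partition)
  expect_lt(abs(sum(tc$area_um2) - 250 * 250) / (250 * 250), 0.01)
  # neighbor symmetry
  for (i in seq_along(tess@neighbors))
    for (j in tess@neighbors[[i]])
      expect_true(i %in% tess@neighbors[[j]])
  # interior polygons pairwise disjoint: sum of areas <= window area
  expect_lte(sum(tc$area_um2[!tc$is_border]), 250 * 250 + 1)
})

test_that("circularity matches closed forms and is monotone over n-gons", {
  ngon <- function(n, r = 10) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(r * cos(a), r * sin(a))
  }
  sq <- cellTessellationFromPolygons(list(cbind(c(0, 20, 20, 0),
                                                c(0, 0, 20, 20))))
  expect_equal(morphometrics(sq)$circularity, pi / 4, tolerance = 1e-9)
  disc <- cellTessellationFromPolygons(list(ngon(256)))
  expect_equal(morphometrics(disc)$circularity, 1, tolerance = 0.02)
  circ <- vapply(c(3, 4, 6, 256), function(n)
    morphometrics(cellTessellationFromPolygons(list(ngon(n))))$circularity,
    numeric(1))
  expect_true(all(diff(circ) > 0))
  expect_true(all(circ >= 0 & circ <= 1))
})

test_that("interior cells of a hexagonal lattice have six neighbors", {
  cfg <- simulationConfig(junctionPixelScale = 1, noise = noiseOff, seed = 1)
  sp <- 24
  g <- expand.grid(i = 0:8, j = 0:8)
  pts <- cbind(g$i * sp + (g$j %% 2) * sp / 2 + 20,
               g$j * sp * sqrt(3) / 2 + 20)
  tess <- detectCells(renderJunctions(pts, cfg,
                                      window = c(0, max(pts[, 1]) + 20,
                                                 0, max(pts[, 2]) + 20)))
  m <- morphometrics(tess)
  tc <- cells(tess)
  # lattice cells away from the field edge (their whole neighborhood is
  # interior, so no tile is clipped by the window)
  deep <- !tc$is_border &
    vapply(tess@neighbors, function(nb) all(!tc$is_border[nb]), logical(1))
  interior <- m[deep[m$id], ]
  expect_gt(nrow(interior), 10)
  expect_true(all(interior$n_neighbors == 6))
})

test_that("degenerate polygons are dropped with a message", {
  polys <- list(cbind(c(0, 20, 20, 0), c(0, 0, 20, 20)),
                cbind(c(0, 10, 20), c(0, 0, 0)))   # collinear: zero area
  tess <- cellTessellationFromPolygons(polys)
  expect_message(m <- morphometrics(tess), "degenerate")
  expect_equal(nrow(m), 1)
})

test_that("density arithmetic and border weighting are exact", {
  expect_equal(cellDensity(100, areaMm2 = 0.04), 2500)
  expect_equal(cellDensity(0, areaMm2 = 1), 0)
  expect_equal(cellDensity(90, areaMm2 = 0.04, borderCount = 20), 2500)
  expect_error(cellDensity(10, areaMm2 = 0), "area")
})

test_that("density recovery on a cropped ROI is within 5% of planted", {
  cfg <- simulationConfig(targetDensity = 2500, junctionPixelScale = 1,
                          noise = noiseOff, seed = 23)
  pts <- generatePositions(cfg, shape = "rect", width = 420, height = 420)
  img <- renderJunctions(pts, cfg)
  roi <- cropField(img, c(50, 370, 50, 370))
  est <- cellDensity(detectCells(roi))
  expect_lt(abs(est - 2500) / 2500, 0.05)
})

test_that("regional classification follows the sampling geometry", {
  sp <- regionSpec()
  expect_equal(classifyRegion(1000, 0, sp), "central")
  expect_equal(classifyRegion(1380, 0, sp), "peripheral")  # 120 um in from edge
  expect_true(is.na(classifyRegion(1300, 0, sp)))
  expect_error(regionSpec(centralRadius = 1400), "centralRadius")

  rois <- sampleRegions(sp)
  expect_equal(nrow(rois), 8)
  expect_equal(sum(rois$region == "central"), 4)
  expect_equal(sum(rois$region == "peripheral"), 4)
  r <- sqrt(rois$cx_um^2 + rois$cy_um^2)
  expect_true(all(r[rois$region == "central"] <= sp@centralRadius))
  expect_true(all(r[rois$region == "peripheral"] >=
                  sp@corneaRadius - sp@peripheralBand))
  expect_equal(classifyRegion(rois$cx_um, rois$cy_um, sp), rois$region)
  # one ROI of each class per quadrant
  quad <- (atan2(rois$cy_um, rois$cx_um) %% (2 * pi)) %/% (pi / 2) + 1
  expect_equal(unname(table(quad, rois$region)["1", ]), c(1, 1),
               ignore_attr = TRUE)

  expect_equal(averageRegions(c(1, 2, 3, 4),
                              c("central", "central", "peripheral",
                                "peripheral")),
               c(central = 1.5, peripheral = 3.5))
})
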