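#' Segmentation parameters for junction images
#'
#' @param smoothSigmaUm Gaussian smoothing sigma, um.
#' @param hFrac watershed seed depth (h-minima) as a fraction of the
#'   enhanced image's dynamic range.
#' @param enhance logical; subtract a large-scale Gaussian background
#'   (white-ridge enhancement) before seed extraction.
#' @param enhanceSigmaFactor background sigma as a multiple of
#'   \code{smoothSigmaUm}.
#' @param minAreaUm2 basins smaller than this are treated as noise seeds and
#'   dropped before tessellation.
#' @return list of parameters.
#' @export
segmentationParams <- function(smoothSigmaUm = 1.5, hFrac = 0.1,
                               enhance = TRUE, enhanceSigmaFactor = 8,
                               minAreaUm2 = 20) {
  list(smoothSigmaUm = smoothSigmaUm, hFrac = hFrac, enhance = enhance,
       enhanceSigmaFactor = enhanceSigmaFactor, minAreaUm2 = minAreaUm2)
}

#' Detect endothelial cells in a junction-label image
#'
#' Implements the filtering + Dirichlet-tessellation segmentation used for
#' boundary-labeled monolayers: Gaussian smoothing, optional white-ridge
#' enhancement (large-scale background subtraction), seed extraction as
#' h-minima basins of the junction signal (watershed of the inverted image
#' with flooding tolerance \code{hFrac} of the dynamic range), and a
#' Dirichlet/Voronoi partition of the seed centroids clipped to the image
#' window. One polygon is returned per seed; cells whose tile touches the
#' image border are flagged \code{is_border}.
#'
#' @param image numeric matrix (junction intensity; bright ridges).
#' @param pixelScale micrometers per pixel; taken from the image attribute
#'   when absent.
#' @param params from [segmentationParams()].
#' @return a [CellTessellation-class].
#' @examples
#' cfg <- simulationConfig(seed = 4, junctionPixelScale = 1,
#'                         noise = list(background = 0, poisson = FALSE,
#'                                      streaks = FALSE))
#' pts <- generatePositions(cfg, shape = "rect", width = 300, height = 300)
#' img <- renderJunctions(pts, cfg)
#' tess <- detectCells(img)
#' nrow(cells(tess))
#' @export
detectCells <- function(image, pixelScale = NULL,
                        params = segmentationParams()) {
  if (is.null(pixelScale)) pixelScale <- attr(image, "pixelScale")
  if (is.null(pixelScale)) stop("pixelScale is required")
  window <- attr(image, "window")
  m <- as.matrix(image)
  nx <- nrow(m); ny <- ncol(m)
  if (is.null(window)) window <- c(0, nx * pixelScale, 0, ny * pixelScale)

  emptyTess <- function() new("CellTessellation",
    cells = data.frame(id = integer(0), centroid_x_um = numeric(0),
                       centroid_y_um = numeric(0), area_um2 = numeric(0),
                       perimeter_um = numeric(0), is_border = logical(0)),
    polygons = list(), neighbors = list(), pixelScale = pixelScale,
    window = window, provenance = "detectCells")

  if (diff(range(m)) == 0) {
    warning("blank or constant image: empty tessellation")
    return(emptyTess())
  }

  sm <- as.matrix(EBImage::gblur(EBImage::Image(m),
                                 sigma = max(params$smoothSigmaUm / pixelScale,
                                             0.3)))
  if (isTRUE(params$enhance)) {
    bgS <- params$enhanceSigmaFactor * params$smoothSigmaUm / pixelScale
    bg <- as.matrix(EBImage::gblur(EBImage::Image(sm), sigma = bgS))
    sm <- pmax(sm - bg, 0)
  }
  rng <- diff(range(sm))
  if (rng == 0) {
    warning("image has no structure after filtering: empty tessellation")
    return(emptyTess())
  }
  inv <- max(sm) - sm
  ws <- EBImage::watershed(EBImage::Image(inv),
                           tolerance = params$hFrac * rng, ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))
  nlab <- max(lab)
  if (nlab < 1) {
    warning("no basins found: empty tessellation")
    return(emptyTess())
  }

  # seed per basin: centroid of the pixels near the basin minimum
  idx <- which(lab > 0)
  labv <- lab[idx]
  vals <- sm[idx]
  minv <- tapply(vals, labv, min)
  eps <- 0.02 * rng
  nearMin <- vals <= minv[as.character(labv)] + eps
  ix <- ((idx - 1) %% nx) + 1
  iy <- ((idx - 1) %/% nx) + 1
  sx <- tapply(ix[nearMin], labv[nearMin], mean)
  sy <- tapply(iy[nearMin], labv[nearMin], mean)
  npix <- tapply(rep(1, sum(nearMin)), labv[nearMin], length)
  basinSize <- tapply(rep(1, length(labv)), labv, length)
  keep <- basinSize * pixelScale^2 >= params$minAreaUm2
  sx <- sx[keep]; sy <- sy[keep]
  if (length(sx) < 3) {
    warning("fewer than 3 seeds: empty tessellation")
    return(emptyTess())
  }
  seedX <- pxIndexToUm(as.numeric(sx), window[1], pixelScale)
  seedY <- pxIndexToUm(as.numeric(sy), window[3], pixelScale)

  tessellationFromSeeds(cbind(seedX, seedY), window, pixelScale,
                        provenance = "detectCells")
}

# Dirichlet tessellation of seed points clipped to a rectangular window,
# with polygon geometry, edge-sharing neighbors and border flags.
tessellationFromSeeds <- function(seeds, window, pixelScale,
                                  provenance = "seeds") {
  dd <- deldir::deldir(seeds[, 1], seeds[, 2], rw = window[c(1, 2, 3, 4)])
  tiles <- deldir::tile.list(dd)
  n <- length(tiles)
  polys <- vector("list", n)
  area <- per <- cx <- cy <- numeric(n)
  isBorder <- logical(n)
  tol <- 1e-7 * max(diff(window[1:2]), diff(window[3:4]))
  for (i in seq_len(n)) {
    p <- cbind(tiles[[i]]$x, tiles[[i]]$y)
    polys[[i]] <- p
    area[i] <- polygonArea(p)
    per[i] <- polygonPerimeter(p)
    cen <- polygonCentroid(p)
    cx[i] <- cen[1]; cy[i] <- cen[2]
    isBorder[i] <- any(p[, 1] <= window[1] + tol | p[, 1] >= window[2] - tol |
                       p[, 2] <= window[3] + tol | p[, 2] >= window[4] - tol)
  }
  # neighbors: tiles sharing a Dirichlet edge of length >= 1 px
  segs <- dd$dirsgs
  elen <- sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2)
  nb <- rep(list(integer(0)), n)
  good <- elen >= pixelScale
  for (k in which(good)) {
    a <- segs$ind1[k]; b <- segs$ind2[k]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  cl <- data.frame(id = seq_len(n), centroid_x_um = cx, centroid_y_um = cy,
                   area_um2 = area, perimeter_um = per, is_border = isBorder)
  new("CellTessellation", cells = cl, polygons = polys, neighbors = nb,
      pixelScale = pixelScale, window = window, provenance = provenance)
}

#' Build a tessellation directly from polygons
#'
#' Bypasses image analysis: wraps user-supplied polygons (e.g. analytic
#' shapes) in a [CellTessellation-class] so that [morphometrics()] can be
#' applied to exact geometry.
#'
#' @param polygons list of n x 2 vertex matrices (um).
#' @param pixelScale nominal pixel scale, um/px (affects only the neighbor
#'   edge-length threshold).
#' @return a [CellTessellation-class] with no neighbor relation.
#' @examples
#' sq <- cellTessellationFromPolygons(list(cbind(c(0, 1, 1, 0),
#'                                               c(0, 0, 1, 1)) * 20))
#' morphometrics(sq)$circularity  # pi/4 for a square
#' @export
cellTessellationFromPolygons <- function(polygons, pixelScale = 1) {
  n <- length(polygons)
  area <- per <- cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    area[i] <- polygonArea(p)
    per[i] <- polygonPerimeter(p)
    cen <- polygonCentroid(p)
    cx[i] <- cen[1]; cy[i] <- cen[2]
  }
  allx <- unlist(lapply(polygons, function(p) p[, 1]))
  ally <- unlist(lapply(polygons, function(p) p[, 2]))
  cl <- data.frame(id = seq_len(n), centroid_x_um = cx, centroid_y_um = cy,
                   area_um2 = area, perimeter_um = per, is_border = FALSE)
  new("CellTessellation", cells = cl, polygons = polygons,
      neighbors = rep(list(integer(0)), n), pixelScale = pixelScale,
      window = c(min(allx), max(allx), min(ally), max(ally)),
      provenance = "polygons")
}

#' Per-cell morphometrics
#'
#' Computes the shape readouts of the monolayer analysis: apical area,
#' circularity \eqn{4\pi A / P^2} (1 for a disc, clipped to [0, 1]) and the
#' number of neighboring cells (cells sharing a tessellation edge of length
#' at least one pixel). Degenerate polygons (area <= 0) are dropped with a
#' message. Border cells are retained in the table (flagged) but excluded
#' by [summarizeMorphometrics()].
#'
#' @param tess a [CellTessellation-class].
#' @return data.frame: \code{id}, \code{area_um2}, \code{perimeter_um},
#'   \code{circularity}, \code{n_neighbors}, \code{is_border}.
#' @export
morphometrics <- function(tess) {
  stopifnot(is(tess, "CellTessellation"))
  cl <- tess@cells
  if (nrow(cl) == 0) stop("empty tessellation")
  drop <- cl$area_um2 <= 0
  if (any(drop)) {
    message(sum(drop), " degenerate cell(s) dropped (area <= 0)")
  }
  keep <- which(!drop)
  data.frame(
    id = cl$id[keep],
    area_um2 = cl$area_um2[keep],
    perimeter_um = cl$perimeter_um[keep],
    circularity = pmin(pmax(4 * pi * cl$area_um2[keep] /
                              cl$perimeter_um[keep]^2, 0), 1),
    n_neighbors = vapply(tess@neighbors[keep], length, integer(1)),
    is_border = cl$is_border[keep])
}

#' Summary distributions of morphometrics (border cells excluded)
#'
#' @param morpho output of [morphometrics()].
#' @return list with mean/median area, mean circularity, and the neighbor
#'   count histogram over interior cells.
#' @export
summarizeMorphometrics <- function(morpho) {
  m <- morpho[!morpho$is_border, , drop = FALSE]
  list(n = nrow(m),
       meanArea = mean(m$area_um2), medianArea = stats::median(m$area_um2),
       meanCircularity = mean(m$circularity),
       neighborHist = table(factor(m$n_neighbors, levels = 0:12)))
}

#' @describeIn cellDensity density of a tessellated field: interior cells
#'   count 1, border cells 1/2; the sampled area is the image window.
#' @export
setMethod("cellDensity", "CellTessellation", function(x, ...) {
  areaMm2 <- diff(x@window[1:2]) * diff(x@window[3:4]) / 1e6
  nIn <- sum(!x@cells$is_border)
  nBd <- sum(x@cells$is_border)
  cellDensity(nIn, areaMm2 = areaMm2, borderCount = nBd)
})

#' @describeIn cellDensity density from a raw count: \code{x} interior
#'   cells (weight 1) plus \code{borderCount} border cells (weight 1/2)
#'   over \code{areaMm2}.
#' @param areaMm2 sampled area in mm^2.
#' @param borderCount number of border cells (weight 1/2).
#' @export
setMethod("cellDensity", "numeric", function(x, areaMm2, borderCount = 0, ...) {
  if (areaMm2 <= 0) stop("sampled area must be > 0")
  (x + borderCount / 2) / areaMm2
})

#' Place the regional sampling fields of a flat-mount
#'
#' Returns the eight regions of interest of the standard sampling design:
#' one central and one peripheral field per tissue quadrant. Central fields
#' lie inside the central zone; peripheral fields sit in the annulus within
#' \code{peripheralBand} of the cornea edge, both on the quadrant diagonals.
#'
#' @param spec a [RegionSpec-class].
#' @param roiSizeUm side length of each square field, um. The default, with
#'   4+4 fields of 177 um, samples ~0.25 mm^2 in total.
#' @return data.frame: \code{region} (central/peripheral), \code{quadrant},
#'   \code{cx_um}, \code{cy_um}, \code{w_um}, \code{h_um}.
#' @export
sampleRegions <- function(spec, roiSizeUm = 177) {
  stopifnot(is(spec, "RegionSpec"))
  q <- seq_len(spec@nQuadrants)
  ang <- (q - 0.5) * 2 * pi / spec@nQuadrants
  half <- roiSizeUm / 2
  rCen <- min(spec@centralRadius / 2,
              spec@centralRadius - half * sqrt(2))
  rPer <- spec@corneaRadius - spec@peripheralBand / 2
  rows <- rbind(
    data.frame(region = "central", quadrant = q,
               cx_um = spec@center[1] + rCen * cos(ang),
               cy_um = spec@center[2] + rCen * sin(ang)),
    data.frame(region = "peripheral", quadrant = q,
               cx_um = spec@center[1] + rPer * cos(ang),
               cy_um = spec@center[2] + rPer * sin(ang)))
  rows$w_um <- roiSizeUm
  rows$h_um <- roiSizeUm
  rows
}

#' Classify a point as central, peripheral, or neither
#'
#' @param x,y coordinates in um (vectorized).
#' @param spec a [RegionSpec-class].
#' @return character vector: "central", "peripheral" or NA (excluded
#'   mid-zone).
#' @examples
#' sp <- regionSpec()
#' classifyRegion(1000, 0, sp)   # central
#' classifyRegion(1380, 0, sp)   # peripheral
#' classifyRegion(1300, 0, sp)   # NA: neither zone
#' @export
classifyRegion <- function(x, y, spec) {
  stopifnot(is(spec, "RegionSpec"))
  r <- sqrt((x - spec@center[1])^2 + (y - spec@center[2])^2)
  out <- rep(NA_character_, length(r))
  out[r <= spec@centralRadius] <- "central"
  out[r > spec@corneaRadius - spec@peripheralBand &
      r <= spec@corneaRadius] <- "peripheral"
  out
}

#' Average per-region measurements
#'
#' The four central and four peripheral field measurements are averaged
#' separately, yielding one central and one peripheral value per cornea.
#'
#' @param values numeric vector of per-field measurements.
#' @param regions character vector ("central"/"peripheral") parallel to
#'   \code{values}.
#' @return named numeric (central, peripheral).
#' @export
averageRegions <- function(values, regions) {
  c(central = mean(values[regions == "central"]),
    peripheral = mean(values[regions == "peripheral"]))
}
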