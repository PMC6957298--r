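#' Detection parameters for two-channel panoramas
#'
#' @param bpSigmaUm band-pass small sigma (spot scale), um.
#' @param bpBackgroundUm band-pass large sigma (background scale), um.
#' @param pairingRadiusUm cross-channel matching radius for double-labeled
#'   (yellow) cells, um (~half a cell radius).
#' @param dupRadiusUm duplicate-suppression radius within a channel, um.
#' @param maxAspect connected components more elongated than this
#'   (major/minor axis ratio) are rejected as epithelial bleed-through
#'   streaks.
#' @param minAreaPx minimum component area in pixels.
#' @param relFloor classification thresholds are never below this fraction
#'   of the brightest detected spot (guards the degenerate single-color
#'   case where Otsu has no second mode).
#' @return list of parameters.
#' @export
detectionParams <- function(bpSigmaUm = 4, bpBackgroundUm = 20,
                            pairingRadiusUm = 5, dupRadiusUm = 8,
                            maxAspect = 5, minAreaPx = 3, relFloor = 0.25) {
  list(bpSigmaUm = bpSigmaUm, bpBackgroundUm = bpBackgroundUm,
       pairingRadiusUm = pairingRadiusUm, dupRadiusUm = dupRadiusUm,
       maxAspect = maxAspect, minAreaPx = minAreaPx, relFloor = relFloor)
}

# Band-pass filter, streak rejection and local-maximum extraction for one
# channel. Returns a data.frame of candidate spot centers (um) with their
# filtered peak intensity.
detectChannelSpots <- function(m, pixelScale, origin, params) {
  if (diff(range(m)) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(m),
                                 sigma = max(params$bpSigmaUm / pixelScale,
                                             0.5)))
  bg <- as.matrix(EBImage::gblur(EBImage::Image(m),
                                 sigma = params$bpBackgroundUm / pixelScale))
  bp <- pmax(sm - bg, 0)
  rng <- max(bp)
  if (rng <= 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  thr <- EBImage::otsu(EBImage::Image(bp / rng), range = c(0, 1)) * rng
  mask <- bp > thr
  compLab <- EBImage::bwlabel(EBImage::Image(mask))
  ncomp <- max(compLab)
  if (ncomp == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  feat <- EBImage::computeFeatures.moment(compLab, bp)
  shp <- EBImage::computeFeatures.shape(compLab)
  major <- feat[, "m.majoraxis"]
  ecc <- feat[, "m.eccentricity"]
  minor <- major * sqrt(pmax(1 - ecc^2, 1e-6))
  aspect <- major / pmax(minor, 1e-6)
  okComp <- which(shp[, "s.area"] >= params$minAreaPx &
                  aspect <= params$maxAspect)
  if (!length(okComp))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  lab <- as.matrix(EBImage::imageData(compLab))
  keepMask <- matrix(lab %in% okComp, nrow(lab), ncol(lab))

  # local maxima of the band-passed signal inside surviving components
  r <- max(1L, round(params$bpSigmaUm / pixelScale))
  nx <- nrow(bp); ny <- ncol(bp)
  shifts <- expand.grid(dx = -r:r, dy = -r:r)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  isMax <- keepMask & (bp > thr)
  for (k in seq_len(nrow(shifts))) {
    dx <- shifts$dx[k]; dy <- shifts$dy[k]
    sh <- matrix(-Inf, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    sh[xs, ys] <- bp[xs - dx, ys - dy]
    isMax <- isMax & (bp >= sh)
    if (!any(isMax)) break
  }
  idx <- which(isMax)
  if (!length(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  ix <- ((idx - 1) %% nx) + 1
  iy <- ((idx - 1) %/% nx) + 1
  # subpixel refinement: intensity-weighted centroid in a (2r+1)^2 patch
  cx <- cy <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xs <- max(1, ix[k] - r):min(nx, ix[k] + r)
    ys <- max(1, iy[k] - r):min(ny, iy[k] + r)
    w <- bp[xs, ys]
    cx[k] <- sum(outer(xs, rep(1, length(ys))) * w) / sum(w)
    cy[k] <- sum(outer(rep(1, length(xs)), ys) * w) / sum(w)
  }
  spotsDf <- data.frame(
    x_um = pxIndexToUm(cx, origin[1], pixelScale),
    y_um = pxIndexToUm(cy, origin[2], pixelScale),
    intensity = bp[idx])
  # duplicate suppression: keep the brighter of any pair closer than dupRadius
  o <- order(-spotsDf$intensity)
  spotsDf <- spotsDf[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(spotsDf))
  for (k in seq_len(nrow(spotsDf))) {
    if (!keep[k]) next
    if (k < nrow(spotsDf)) {
      later <- (k + 1):nrow(spotsDf)
      d <- sqrt((spotsDf$x_um[later] - spotsDf$x_um[k])^2 +
                (spotsDf$y_um[later] - spotsDf$y_um[k])^2)
      keep[later][d < params$dupRadiusUm] <- FALSE
    }
  }
  out <- spotsDf[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and classify labeled cells in a two-channel panorama
#'
#' Per-channel band-pass filtering (difference of Gaussians), Otsu
#' thresholding, rejection of elongated bleed-through streaks, and
#' local-maximum spot detection with duplicate suppression; red and green
#' maxima closer than the pairing radius are merged into one double-labeled
#' detection. Each detection is classified red / green / yellow by
#' [classifyColor()] with per-channel Otsu thresholds computed on the
#' detected-spot intensities.
#'
#' @param channels list with matrices \code{red} and \code{green} (equal
#'   dimensions) as produced by [renderChannels()], plus \code{pixelScale}
#'   and optionally \code{window}.
#' @param pixelScale um/px; defaults to \code{channels$pixelScale}.
#' @param params from [detectionParams()].
#' @return a [LabeledCellSet-class].
#' @export
detectLabeledCells <- function(channels, pixelScale = NULL,
                               params = detectionParams()) {
  red <- as.matrix(channels$red)
  green <- as.matrix(channels$green)
  if (!all(dim(red) == dim(green)))
    stop("channel dimensions differ")
  if (is.null(pixelScale)) pixelScale <- channels$pixelScale
  if (is.null(pixelScale)) stop("pixelScale is required")
  window <- channels$window
  if (is.null(window)) window <- c(0, nrow(red) * pixelScale,
                                   0, ncol(red) * pixelScale)
  if (max(red) >= 0.999 * 65535 || max(green) >= 0.999 * 65535)
    warning("channel appears saturated; proceeding")
  origin <- window[c(1, 3)]

  empty <- function() new("LabeledCellSet",
    detections = data.frame(id = integer(0), x_um = numeric(0),
                            y_um = numeric(0), red_int = numeric(0),
                            green_int = numeric(0), class = character(0),
                            stringsAsFactors = FALSE),
    pixelScale = pixelScale, thresholds = c(red = Inf, green = Inf),
    source = "detectLabeledCells")

  rs <- detectChannelSpots(red, pixelScale, origin, params)
  gs <- detectChannelSpots(green, pixelScale, origin, params)
  if (nrow(rs) + nrow(gs) == 0) return(empty())

  sampleAt <- function(m, x, y) {
    ix <- pmin(pmax(umToPxIndex(x, origin[1], pixelScale), 1L), nrow(m))
    iy <- pmin(pmax(umToPxIndex(y, origin[2], pixelScale), 1L), ncol(m))
    m[cbind(ix, iy)]
  }

  # cross-channel pairing: greedy nearest pairs within the pairing radius
  pairedR <- rep(FALSE, nrow(rs))
  pairedG <- rep(FALSE, nrow(gs))
  det <- list()
  if (nrow(rs) && nrow(gs)) {
    d <- crossDist(rs[, c("x_um", "y_um")], gs[, c("x_um", "y_um")])
    cand <- which(d <= params$pairingRadiusUm, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (pairedR[i] || pairedG[j]) next
        pairedR[i] <- TRUE; pairedG[j] <- TRUE
        det[[length(det) + 1]] <- data.frame(
          x_um = (rs$x_um[i] + gs$x_um[j]) / 2,
          y_um = (rs$y_um[i] + gs$y_um[j]) / 2,
          red_int = rs$intensity[i], green_int = gs$intensity[j])
      }
    }
  }
  if (any(!pairedR)) {
    i <- which(!pairedR)
    det[[length(det) + 1]] <- data.frame(
      x_um = rs$x_um[i], y_um = rs$y_um[i], red_int = rs$intensity[i],
      green_int = sampleAt(green, rs$x_um[i], rs$y_um[i]))
  }
  if (any(!pairedG)) {
    j <- which(!pairedG)
    det[[length(det) + 1]] <- data.frame(
      x_um = gs$x_um[j], y_um = gs$y_um[j],
      red_int = sampleAt(red, gs$x_um[j], gs$y_um[j]),
      green_int = gs$intensity[j])
  }
  det <- do.call(rbind, det)

  # classification thresholds: per-channel Otsu over detected-spot
  # intensities, floored at relFloor of the global spot maximum
  thr <- c(red = otsuThreshold(det$red_int),
           green = otsuThreshold(det$green_int))
  floorv <- params$relFloor * max(det$red_int, det$green_int)
  thr <- pmax(thr, floorv)
  cls <- classifyColor(det$red_int, det$green_int, thr[["red"]],
                       thr[["green"]])
  keep <- cls != "none"
  det <- det[keep, , drop = FALSE]
  cls <- cls[keep]
  o <- order(det$x_um, det$y_um)
  det <- det[o, , drop = FALSE]
  out <- data.frame(id = seq_len(nrow(det)), x_um = det$x_um,
                    y_um = det$y_um, red_int = det$red_int,
                    green_int = det$green_int, class = cls[o],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("LabeledCellSet", detections = out, pixelScale = pixelScale,
      thresholds = thr, source = "detectLabeledCells")
}

# 1-D Otsu threshold on a numeric vector (maximize between-class variance
# over a 256-bin histogram).
otsuThreshold <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(Inf)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[256]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Classify a detection by its channel intensities
#'
#' Both channels above their thresholds: yellow (double-labeled); exactly
#' one above: that color; neither: "none" (not a labeled cell).
#'
#' @param redInt,greenInt non-negative intensities (vectorized).
#' @param redThr,greenThr channel thresholds.
#' @return character vector in \{red, green, yellow, none\}.
#' @examples
#' classifyColor(1000, 10, 100, 100)   # red
#' classifyColor(800, 900, 100, 100)   # yellow
#' classifyColor(50, 50, 100, 100)     # none
#' @export
classifyColor <- function(redInt, greenInt, redThr, greenThr) {
  if (any(redInt < 0) || any(greenInt < 0))
    stop("intensities must be non-negative")
  r <- redInt > redThr
  g <- greenInt > greenThr
  out <- rep("none", length(r))
  out[r & g] <- "yellow"
  out[r & !g] <- "red"
  out[!r & g] <- "green"
  out
}
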