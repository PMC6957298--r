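# Rendering of simulated monolayers into images.
#
# Images are plain numeric matrices indexed [ix, iy] with pixel indices
# 0-based in the coordinate convention (x right, y down in image terms):
# x_um = window[1] + (ix - 0.5) * pixelScale for 1-based R index ix, i.e.
# the 0-based pixel k covers [window[1] + k*scale, window[1] + (k+1)*scale).

umToPxIndex <- function(um, origin, scale) floor((um - origin) / scale) + 1L

pxIndexToUm <- function(ix, origin, scale) origin + (ix - 0.5) * scale

# stamp a unit-amplitude Gaussian at (cx, cy) (um) into image m
stampGaussian <- function(m, cx, cy, sigmaUm, origin, scale, amplitude = 1) {
  sPx <- sigmaUm / scale
  r <- ceiling(4 * sPx)
  icx <- (cx - origin[1]) / scale + 0.5   # fractional 1-based index
  icy <- (cy - origin[2]) / scale + 0.5
  ix <- max(1, floor(icx) - r):min(nrow(m), ceiling(icx) + r)
  iy <- max(1, floor(icy) - r):min(ncol(m), ceiling(icy) + r)
  if (!length(ix) || !length(iy)) return(m)
  gx <- exp(-((ix - icx)^2) / (2 * sPx^2))
  gy <- exp(-((iy - icy)^2) / (2 * sPx^2))
  m[ix, iy] <- m[ix, iy] + amplitude * outer(gx, gy)
  m
}

#' Render a two-channel fluorescence panorama
#'
#' Renders every labeled cell of a mosaic as a Gaussian spot: red cells into
#' the red channel, green into the green channel, yellow (double-labeled)
#' into both at the same location. Optional background offset, Poisson
#' photon noise and green radial streak artifacts (bleed-through from the
#' epithelial layer of an undulating flat-mount) follow the configuration's
#' \code{noise} settings.
#'
#' @param object a [SimulatedMonolayer-class], or a data.frame with columns
#'   \code{x_um}, \code{y_um}, \code{color}.
#' @param config a [SimulationConfig-class] (defaults to the monolayer's).
#' @param window field of view \code{c(xmin, xmax, ymin, ymax)} in um;
#'   default covers the cornea disc plus a margin.
#' @return list with matrices \code{red} and \code{green}, \code{pixelScale}
#'   (um/px) and \code{window}.
#' @examples
#' cfg <- madmPreset("WT", seed = 3, corneaRadius = 400,
#'                   targetDensity = 1500, nEvents = 4, eventMinSpacing = 150)
#' mono <- simulateMadm(cfg, generatePositions(cfg))
#' ch <- renderChannels(mono)
#' dim(ch$red)
#' @export
renderChannels <- function(object, config = NULL, window = NULL) {
  if (is(object, "SimulatedMonolayer")) {
    if (is.null(config)) config <- object@config
    tab <- object@cells
  } else {
    tab <- object
    if (is.null(config)) stop("config is required for a plain cell table")
  }
  scale <- config@pixelScale
  if (scale <= 0) stop("pixelScale must be > 0")
  if (is.null(window)) {
    pad <- 4 * config@spotSigma
    Rp <- config@corneaRadius + pad
    window <- c(-Rp, Rp, -Rp, Rp)
  }
  lab <- tab[tab$color %in% c("red", "green", "yellow"), , drop = FALSE]
  if (nrow(lab)) {
    inx <- lab$x_um >= window[1] & lab$x_um <= window[2] &
           lab$y_um >= window[3] & lab$y_um <= window[4]
    if (!all(inx))
      stop("field too small: labeled cells fall outside the window")
  }
  nx <- ceiling((window[2] - window[1]) / scale)
  ny <- ceiling((window[4] - window[3]) / scale)
  red <- matrix(0, nx, ny)
  green <- matrix(0, nx, ny)
  origin <- window[c(1, 3)]
  for (i in seq_len(nrow(lab))) {
    col <- lab$color[i]
    if (col %in% c("red", "yellow"))
      red <- stampGaussian(red, lab$x_um[i], lab$y_um[i], config@spotSigma,
                           origin, scale)
    if (col %in% c("green", "yellow"))
      green <- stampGaussian(green, lab$x_um[i], lab$y_um[i],
                             config@spotSigma, origin, scale)
  }

  noise <- config@noise
  set.seed(stageSeed(config, "channels"))
  if (isTRUE(noise$streaks) && noise$nStreaks > 0) {
    R <- config@corneaRadius
    for (s in seq_len(noise$nStreaks)) {
      ang <- stats::runif(1, 0, 2 * pi)
      r0 <- stats::runif(1, 0.1, 0.4) * R
      r1 <- stats::runif(1, 0.7, 1.0) * R
      along <- seq(r0, r1, by = scale / 2)
      sx <- along * cos(ang); sy <- along * sin(ang)
      keep <- sx >= window[1] & sx <= window[2] &
              sy >= window[3] & sy <= window[4]
      for (k in which(keep))
        green <- stampGaussian(green, sx[k], sy[k], 1.5 * scale,
                               origin, scale, amplitude = 0.12)
    }
  }
  bg <- noise$background
  if (bg > 0) { red <- red + bg; green <- green + bg }
  if (isTRUE(noise$poisson)) {
    photons <- 200
    red <- matrix(stats::rpois(length(red), pmax(red, 0) * photons) / photons,
                  nx, ny)
    green <- matrix(stats::rpois(length(green), pmax(green, 0) * photons) /
                    photons, nx, ny)
  }
  list(red = red, green = green, pixelScale = scale, window = window)
}

#' Render a junction-label (boundary) image
#'
#' Draws bright ridges of finite width along the Dirichlet-tessellation
#' edges of the cell positions (the apical junction lattice a ZO-1-like
#' stain reveals), with dark cell interiors. The window border is drawn as
#' a ridge so every cell, including clipped border cells, is an enclosed
#' face. Ground truth (tile areas and seed coordinates) is attached as
#' attributes for recovery benchmarking.
#'
#' @param positions n x 2 matrix of cell centers in um (n >= 3), e.g. from
#'   [generatePositions()].
#' @param config a [SimulationConfig-class]; \code{junctionPixelScale} and
#'   \code{noise} are used.
#' @param window \code{c(xmin, xmax, ymin, ymax)} um; defaults to the
#'   positions' generating field.
#' @param ridgeSigmaUm Gaussian ridge half-width, um.
#' @return numeric matrix in [0, 1] with attributes \code{pixelScale},
#'   \code{window}, \code{truthAreas} (um^2), \code{truthSeeds} (um).
#' @export
renderJunctions <- function(positions, config, window = NULL,
                            ridgeSigmaUm = 0.8) {
  if (is.null(nrow(positions)) || nrow(positions) < 3)
    stop("at least 3 positions are required")
  scale <- config@junctionPixelScale
  if (is.null(window)) {
    shp <- attr(positions, "shape")
    if (identical(shp, "rect"))
      window <- c(0, attr(positions, "width"), 0, attr(positions, "height"))
    else if (identical(shp, "disc")) {
      R <- attr(positions, "corneaRadius")
      window <- c(-R, R, -R, R)
    } else {
      window <- c(range(positions[, 1]), range(positions[, 2]))
      pad <- 0.02 * max(diff(window[1:2]), diff(window[3:4]))
      window <- window + c(-pad, pad, -pad, pad)
    }
  }
  nx <- ceiling((window[2] - window[1]) / scale)
  ny <- ceiling((window[4] - window[3]) / scale)
  dd <- deldir::deldir(positions[, 1], positions[, 2],
                       rw = window[c(1, 2, 3, 4)])
  segs <- dd$dirsgs
  mask <- matrix(0, nx, ny)
  rasterSeg <- function(mask, x1, y1, x2, y2) {
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    nsamp <- max(2L, ceiling(len / (scale / 4)))
    t <- seq(0, 1, length.out = nsamp)
    ix <- pmin(pmax(umToPxIndex(x1 + t * (x2 - x1), window[1], scale), 1L), nx)
    iy <- pmin(pmax(umToPxIndex(y1 + t * (y2 - y1), window[3], scale), 1L), ny)
    mask[cbind(ix, iy)] <- 1
    mask
  }
  for (k in seq_len(nrow(segs)))
    mask <- rasterSeg(mask, segs$x1[k], segs$y1[k], segs$x2[k], segs$y2[k])
  # window border closes the clipped border cells
  mask[c(1, nx), ] <- 1
  mask[, c(1, ny)] <- 1
  img <- as.matrix(EBImage::gblur(EBImage::Image(mask),
                                  sigma = max(ridgeSigmaUm / scale, 0.5)))
  if (max(img) > 0) img <- img / max(img)
  noise <- config@noise
  set.seed(stageSeed(config, "junctions"))
  if (noise$background > 0) img <- img + noise$background
  if (isTRUE(noise$poisson)) {
    photons <- 400
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * photons) / photons,
                  nx, ny)
  }
  tiles <- deldir::tile.list(dd)
  attr(img, "pixelScale") <- scale
  attr(img, "window") <- window
  attr(img, "truthAreas") <- vapply(tiles, function(t)
    polygonArea(cbind(t$x, t$y)), numeric(1))
  attr(img, "truthSeeds") <- cbind(x = positions[, 1], y = positions[, 2])
  img
}

#' Crop a rendered field to a region of interest
#'
#' Extracts a rectangular ROI from a junction image (or any rendered
#' matrix carrying \code{pixelScale}/\code{window} attributes), preserving
#' the physical coordinate mapping. Cells straddling the new border become
#' genuine partial cells, as when a microscope field samples a larger
#' tissue.
#'
#' @param img matrix with \code{pixelScale} and \code{window} attributes.
#' @param window target \code{c(xmin, xmax, ymin, ymax)} in um; must lie
#'   inside the image window.
#' @return cropped matrix with updated attributes.
#' @export
cropField <- function(img, window) {
  scale <- attr(img, "pixelScale")
  w0 <- attr(img, "window")
  if (is.null(scale) || is.null(w0))
    stop("img must carry pixelScale and window attributes")
  if (window[1] < w0[1] || window[2] > w0[2] ||
      window[3] < w0[3] || window[4] > w0[4])
    stop("crop window must lie inside the image window")
  ix <- (umToPxIndex(window[1], w0[1], scale)):(umToPxIndex(window[2], w0[1], scale) - 1L)
  iy <- (umToPxIndex(window[3], w0[3], scale)):(umToPxIndex(window[4], w0[3], scale) - 1L)
  ix <- ix[ix >= 1 & ix <= nrow(img)]
  iy <- iy[iy >= 1 & iy <= ncol(img)]
  out <- img[ix, iy]
  attr(out, "pixelScale") <- scale
  attr(out, "window") <- c(w0[1] + (ix[1] - 1) * scale,
                           w0[1] + ix[length(ix)] * scale,
                           w0[3] + (iy[1] - 1) * scale,
                           w0[3] + iy[length(iy)] * scale)
  out
}
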