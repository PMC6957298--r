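#' Simulate MADM recombination events on a monolayer
#'
#' Converts a background point set into a ground-truth mosaic. Each event
#' draws a segregation mode from \code{segProbs}:
#' \itemize{
#'   \item G2-X: one red and one green founding sibling at adjacent
#'     positions. In GR-MADM mode the green founder is homozygous mutant
#'     (MUT) and the red founder homozygous wild-type (WT); in WT-MADM both
#'     are WT.
#'   \item G2-Z: one yellow and one colorless daughter, both heterozygous.
#'   \item G0/G1: a single yellow heterozygous cell.
#' }
#' Single-labeled founders expand into clones whose size is drawn as
#' \code{1 + Poisson(cloneBaseMean * fold[genotype] - 1)} (mean exactly
#' \code{cloneBaseMean * fold}, minimum 1). Clone members are laid out as a
#' random walk from the founder with per-division isotropic Gaussian steps
#' of scale \code{dispersalSigma[genotype]}, reflected at the cornea
#' boundary. Because cells occupy space in a monolayer, a placement closer
#' than ~80% of the mean cell spacing to any previously placed labeled cell
#' is resampled (hard-core exclusion). Remaining background positions
#' become colorless cells.
#'
#' @param config a [SimulationConfig-class].
#' @param positions point set from [generatePositions()] (disc shape).
#' @return a [SimulatedMonolayer-class].
#' @examples
#' cfg <- madmPreset("WT", seed = 2, corneaRadius = 800, targetDensity = 1500)
#' mono <- simulateMadm(cfg, generatePositions(cfg))
#' head(cells(mono))
#' @export
simulateMadm <- function(config, positions) {
  stopifnot(is(config, "SimulationConfig"))
  if (abs(sum(config@segProbs) - 1) > 1e-9)
    stop("segProbs must sum to 1")
  n <- nrow(positions)
  if (is.null(n) || n == 0) stop("positions must be non-empty")
  nEvents <- as.integer(config@nEvents)
  if (nEvents > n / 4)
    stop("nEvents must be small relative to the number of cells")
  set.seed(stageSeed(config, "madm"))
  R <- config@corneaRadius

  # --- event anchors: random positions subject to a minimum spacing -------
  anchors <- integer(0)
  if (nEvents > 0) {
    cand <- sample.int(n)
    for (i in cand) {
      if (length(anchors) == nEvents) break
      if (length(anchors) == 0) { anchors <- i; next }
      d <- sqrt((positions[anchors, 1] - positions[i, 1])^2 +
                (positions[anchors, 2] - positions[i, 2])^2)
      if (all(d >= config@eventMinSpacing)) anchors <- c(anchors, i)
    }
    if (length(anchors) < nEvents)
      stop("could not place ", nEvents, " events at spacing ",
           config@eventMinSpacing, " um; reduce nEvents or spacing")
  }

  # nearest free position to each anchor hosts the second daughter
  used <- rep(FALSE, n)
  used[anchors] <- TRUE
  nearestFree <- function(i) {
    d <- sqrt((positions[, 1] - positions[i, 1])^2 +
              (positions[, 2] - positions[i, 2])^2)
    d[used] <- Inf
    which.min(d)
  }

  modes <- if (nEvents > 0)
    sample(c("g2x", "g2z", "g0g1"), nEvents, replace = TRUE,
           prob = config@segProbs[c("g2x", "g2z", "g0g1")])
  else character(0)

  hetGeno <- if (config@mode == "GR") "HET" else "WT"
  rows <- vector("list", 2 * nEvents + 1)
  cloneId <- 0L

  # hard-core exclusion radius between labeled cells (cells fill space);
  # inactive for dispersalSigma = 0, where members stack on the founder
  densUm2 <- n / (pi * R^2)
  minSep <- 0.8 / sqrt(densUm2)
  placed <- matrix(numeric(0), 0, 2)

  growClone <- function(founderXY, genotype, color, eventId) {
    cloneId <<- cloneId + 1L
    fold <- config@expansionFold[[genotype]]
    lam <- config@cloneBaseMean * fold - 1
    size <- 1L + stats::rpois(1, lam)
    sig <- config@dispersalSigma[[genotype]]
    cur <- as.numeric(founderXY)
    xy <- matrix(cur, nrow = 1)
    placed <<- rbind(placed, xy)
    if (size > 1) for (k in 2:size) {
      best <- cur; bestd <- -Inf
      for (try in 1:60) {
        cand <- cur + stats::rnorm(2, sd = sig)
        cand <- as.numeric(reflectIntoDisc(matrix(cand, 1), R))
        dmin <- if (sig > 0)
          min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2))
        else Inf
        if (dmin >= minSep) { best <- cand; break }
        if (dmin > bestd) { bestd <- dmin; best <- cand }
      }
      cur <- best
      xy <- rbind(xy, cur)
      placed <<- rbind(placed, matrix(cur, 1))
    }
    data.frame(x_um = xy[, 1], y_um = xy[, 2], color = color,
               clone_id = cloneId, event_id = eventId, genotype = genotype,
               stringsAsFactors = FALSE)
  }

  for (e in seq_len(nEvents)) {
    a <- anchors[e]
    if (modes[e] == "g2x") {
      b <- nearestFree(a)
      used[b] <- TRUE
      redGeno <- "WT"
      greenGeno <- if (config@mode == "GR") "MUT" else "WT"
      rows[[2 * e - 1]] <- growClone(positions[a, ], redGeno, "red", e)
      rows[[2 * e]] <- growClone(positions[b, ], greenGeno, "green", e)
    } else if (modes[e] == "g2z") {
      b <- nearestFree(a)
      used[b] <- TRUE
      rows[[2 * e - 1]] <- data.frame(
        x_um = positions[a, 1], y_um = positions[a, 2], color = "yellow",
        clone_id = NA_integer_, event_id = e, genotype = hetGeno,
        stringsAsFactors = FALSE)
      rows[[2 * e]] <- data.frame(
        x_um = positions[b, 1], y_um = positions[b, 2], color = "colorless",
        clone_id = NA_integer_, event_id = e, genotype = hetGeno,
        stringsAsFactors = FALSE)
    } else {
      rows[[2 * e - 1]] <- data.frame(
        x_um = positions[a, 1], y_um = positions[a, 2], color = "yellow",
        clone_id = NA_integer_, event_id = e, genotype = hetGeno,
        stringsAsFactors = FALSE)
    }
  }

  bg <- which(!used)
  rows[[2 * nEvents + 1]] <- if (length(bg)) data.frame(
    x_um = positions[bg, 1], y_um = positions[bg, 2], color = "colorless",
    clone_id = NA_integer_, event_id = NA_integer_, genotype = hetGeno,
    stringsAsFactors = FALSE) else NULL

  cl <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  cl <- cbind(id = seq_len(nrow(cl)), cl)
  rownames(cl) <- NULL
  new("SimulatedMonolayer", cells = cl, config = config,
      provenance = list(seed = config@seed,
                        generator = paste0("corneaMADM ",
                                           utils::packageVersion("corneaMADM"))))
}

#' Ground-truth labeled cells as a detection set
#'
#' Converts the labeled (red/green/yellow) cells of a simulated monolayer
#' into a [LabeledCellSet-class], bypassing rendering and detection. Used to
#' analyse the generator's truth table with the same twin-spot and
#' clustering machinery applied to image-derived detections.
#'
#' @param mono a [SimulatedMonolayer-class].
#' @return a [LabeledCellSet-class] with unit intensities.
#' @export
asLabeledCellSet <- function(mono) {
  stopifnot(is(mono, "SimulatedMonolayer"))
  cl <- mono@cells
  lab <- cl[cl$color %in% c("red", "green", "yellow"), , drop = FALSE]
  det <- data.frame(
    id = lab$id, x_um = lab$x_um, y_um = lab$y_um,
    red_int = as.numeric(lab$color %in% c("red", "yellow")),
    green_int = as.numeric(lab$color %in% c("green", "yellow")),
    class = lab$color, stringsAsFactors = FALSE)
  rownames(det) <- NULL
  new("LabeledCellSet", detections = det,
      pixelScale = mono@config@pixelScale,
      thresholds = c(red = 0.5, green = 0.5),
      source = "ground-truth")
}
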