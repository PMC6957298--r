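#' Find twin spots among single-labeled cells
#'
#' A twin spot is the spatially coherent group of red and green cells
#' descending from one G2-X recombination event. Groups are formed by
#' single-linkage connected components over single-labeled (red/green)
#' cells, linking any pair closer than the grouping radius; components
#' containing at least one red and at least one green member are twin-spot
#' candidates. A candidate is accepted when it is isolated: every
#' non-member single-labeled cell lies farther than the isolation distance
#' from every member (automatic when the isolation distance does not exceed
#' the grouping radius). Components wider than the overlap-flag diameter
#' are retained but flagged as possible mergers of two events.
#'
#' Yellow (double-labeled) cells are never twin-spot members.
#'
#' @param cellSet a [LabeledCellSet-class] with classified detections.
#' @param params from [twinSpotParams()].
#' @return a [TwinSpotSet-class].
#' @examples
#' det <- data.frame(id = 1:2, x_um = c(0, 50), y_um = c(0, 0),
#'                   red_int = c(1, 0), green_int = c(0, 1),
#'                   class = c("red", "green"))
#' cs <- new("LabeledCellSet", detections = det, pixelScale = 3.02,
#'           thresholds = c(red = 0.5, green = 0.5), source = "example")
#' spots(findTwinSpots(cs))
#' @export
findTwinSpots <- function(cellSet, params = twinSpotParams()) {
  stopifnot(is(cellSet, "LabeledCellSet"))
  det <- cellSet@detections
  if (nrow(det) && any(!det$class %in% c("red", "green", "yellow")))
    stop("detections must be classified before twin-spot analysis")
  singles <- det[det$class %in% c("red", "green"), , drop = FALSE]
  emptySet <- function() new("TwinSpotSet",
    spots = data.frame(spot_id = integer(0), size = integer(0),
                       n_red = integer(0), n_green = integer(0),
                       centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                       diameter_um = numeric(0), flagged = logical(0)),
    members = list(), params = params)
  n <- nrow(singles)
  if (n == 0) return(emptySet())

  xy <- as.matrix(singles[, c("x_um", "y_um")])
  d <- crossDist(xy, xy)
  adj <- which(d <= params$groupRadiusUm & upper.tri(d), arr.ind = TRUE)
  comp <- unionFind(n, adj)
  compIds <- split(seq_len(n), comp)

  rows <- list()
  members <- list()
  for (g in compIds) {
    nRed <- sum(singles$class[g] == "red")
    nGreen <- sum(singles$class[g] == "green")
    if (nRed < 1 || nGreen < 1) next
    others <- setdiff(seq_len(n), g)
    if (length(others)) {
      minOut <- min(d[g, others])
      if (minOut <= params$isolationUm) next
    }
    diam <- if (length(g) > 1) max(d[g, g]) else 0
    rows[[length(rows) + 1]] <- data.frame(
      size = length(g), n_red = nRed, n_green = nGreen,
      centroid_x_um = mean(xy[g, 1]), centroid_y_um = mean(xy[g, 2]),
      diameter_um = diam,
      flagged = diam > params$overlapFlagDiameterUm)
    members[[length(members) + 1]] <- singles$id[g]
  }
  if (!length(rows)) return(emptySet())
  sp <- do.call(rbind, rows)
  o <- order(sp$centroid_x_um, sp$centroid_y_um)
  sp <- sp[o, , drop = FALSE]
  members <- members[o]
  sp <- cbind(spot_id = seq_len(nrow(sp)), sp)
  rownames(sp) <- NULL
  new("TwinSpotSet", spots = sp, members = members, params = params)
}

#' Summarize a set of twin spots
#'
#' @param spotSet a [TwinSpotSet-class].
#' @param includeFlagged include overlap-flagged spots in the summary
#'   (default FALSE: flagged spots are separable, mirroring the exclusion
#'   of possibly overlapping clones).
#' @return list: \code{nSpots}, \code{sizeHist} (table over sizes),
#'   \code{frac2to4} (fraction of spots with 2-4 cells),
#'   \code{perSpotRatio} (green/red per spot; NA when a spot has no red),
#'   \code{pooledRatio} (sum green / sum red), \code{greenFraction}
#'   (pooled green / (green + red)), \code{meanSize}.
#' @examples
#' # sizes 2,2,3,4,8 -> fraction of 2-4-cell spots is 0.8
#' @export
twinSpotStats <- function(spotSet, includeFlagged = FALSE) {
  stopifnot(is(spotSet, "TwinSpotSet"))
  s <- spotSet@spots
  if (!includeFlagged) s <- s[!s$flagged, , drop = FALSE]
  if (nrow(s) == 0)
    return(list(nSpots = 0L, sizeHist = table(integer(0)),
                frac2to4 = NA_real_, perSpotRatio = numeric(0),
                pooledRatio = NA_real_, greenFraction = NA_real_,
                meanSize = NA_real_))
  list(nSpots = nrow(s),
       sizeHist = table(s$size),
       frac2to4 = mean(s$size >= 2 & s$size <= 4),
       perSpotRatio = ifelse(s$n_red > 0, s$n_green / s$n_red, NA_real_),
       pooledRatio = if (sum(s$n_red) > 0) sum(s$n_green) / sum(s$n_red)
                     else NA_real_,
       greenFraction = sum(s$n_green) / sum(s$n_green + s$n_red),
       meanSize = mean(s$size))
}
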