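#' Default pixel scale of the two-channel panoramas
#'
#' Fixed by equating 82 px to 248 um: 248/82 = 3.02439 um/px. All pixel/um
#' conversions in the package default to this scale.
#' @export
DEFAULT_PIXEL_SCALE <- 248 / 82

#' Convert pixels to micrometers (and back)
#'
#' @param px length in pixels.
#' @param scale micrometers per pixel (default 248/82).
#' @return length in micrometers.
#' @examples
#' pxToUm(45)  # the cluster radius: 45 px = 136 um
#' pxToUm(82)  # the twin-spot grouping radius: 82 px = 248 um
#' @export
pxToUm <- function(px, scale = DEFAULT_PIXEL_SCALE) px * scale

#' @rdname pxToUm
#' @param um length in micrometers.
#' @export
umToPx <- function(um, scale = DEFAULT_PIXEL_SCALE) um / scale

#' Build a simulation configuration
#'
#' Constructor for [SimulationConfig-class]. Defaults describe a wild-type
#' (WT-MADM) adult mouse cornea: a 1500-um-radius disc at 2500 cells/mm^2
#' with rare, widely spaced recombination events, most of which are
#' yellow-producing (G2-Z or G0/G1) so that single-labeled cells are the
#' minority, as observed in flat-mounted corneas.
#'
#' @param corneaRadius cornea disc radius, um.
#' @param targetDensity target cell density, cells/mm^2.
#' @param nEvents number of recombination events.
#' @param segProbs named probabilities (g2x, g2z, g0g1), must sum to 1.
#' @param expansionFold named clone-size fold (WT, MUT) relative to the
#'   wild-type baseline.
#' @param cloneBaseMean expected wild-type single-labeled clone size.
#' @param dispersalSigma named per-division displacement scale (WT, MUT), um.
#' @param eventMinSpacing minimum spacing between event anchors, um.
#' @param mode "WT" (WT-MADM) or "GR" (GR-MADM).
#' @param pixelScale panorama pixel scale, um/px.
#' @param junctionPixelScale junction-image pixel scale, um/px.
#' @param spotSigma rendered spot sigma, um.
#' @param noise list(background, poisson, streaks, nStreaks).
#' @param lloydSteps Lloyd relaxation steps for the point process.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(corneaRadius = 1500,
                             targetDensity = 2500,
                             nEvents = 20,
                             segProbs = c(g2x = 0.25, g2z = 0.25, g0g1 = 0.5),
                             expansionFold = c(WT = 1, MUT = 1),
                             cloneBaseMean = 1.6,
                             dispersalSigma = c(WT = 25, MUT = 25),
                             eventMinSpacing = 400,
                             mode = c("WT", "GR"),
                             pixelScale = DEFAULT_PIXEL_SCALE,
                             junctionPixelScale = 1,
                             spotSigma = 6,
                             noise = list(background = 0.02, poisson = TRUE,
                                          streaks = FALSE, nStreaks = 6),
                             lloydSteps = 1,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(noise$nStreaks)) noise$nStreaks <- 6
  new("SimulationConfig",
      corneaRadius = corneaRadius, targetDensity = targetDensity,
      nEvents = nEvents, segProbs = segProbs[c("g2x", "g2z", "g0g1")],
      expansionFold = expansionFold, cloneBaseMean = cloneBaseMean,
      dispersalSigma = dispersalSigma, eventMinSpacing = eventMinSpacing,
      mode = mode, pixelScale = pixelScale,
      junctionPixelScale = junctionPixelScale, spotSigma = spotSigma,
      noise = noise, lloydSteps = lloydSteps, seed = as.numeric(seed))
}

#' Genotype presets for the mosaic experiments
#'
#' Three presets mirror the biological contrasts quantified by the pipeline:
#' \describe{
#'   \item{WT}{WT-MADM: both siblings wild-type, symmetric expansion
#'     (fold 1/1), moderate dispersal. Rare events.}
#'   \item{CK}{GR-MADM with a cyclin/CDK-binding-dead mutant: green (mutant)
#'     clones expand ~3-fold and scatter widely across the monolayer
#'     (high dispersal).}
#'   \item{KO}{GR-MADM with a null mutant: green clones expand ~6-fold and
#'     stay tightly packed at their site of production (low dispersal).}
#' }
#' Mutant mosaics carry more events than WT-MADM, matching the greater
#' abundance of single-labeled cells in those corneas.
#'
#' @param preset "WT", "CK" or "KO".
#' @param seed integer RNG seed.
#' @param ... overrides passed to [simulationConfig()].
#' @return a [SimulationConfig-class].
#' @examples
#' madmPreset("KO", seed = 7)
#' @export
madmPreset <- function(preset = c("WT", "CK", "KO"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    WT = list(mode = "WT",
              expansionFold = c(WT = 1, MUT = 1),
              dispersalSigma = c(WT = 25, MUT = 25),
              nEvents = 20),
    CK = list(mode = "GR",
              expansionFold = c(WT = 1, MUT = 3),
              dispersalSigma = c(WT = 25, MUT = 300),
              nEvents = 40, eventMinSpacing = 300),
    KO = list(mode = "GR",
              expansionFold = c(WT = 1, MUT = 6),
              dispersalSigma = c(WT = 25, MUT = 14),
              nEvents = 40, eventMinSpacing = 300))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(simulationConfig, args)
}

#' Clustering parameters for density-based dispersion analysis
#'
#' Defaults are the published operating point: eps = 45 px = 136 um at the
#' 248/82 um/px panorama scale, minimum density 4 (neighborhood occupancy
#' including the query point itself).
#'
#' @param epsUm neighborhood radius, um.
#' @param minDensity minimum number of points within eps (inclusive of the
#'   point itself) for a core point.
#' @param inclusive logical; if FALSE, minDensity is interpreted exclusive
#'   of the query point (classic convention).
#' @return list of class parameters.
#' @export
clusteringParams <- function(epsUm = pxToUm(45), minDensity = 4,
                             inclusive = TRUE) {
  stopifnot(epsUm > 0, minDensity >= 2)
  list(epsUm = epsUm, minDensity = minDensity, inclusive = inclusive)
}

#' Twin-spot grouping parameters
#'
#' Defaults are the published operating point: grouping radius 82 px =
#' 248 um, isolation distance 200 um; components wider than twice the
#' grouping radius are flagged as possible overlaps of two events.
#'
#' @param groupRadiusUm grouping (single-linkage) radius, um.
#' @param isolationUm minimum distance from any member to the nearest
#'   non-member single-labeled cell, um.
#' @param overlapFlagDiameterUm components with diameter above this are
#'   flagged, um.
#' @return list of parameters.
#' @export
twinSpotParams <- function(groupRadiusUm = pxToUm(82), isolationUm = 200,
                           overlapFlagDiameterUm = 2 * groupRadiusUm) {
  stopifnot(groupRadiusUm > 0, isolationUm > 0, overlapFlagDiameterUm > 0)
  list(groupRadiusUm = groupRadiusUm, isolationUm = isolationUm,
       overlapFlagDiameterUm = overlapFlagDiameterUm)
}

#' Regional sampling specification
#'
#' @param center cornea center (x, y) in um.
#' @param corneaRadius cornea radius, um.
#' @param centralRadius radius of the central zone, um.
#' @param peripheralBand width of the peripheral annulus, um.
#' @param nQuadrants number of quadrants.
#' @return a [RegionSpec-class].
#' @export
regionSpec <- function(center = c(0, 0), corneaRadius = 1500,
                       centralRadius = 1250, peripheralBand = 200,
                       nQuadrants = 4) {
  new("RegionSpec", center = center, corneaRadius = corneaRadius,
      centralRadius = centralRadius, peripheralBand = peripheralBand,
      nQuadrants = nQuadrants)
}
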