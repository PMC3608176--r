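#' Membrane frame derived from a structure
#'
#' PDB inputs carry no membrane, so a default frame is constructed from the
#' bundle itself: the normal is the mean of the seven helix axis directions
#' after sign alignment (axes alternate up/down through the membrane), and
#' the midplane passes through the centroid of all TM CA atoms.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param topology its \linkS4class{Topology}.
#' @return a \linkS4class{MembraneFrame}.
#' @export
membraneFrameFromStructure <- function(s, topology) {
  axes <- t(vapply(seq_len(7), function(i)
    fitHelixAxis(s, topology@tmRanges[i, ], i)@axis, numeric(3)))
  ref <- axes[1, ]
  signs <- ifelse(axes %*% ref >= 0, 1, -1)
  normal <- unitv(colSums(axes * as.vector(signs)))
  mid <- colMeans(caCoords(s, regionResidues(topology, "TM")))
  new("MembraneFrame", normal = normal, midplanePoint = mid)
}

#' Intersections of helix axes with the membrane midplane
#'
#' Each helix axis is extended as the line through its centroid and
#' intersected with the midplane.
#'
#' @param helices list of 7 \linkS4class{HelixSegment} objects (TM1..TM7).
#' @param frame a \linkS4class{MembraneFrame}.
#' @return 7x3 matrix of intersection points.
#' @export
membraneIntersections <- function(helices, frame) {
  if (length(helices) != 7L) stop("need exactly 7 helices")
  m <- frame@normal; p0 <- frame@midplanePoint
  t(vapply(seq_len(7), function(i) {
    h <- helices[[i]]
    denom <- sum(h@axis * m)
    if (abs(denom) <= 1e-6)
      stop("degenerate intersection: helix ", i,
           " axis is parallel to the membrane plane")
    tt <- sum((p0 - h@centroid) * m) / denom
    h@centroid + tt * h@axis
  }, numeric(3)))
}

#' Fanned triangle areas of the projected bundle
#'
#' O is the centroid of the seven intersection points; Si is the area of the
#' triangle (O, p_i, p_{i+1}) with p_8 = p_1, adjacency following sequence
#' order TM1..TM7.  Coincident points give zero areas (no error; the packing
#' term penalizes the collapsed bundle).
#'
#' @param points 7x3 matrix of midplane points (TM order).
#' @return a \linkS4class{PackingGeometry}.
#' @export
packingAreas <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 7L) stop("need exactly 7 points")
  O <- colMeans(points)
  areas <- vapply(seq_len(7), function(i) {
    j <- if (i == 7L) 1L else i + 1L
    0.5 * vnorm(cross3(points[i, ] - O, points[j, ] - O))
  }, numeric(1))
  new("PackingGeometry", intersections = points, center = O,
      areas = areas, totalArea = sum(areas))
}

#' Packing parameters
#'
#' @param sMin,sMax area bounds in square angstroms (\code{0 < sMin < sMax}).
#' @param weight non-negative combination weight (default 1).
#' @return a \linkS4class{PackingParams}.
#' @export
PackingParams <- function(sMin, sMax, weight = 1) {
  new("PackingParams", sMin = as.numeric(sMin), sMax = as.numeric(sMax),
      weight = as.numeric(weight))
}

#' Piecewise bundle-packing penalty
#'
#' Zero when the summed projected triangle area S lies within
#' \code{[sMin, sMax]}; a relative quadratic penalty
#' \code{((S - sMin) / sMin)^2} below the band and
#' \code{((S - sMax) / sMax)^2} above it.  Small values indicate a tight,
#' well-packed bundle; large values a collapsed or blown-open one.
#'
#' @param S summed triangle area (square angstroms, non-negative).
#' @param params a \linkS4class{PackingParams}.
#' @return dimensionless penalty.
#' @export
packingEnergyTerm <- function(S, params) {
  if (!is.numeric(S) || any(S < 0)) stop("S must be non-negative")
  ifelse(S < params@sMin, ((S - params@sMin) / params@sMin)^2,
         ifelse(S > params@sMax, ((S - params@sMax) / params@sMax)^2, 0))
}

# Positions within a dist() vector of the CA pairs that are at least
# minSep apart in sequence and are both loop residues (the atom-level
# clash term; any pair involving a helix is handled on the axis segments
# so that the clash term cannot rank helix register).  Cached per
# topology, since the term is evaluated for every move proposal.
.distIdxCache <- new.env(parent = emptyenv())
loopPairIdx <- function(topology, minSep = 4L) {
  n <- topology@n
  key <- paste(n, minSep, paste(topology@tmRanges, collapse = ","),
               sep = "_")
  if (!exists(key, envir = .distIdxCache)) {
    inTM <- rep(FALSE, n)
    for (i in seq_len(7)) inTM[topology@tmRanges[i, 1]:topology@tmRanges[i, 2]] <- TRUE
    # dist() vector order: pairs (i, j), j > i, grouped by i
    ii <- unlist(lapply(seq_len(n - 1L), function(i) rep(i, n - i)))
    jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    keep <- (jj - ii >= minSep) & !inTM[ii] & !inTM[jj]
    assign(key, which(keep), envir = .distIdxCache)
  }
  get(key, envir = .distIdxCache)
}

#' Surrogate membrane score
#'
#' A deterministic, coarse-grained stand-in for a membrane-environment
#' score, composed of (a) an excluded-volume penalty -- a soft-cylinder
#' helix-helix clash \code{sum(max(0, dHelix - d)^2)} over the 21 fitted
#' axis-segment pair distances, a loop-vs-helix clash holding every loop
#' residue CA at least \code{dLoopAxis} from every non-flanking helix
#' axis segment, and a soft-sphere CA-CA clash
#' \code{sum(max(0, dClash - d)^2)} over loop residue pairs at least 4
#' apart in sequence (all helix exclusion lives on the axes so that the
#' term is exactly invariant under a spin about the helix axis, which a
#' backbone-level score cannot rank) -- (b) a depth term penalizing helix-axis segment endpoints
#' whose distance from the midplane exceeds the slab half-thickness
#' (\code{sum(max(0, |depth| - halfThickness)^2)} over the two fitted
#' axis endpoints of each helix; axis-based rather than per-CA so the
#' term is exactly invariant under a spin about the helix axis, a
#' symmetry a backbone-level score cannot meaningfully break), and (c) a
#' bundle-shape term standing in for the packing role of a full membrane
#' score, which a CA-only clash penalty cannot see: a contact-maintenance
#' hinge penalizing adjacent helix axes that run farther apart than
#' \code{contactMax} at any of three stations along the membrane normal
#' (lower leaflet, midplane, upper leaflet; ring adjacency TM7 -> TM1),
#' plus a regularity penalty holding every projected fan triangle's area
#' within its proportional share of the packing band (each \code{7 * Si}
#' scored by the same relative quadratic penalty as the total area).
#' Without (c), a bundle can collapse a helix into the (side-chain-free)
#' pore, bunch helices tangentially, blow a helix outward, or swing a
#' helix's lean direction at no cost.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param topology its \linkS4class{Topology}.
#' @param frame a \linkS4class{MembraneFrame}.
#' @param dClash atom-level clash distance in angstroms (default 4).
#' @param dHelix soft-cylinder helix-helix clash distance in angstroms
#'   (default 9, the reference family's closest adjacent axis approach minus a
#'   small margin).
#' @param dLoopAxis loop-CA to non-flanking-helix-axis floor distance in
#'   angstroms (default 7, calibrated the same way).
#' @param halfThickness membrane slab half-thickness in angstroms
#'   (default 16.5, the reference family's helix-axis endpoint depth plus a
#'   small margin).
#' @param clashWeight,depthWeight,shapeWeight term weights (default 1).
#' @param contactMax largest adjacent-axis separation held at zero
#'   penalty (angstroms; default 11, the reference family's adjacent
#'   axis-axis distance plus a small margin).
#' @param shapeParams \linkS4class{PackingParams} band used by the
#'   regularity part of the shape term (default
#'   \code{\link{defaultPackingParams}()}); \code{NULL} disables the
#'   whole shape term.
#' @return dimensionless score (0 for a clash-free, regularly packed
#'   bundle inside the slab).
#' @export
surrogateMembraneScore <- function(s, topology, frame, dClash = 4,
                                   dHelix = 9, dLoopAxis = 7,
                                   halfThickness = 16.5,
                                   clashWeight = 1,
                                   depthWeight = 1, shapeWeight = 1,
                                   contactMax = 11,
                                   shapeParams = defaultPackingParams()) {
  ca <- caCoords(s)
  dv <- stats::dist(ca)
  viol <- pmax(0, dClash - dv[loopPairIdx(topology)])
  axes <- lapply(seq_len(7), function(i) .fitAxisRaw(s, topology@tmRanges[i, ]))
  clash <- sum(viol^2) + .cylinderClash(axes, dHelix) +
    .loopAxisClash(s, topology, axes, dLoopAxis)
  depthPen <- .depthPenalty(axes, frame, halfThickness)
  shape <- 0
  if (!is.null(shapeParams) && shapeWeight > 0) {
    geom <- .bundleGeomRaw(s, topology, frame, axes = axes)
    contact <- .contactPenalty(axes, frame, contactMax)
    shape <- contact + sum(packingEnergyTerm(7 * geom$areas, shapeParams))
  }
  clashWeight * clash + depthWeight * depthPen + shapeWeight * shape
}

#' Total refinement energy
#'
#' The whole-pose score used by the greedy refinement stages: the surrogate
#' membrane score plus \code{weight} times the bundle-packing penalty
#' evaluated on the current projected-area geometry.
#'
#' @inheritParams surrogateMembraneScore
#' @param params a \linkS4class{PackingParams}.
#' @param ... further arguments passed to \code{surrogateMembraneScore}.
#' @return an \linkS4class{EnergyReport}.
#' @export
totalEnergy <- function(s, topology, frame, params, ...) {
  helices <- lapply(seq_len(7), function(i)
    fitHelixAxis(s, topology@tmRanges[i, ], i))
  geom <- packingAreas(membraneIntersections(helices, frame))
  ep <- packingEnergyTerm(geom@totalArea, params)
  surr <- surrogateMembraneScore(s, topology, frame, shapeParams = params,
                                 ...)
  new("EnergyReport", total = surr + params@weight * ep,
      surrogateMembrane = surr, packing = params@weight * ep,
      area = geom@totalArea)
}

#' Calibrate packing area bounds from reference bundles
#'
#' Sets the band \code{[sMin, sMax]} to the minimum and maximum summed
#' projected triangle area over a set of reference bundles.
#'
#' @param references list of reference bundles, each a list with elements
#'   \code{structure}, \code{topology}, and optionally \code{frame} (derived
#'   from the structure when absent).
#' @param weight combination weight carried into the returned parameters.
#' @return a \linkS4class{PackingParams}.
#' @export
calibrateAreaBounds <- function(references, weight = 1) {
  if (length(references) < 2L) stop("need at least 2 reference bundles")
  S <- vapply(references, function(r) {
    frame <- if (is.null(r$frame))
      membraneFrameFromStructure(r$structure, r$topology) else r$frame
    helices <- lapply(seq_len(7), function(i)
      fitHelixAxis(r$structure, r$topology@tmRanges[i, ], i))
    packingAreas(membraneIntersections(helices, frame))@totalArea
  }, numeric(1))
  if (max(S) - min(S) < 1e-9)
    stop("degenerate bounds (sMin = sMax): references have identical areas")
  PackingParams(min(S), max(S), weight)
}

#' Default packing parameters
#'
#' The shipped band was calibrated with \code{calibrateAreaBounds} on the
#' synthetic ideal-bundle family.  The 7-TM bundle cross-section is a
#' conserved feature, so the reference family spans ring radii within 5
#' percent of the default 12 angstroms (11.4 to 12.6); users working with
#' real receptors should re-calibrate on known structures.
#'
#' @param weight combination weight (default 1).
#' @return a \linkS4class{PackingParams}.
#' @export
defaultPackingParams <- function(weight = 1) {
  # S for a vertical-helix bundle on a ring of radius R is the heptagon
  # area 3.5 * sin(2*pi/7) * R^2; radii 11.4 and 12.6 bound the family.
  PackingParams(3.5 * sin(2 * pi / 7) * 11.4^2,
                3.5 * sin(2 * pi / 7) * 12.6^2, weight)
}

setMethod("show", "EnergyReport", function(object) {
  cat(sprintf("EnergyReport: total %.4f (membrane %.4f + packing %.4f; S = %.1f A^2)\n",
              object@total, object@surrogateMembrane, object@packing,
              object@area))
})

setMethod("show", "PackingGeometry", function(object) {
  cat(sprintf("PackingGeometry: S = %.2f A^2 (S1..S7: %s)\n",
              object@totalArea,
              paste(sprintf("%.2f", object@areas), collapse = " ")))
})
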