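#' Move-sampling ranges
#'
#' Defaults follow the refinement protocol: per-axis translations uniform on
#' \code{[-5, 5]} angstroms, spins uniform on \code{[-180, 180]} degrees,
#' and tilt targets drawn from a Gaussian with mean 30 degrees and standard
#' deviation 5 degrees.
#'
#' @param translateMax maximum per-axis translation (angstroms).
#' @param spinMax maximum spin magnitude (degrees).
#' @param tiltMean,tiltSd tilt-target Gaussian parameters (degrees).
#' @return a \linkS4class{MoveRanges}.
#' @export
MoveRanges <- function(translateMax = 5, spinMax = 180, tiltMean = 30,
                       tiltSd = 5) {
  new("MoveRanges", translateMax = as.numeric(translateMax),
      spinMax = as.numeric(spinMax), tiltMean = as.numeric(tiltMean),
      tiltSd = as.numeric(tiltSd))
}

#' Sample a rigid translation
#'
#' Each component is drawn independently and uniformly on
#' \code{[-translateMax, +translateMax]}.
#'
#' @param ranges a \linkS4class{MoveRanges}.
#' @param rng a \code{\link{randomStream}}.
#' @return numeric \code{c(dx, dy, dz)} in angstroms.
#' @export
sampleTranslation <- function(ranges, rng) {
  streamEval(rng, stats::runif(3, -ranges@translateMax, ranges@translateMax))
}

#' Sample a spin angle
#'
#' Uniform on \code{[-spinMax, +spinMax]} degrees.
#'
#' @inheritParams sampleTranslation
#' @return angle in degrees.
#' @export
sampleSpin <- function(ranges, rng) {
  streamEval(rng, stats::runif(1, -ranges@spinMax, ranges@spinMax))
}

#' Sample a tilt-angle target
#'
#' Drawn from \code{Normal(tiltMean, tiltSd^2)} degrees.
#'
#' @inheritParams sampleTranslation
#' @return tilt target in degrees.
#' @export
sampleTilt <- function(ranges, rng) {
  streamEval(rng, stats::rnorm(1, ranges@tiltMean, ranges@tiltSd))
}

#' Translate a helix rigidly
#'
#' All atoms of the residues in \code{helixRange} are shifted by
#' \code{delta}; every other residue is untouched, so internal helix
#' geometry is exactly preserved.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param helixRange residue range \code{c(start, end)}.
#' @param delta length-3 translation in angstroms.
#' @return the translated structure.
#' @export
translateHelix <- function(s, helixRange, delta) {
  helixRange <- as.integer(helixRange)
  if (helixRange[1] < 1L || helixRange[2] > nResidues(s) ||
      helixRange[1] > helixRange[2])
    stop("helix range out of bounds")
  rows <- atomRows(helixRange[1]:helixRange[2])
  s@coords[rows, ] <- sweep(s@coords[rows, , drop = FALSE], 2, delta, `+`)
  s
}

#' Spin a helix about its own axis
#'
#' Rotates the helix atoms about the fitted helix axis through the helix
#' centroid; the axis direction and centroid are invariant under the move.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param helix a \linkS4class{HelixSegment}, or a residue range
#'   \code{c(start, end)} (the axis is then fitted on the fly).
#' @param angle spin angle in degrees.
#' @param maxAngle largest allowed magnitude (degrees, default 180).
#' @return the rotated structure.
#' @export
spinHelix <- function(s, helix, angle, maxAngle = 180) {
  if (abs(angle) > maxAngle + 1e-9)
    stop("spin angle out of range [-", maxAngle, ", ", maxAngle, "]")
  if (!is(helix, "HelixSegment")) helix <- fitHelixAxis(s, helix)
  rows <- atomRows(helix@range[1]:helix@range[2])
  s@coords[rows, ] <- rotateAbout(s@coords[rows, , drop = FALSE],
                                  helix@centroid, helix@axis, deg2rad(angle))
  s
}

# Tilt of a helix axis against the membrane normal, in degrees on [0, 90]:
# the angle to whichever of +/-normal the axis points along.
helixTilt <- function(axis, normal) {
  rad2deg(acos(min(1, abs(sum(axis * normal)))))
}

#' Tilt a helix to a sampled angle against the membrane normal
#'
#' Draws a target tilt from the Gaussian in \code{ranges} and rotates the
#' helix rigidly about an axis through its centroid, perpendicular to both
#' the current helix axis and the membrane normal, so that the resulting
#' angle between helix axis and membrane normal equals the sampled target.
#' When the helix axis is parallel to the normal the rotation axis is
#' undefined and is drawn (deterministically from the stream) perpendicular
#' to the normal.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param helix a \linkS4class{HelixSegment} or residue range.
#' @param frame a \linkS4class{MembraneFrame}.
#' @param rng a \code{\link{randomStream}}.
#' @param ranges a \linkS4class{MoveRanges}.
#' @param targetTilt optional fixed target (degrees); sampled when missing.
#' @return list with elements \code{structure} and \code{tilt} (the sampled
#'   target in degrees).
#' @export
tiltHelix <- function(s, helix, frame, rng, ranges = MoveRanges(),
                      targetTilt = NULL) {
  if (!is(helix, "HelixSegment")) helix <- fitHelixAxis(s, helix)
  if (is.null(targetTilt)) targetTilt <- sampleTilt(ranges, rng)
  a <- helix@axis
  m <- frame@normal
  if (sum(a * m) < 0) m <- -m        # sign-align: tilt measured on [0, 90]
  cur <- helixTilt(a, m)
  r <- cross3(a, m)
  if (vnorm(r) < 1e-8) {
    # axis parallel to normal: any perpendicular works; draw one
    v <- streamEval(rng, stats::rnorm(3))
    v <- v - sum(v * m) * m
    if (vnorm(v) < 1e-8) v <- cross3(m, c(1, 0, 0))
    r <- v
  }
  r <- unitv(r)
  # rotating about r = axis x normal by a positive angle moves the axis
  # toward the normal, i.e. decreases the tilt
  phi <- deg2rad(cur - targetTilt)
  rows <- atomRows(helix@range[1]:helix@range[2])
  s@coords[rows, ] <- rotateAbout(s@coords[rows, , drop = FALSE],
                                  helix@centroid, r, phi)
  list(structure = s, tilt = targetTilt)
}

#' Greedy move acceptance
#'
#' Accepts a proposal if and only if its energy is strictly lower than the
#' current energy; ties are rejected.  Ties are judged at a small absolute
#' tolerance so that floating-point jitter on an energy-neutral move (for
#' example a spin, which leaves every helix-level term mathematically
#' unchanged) never counts as a decrease.  A non-finite proposal is
#' rejected and flagged via the \code{"nonfinite"} attribute.
#'
#' @param currentEnergy,proposedEnergy total energies.
#' @param tolerance tie tolerance; a proposal must undercut the current
#'   energy by more than this to be accepted (default 1e-9).
#' @return logical; attribute \code{"nonfinite"} is \code{TRUE} when either
#'   energy was not finite.
#' @export
greedyAccept <- function(currentEnergy, proposedEnergy, tolerance = 1e-9) {
  if (!is.finite(currentEnergy) || !is.finite(proposedEnergy)) {
    res <- FALSE
    attr(res, "nonfinite") <- TRUE
    return(res)
  }
  res <- proposedEnergy < currentEnergy - tolerance
  attr(res, "nonfinite") <- FALSE
  res
}
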