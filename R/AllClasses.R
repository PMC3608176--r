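#' @import methods
NULL

#' Backbone-only protein structure
#'
#' Holds the four backbone atoms (N, CA, C, O) of every residue of a single
#' chain, in angstroms.  Residue numbering is normalized to contiguous
#' \code{1..n} on construction; the original author numbering is retained in
#' \code{originalIds} and used again on output.  This is the pose object that
#' all refinement operations act on.
#'
#' @slot coords numeric matrix with \code{4 * n} rows and 3 columns; rows are
#'   ordered N, CA, C, O within each residue, residues in chain order.
#' @slot nres number of residues \code{n}.
#' @slot chain single-character chain identifier.
#' @slot originalIds integer vector of length \code{n}: the residue numbers
#'   found in the source file (equal to \code{1:n} for generated structures).
#' @exportClass BackboneStructure
setClass("BackboneStructure",
  representation(coords = "matrix", nres = "integer", chain = "character",
                 originalIds = "integer"),
  validity = function(object) {
    n <- object@nres
    if (length(n) != 1L || n < 1L) return("nres must be a single positive integer")
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
      return("coords must be a numeric matrix with 3 columns")
    if (nrow(object@coords) != 4L * n)
      return("coords must have exactly 4 rows (N, CA, C, O) per residue")
    if (!all(is.finite(object@coords))) return("all coordinates must be finite")
    if (length(object@chain) != 1L || nchar(object@chain) != 1L)
      return("chain must be a single character")
    if (length(object@originalIds) != n) return("originalIds must have length nres")
    if (any(diff(object@originalIds) <= 0L))
      return("originalIds must be strictly increasing")
    TRUE
  })

#' Transmembrane/loop topology of a 7-TM chain
#'
#' Partitions residues \code{1..n} into seven ordered transmembrane helix
#' ranges (TM1..TM7) and the complementary loop ranges (N-terminus,
#' inter-helix loops, C-terminus).  All ranges are 1-based and inclusive.
#'
#' @slot tmRanges integer matrix, 7 rows, columns \code{start}, \code{end}.
#' @slot loopRanges integer matrix, one row per loop region (possibly zero
#'   rows), columns \code{start}, \code{end}.
#' @slot n chain length in residues.
#' @exportClass Topology
setClass("Topology",
  representation(tmRanges = "matrix", loopRanges = "matrix", n = "integer"),
  validity = function(object) {
    tm <- object@tmRanges; lp <- object@loopRanges; n <- object@n
    if (nrow(tm) != 7L) return("exactly 7 TM ranges are required")
    if (ncol(tm) != 2L || (nrow(lp) > 0L && ncol(lp) != 2L))
      return("ranges must have columns start, end")
    if (any(tm[, 2] - tm[, 1] + 1L < 5L))
      return("each TM range must span at least 5 residues")
    all <- rbind(tm, lp)
    if (any(all[, 1] > all[, 2])) return("range start must not exceed end")
    if (any(all < 1L) || any(all > n)) return("ranges must lie within 1..n")
    covered <- unlist(lapply(seq_len(nrow(all)), function(i) all[i, 1]:all[i, 2]))
    if (anyDuplicated(covered)) return("TM and loop ranges must be disjoint")
    if (!setequal(covered, seq_len(n)))
      return("TM and loop ranges must jointly cover 1..n")
    if (any(diff(tm[, 1]) <= 0L)) return("TM ranges must be in chain order")
    TRUE
  })

#' Fitted helix segment
#'
#' A transmembrane helix summarized as a unit axis direction (N-to-C sense)
#' and the centroid of its CA atoms.
#'
#' @slot index helix index 1..7 (0 when unknown).
#' @slot range integer \code{c(start, end)} residue range.
#' @slot axis unit vector, N-to-C direction of the fitted axis.
#' @slot centroid mean CA position in angstroms.
#' @exportClass HelixSegment
setClass("HelixSegment",
  representation(index = "integer", range = "integer", axis = "numeric",
                 centroid = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9) return("axis must be unit length")
    if (length(object@range) != 2L) return("range must be c(start, end)")
    TRUE
  })

#' Membrane reference frame
#'
#' The membrane is modeled as a slab; its midplane is given by a point and a
#' unit normal vector.
#'
#' @slot normal unit normal of the midplane.
#' @slot midplanePoint any point on the midplane, in angstroms.
#' @exportClass MembraneFrame
setClass("MembraneFrame",
  representation(normal = "numeric", midplanePoint = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9) return("normal must be unit length")
    if (length(object@midplanePoint) != 3L) return("midplanePoint must be length 3")
    TRUE
  })

#' Result of a least-squares rigid superposition
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation length-3 vector (angstroms); a mobile point \code{x} is
#'   mapped to \code{rotation \%*\% x + translation}.
#' @slot rmsd post-fit root-mean-square deviation (angstroms).
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric", rmsd = "numeric"),
  validity = function(object) {
    if (abs(det(object@rotation) - 1) > 1e-9)
      return("rotation must be proper (det = +1)")
    if (object@rmsd < 0) return("rmsd must be non-negative")
    TRUE
  })

#' Projected bundle-packing geometry
#'
#' The seven intersection points of the helix axes with the membrane
#' midplane, their centroid O, and the areas of the seven triangles fanned
#' from O over adjacent intersection points (TM7 wraps to TM1).
#'
#' @slot intersections 7x3 matrix of midplane intersection points.
#' @slot center centroid O of the seven points.
#' @slot areas areas S1..S7 in square angstroms.
#' @slot totalArea S, the sum of S1..S7.
#' @exportClass PackingGeometry
setClass("PackingGeometry",
  representation(intersections = "matrix", center = "numeric",
                 areas = "numeric", totalArea = "numeric"),
  validity = function(object) {
    if (nrow(object@intersections) != 7L) return("need 7 intersection points")
    if (any(object@areas < -1e-12)) return("areas must be non-negative")
    if (abs(object@totalArea - sum(object@areas)) > 1e-9)
      return("totalArea must equal sum of areas")
    if (max(abs(object@center - colMeans(object@intersections))) > 1e-9)
      return("center must be the centroid of the intersection points")
    TRUE
  })

#' Parameters of the bundle-packing penalty
#'
#' \code{sMin} and \code{sMax} are the lower and upper bounds on the summed
#' projected triangle area S observed in reference bundles; \code{weight}
#' scales the penalty when combined with the surrogate membrane score.
#'
#' @slot sMin lower area bound (square angstroms).
#' @slot sMax upper area bound (square angstroms).
#' @slot weight non-negative combination weight.
#' @exportClass PackingParams
setClass("PackingParams",
  representation(sMin = "numeric", sMax = "numeric", weight = "numeric"),
  validity = function(object) {
    if (!(object@sMin > 0)) return("sMin must be positive")
    if (!(object@sMax > object@sMin)) return("sMax must exceed sMin")
    if (object@weight < 0) return("weight must be non-negative")
    TRUE
  })

#' Per-conformation energy breakdown
#'
#' @slot total total score: surrogate membrane score plus weighted packing
#'   penalty.
#' @slot surrogateMembrane surrogate membrane score (clash + depth terms).
#' @slot packing weighted packing penalty (weight times the piecewise term).
#' @slot area the summed projected triangle area S the packing term saw.
#' @exportClass EnergyReport
setClass("EnergyReport",
  representation(total = "numeric", surrogateMembrane = "numeric",
                 packing = "numeric", area = "numeric"),
  validity = function(object) {
    ok <- is.finite(object@total) && is.finite(object@surrogateMembrane)
    if (ok && abs(object@total - (object@surrogateMembrane + object@packing)) > 1e-9)
      return("total must equal surrogateMembrane + packing")
    TRUE
  })

#' Move-sampling ranges for the rigid-body helix move set
#'
#' @slot translateMax maximum per-axis translation (angstroms, default 5).
#' @slot spinMax maximum spin magnitude about the helix axis (degrees,
#'   default 180).
#' @slot tiltMean mean of the Gaussian tilt-angle target (degrees, default 30).
#' @slot tiltSd standard deviation of the tilt target (degrees, default 5).
#' @exportClass MoveRanges
setClass("MoveRanges",
  representation(translateMax = "numeric", spinMax = "numeric",
                 tiltMean = "numeric", tiltSd = "numeric"),
  validity = function(object) {
    v <- c(object@translateMax, object@spinMax, object@tiltMean, object@tiltSd)
    if (any(v <= 0)) return("all move ranges must be positive")
    TRUE
  })

#' Loop-closure configuration
#'
#' @slot maxOuterCycles maximum full CCD sweeps over the loop pivots.
#' @slot maxInnerCycles per-pivot refinement passes within a sweep.
#' @slot closureTolerance convergence tolerance on the closure distance
#'   (angstroms, default 0.08).
#' @slot protocol closure protocol; only \code{"CCD"} is implemented, the
#'   slot is the extension point for alternatives such as kinematic closure.
#' @exportClass LoopRefineConfig
setClass("LoopRefineConfig",
  representation(maxOuterCycles = "integer", maxInnerCycles = "integer",
                 closureTolerance = "numeric", protocol = "character"),
  validity = function(object) {
    if (object@maxOuterCycles < 1L || object@maxInnerCycles < 1L)
      return("cycle counts must be >= 1")
    if (!(object@closureTolerance > 0)) return("closureTolerance must be positive")
    if (!identical(object@protocol, "CCD")) return("only the CCD protocol is available")
    TRUE
  })

#' Single-pipeline refinement configuration
#'
#' Cycle counts for the three rigid-body stages, the helices and loops the
#' pipeline is allowed to touch, and the pipeline seed.  The framework
#' assigns each pipeline at most an adjacent helix pair; a standalone run of
#' the single-pipeline protocol may take all seven helices.
#'
#' @slot stage2Cycles translation-stage cycles.
#' @slot stage3Cycles spin-stage cycles.
#' @slot stage4Cycles tilt-stage cycles.
#' @slot iterationsT repetitions of the whole stage sequence within one
#'   pipeline run.
#' @slot assignedHelices contiguous non-empty subset of 1..7.
#' @slot assignedLoops subset of loop indices (may be empty).
#' @slot seed pipeline RNG seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(stage2Cycles = "integer", stage3Cycles = "integer",
                 stage4Cycles = "integer", iterationsT = "integer",
                 assignedHelices = "integer",
                 assignedLoops = "integer", seed = "integer"),
  validity = function(object) {
    if (any(c(object@stage2Cycles, object@stage3Cycles, object@stage4Cycles) < 1L))
      return("stage cycle counts must be >= 1")
    if (object@iterationsT < 1L) return("iterationsT must be >= 1")
    h <- object@assignedHelices
    if (length(h) < 1L) return("assignedHelices must be non-empty")
    if (any(h < 1L | h > 7L)) return("assignedHelices must lie in 1..7")
    if (length(h) > 1L && any(diff(sort(h)) != 1L))
      return("assignedHelices must be contiguous")
    TRUE
  })

#' State of a refinement pipeline
#'
#' @slot current current accepted pose.
#' @slot currentEnergy its energy breakdown.
#' @slot best best-so-far pose (equal to current under greedy acceptance).
#' @slot bestEnergy its energy breakdown.
#' @slot acceptCounts named integer vector of accepted moves per stage.
#' @slot trajectory energies of accepted states, in acceptance order,
#'   starting with the initial energy.
#' @exportClass PipelineState
setClass("PipelineState",
  representation(current = "BackboneStructure", currentEnergy = "EnergyReport",
                 best = "BackboneStructure", bestEnergy = "EnergyReport",
                 acceptCounts = "integer", trajectory = "numeric"))

#' Elite pool of low-energy conformations
#'
#' A bounded, energy-sorted store of the best conformations seen so far,
#' shared across pipelines and iterations.  Ties are broken by insertion
#' order (first inserted wins).
#'
#' @slot entries list of entries, each a list with elements
#'   \code{structure}, \code{energy} (numeric total), \code{provenance}
#'   (character), and \code{serial} (insertion counter).
#' @slot capacity maximum number of stored entries.
#' @slot serial monotone insertion counter.
#' @exportClass ElitePool
setClass("ElitePool",
  representation(entries = "list", capacity = "integer", serial = "integer"),
  validity = function(object) {
    if (object@capacity < 1L) return("capacity must be >= 1")
    if (length(object@entries) > object@capacity)
      return("pool exceeds its capacity")
    e <- vapply(object@entries, function(x) x$energy, numeric(1))
    if (length(e) && any(!is.finite(e)))
      return("pool must not hold non-finite energies")
    if (length(e) > 1L && any(diff(e) < 0)) return("entries must be sorted by energy")
    TRUE
  })

#' Multi-template framework configuration
#'
#' @slot nPipelines number of region-assigned pipelines (default 8).
#' @slot nTemplates number of templates F (1 for single-template mode,
#'   2--4 for multi-template mode).
#' @slot iterations number of framework iterations T.
#' @slot eliteCapacity elite-pool capacity (default 4 * F).
#' @slot crossingEnabled whether the helix-crossing step runs.
#' @slot masterSeed master RNG seed; all per-pipeline streams derive from it.
#' @exportClass FrameworkConfig
setClass("FrameworkConfig",
  representation(nPipelines = "integer", nTemplates = "integer",
                 iterations = "integer", eliteCapacity = "integer",
                 crossingEnabled = "logical", masterSeed = "integer"),
  validity = function(object) {
    if (object@nPipelines < 2L) return("need at least 2 pipelines")
    f <- object@nTemplates
    if (f < 1L || f > 4L) return("nTemplates must be 1 (single) or 2-4 (multi)")
    if (object@iterations < 0L) return("iterations must be >= 0")
    if (object@eliteCapacity < 1L) return("eliteCapacity must be >= 1")
    TRUE
  })

#' Synthetic bundle specification
#'
#' Parameters of the ideal seven-helix test bundle: helix and loop lengths,
#' ring radius of the helix centers, helical rise, and the generator seed.
#'
#' @slot nHelices number of helices (must be 7 for topology compatibility).
#' @slot helixLength residues per helix (default 25).
#' @slot loopLength residues per loop and terminus (default 6).
#' @slot ringRadius radius of the circle the helix centers sit on
#'   (angstroms, default 12).
#' @slot risePerResidue helical rise (angstroms per residue, default 1.5).
#' @slot tiltAngle common tilt of the helix axes against the bundle normal
#'   (degrees, default 30 -- the typical transmembrane helix tilt, and the
#'   mean of the refinement protocol's tilt prior).
#' @slot seed generator seed.
#' @exportClass BundleSpec
setClass("BundleSpec",
  representation(nHelices = "integer", helixLength = "integer",
                 loopLength = "integer", ringRadius = "numeric",
                 risePerResidue = "numeric", tiltAngle = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nHelices != 7L) return("nHelices must be 7")
    if (object@helixLength < 5L) return("helixLength must be >= 5")
    if (object@loopLength < 3L) return("loopLength must be >= 3")
    if (object@ringRadius <= 0 || object@risePerResidue <= 0)
      return("ringRadius and risePerResidue must be positive")
    if (object@tiltAngle < 0 || object@tiltAngle >= 60)
      return("tiltAngle must lie in [0, 60) degrees")
    TRUE
  })

#' Result of a framework run
#'
#' @slot best lowest-energy conformation found.
#' @slot bestEnergy its energy breakdown.
#' @slot pool final elite pool.
#' @slot decoys list of decoy conformations (elite-pool snapshot, or the
#'   accumulated history in accumulation mode).
#' @slot log per-(iteration, pipeline) run log as a data.frame.
#' @exportClass RefinementRun
setClass("RefinementRun",
  representation(best = "BackboneStructure", bestEnergy = "EnergyReport",
                 pool = "ElitePool", decoys = "list", log = "data.frame"))
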