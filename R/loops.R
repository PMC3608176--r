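#' Loop-closure configuration
#'
#' @param maxOuterCycles maximum CCD sweeps over the loop pivots
#'   (default 100).
#' @param maxInnerCycles pivot passes per sweep (default 1).
#' @param closureTolerance convergence tolerance on the closure distance
#'   (angstroms, default 0.08).
#' @param protocol closure protocol (only \code{"CCD"}).
#' @return a \linkS4class{LoopRefineConfig}.
#' @export
LoopRefineConfig <- function(maxOuterCycles = 100, maxInnerCycles = 1,
                             closureTolerance = 0.08, protocol = "CCD") {
  new("LoopRefineConfig", maxOuterCycles = as.integer(maxOuterCycles),
      maxInnerCycles = as.integer(maxInnerCycles),
      closureTolerance = as.numeric(closureTolerance),
      protocol = protocol)
}

#' Chain-connectivity gap at a junction
#'
#' The absolute deviation of the C(i)--N(i+1) distance from the ideal
#' peptide bond length (1.33 angstroms).  Rigid helix moves break the chain
#' at helix-loop junctions; this measures the break.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param junctionResidue residue index i (the gap is between i and i+1).
#' @return non-negative gap in angstroms.
#' @export
connectivityGap <- function(s, junctionResidue) {
  i <- as.integer(junctionResidue)
  if (i < 1L || i >= nResidues(s))
    stop("junction must be an internal residue (1 <= i < n)")
  Ci <- atomCoords(s, i, "C")
  Ni1 <- atomCoords(s, i + 1L, "N")
  abs(vnorm(Ni1 - Ci) - .idealGeom$bCN)
}

# Ghost backbone N one residue beyond `res`, built with ideal peptide
# geometry and the supplied psi dihedral (radians).
ghostN <- function(s, res, psi) {
  placeAtom(as.numeric(atomCoords(s, res, "N")),
            as.numeric(atomCoords(s, res, "CA")),
            as.numeric(atomCoords(s, res, "C")),
            .idealGeom$bCN, deg2rad(.idealGeom$aCaCN), psi)
}

# Rigidly translate the residues of a loop so that its first residue's N
# sits at the ideal peptide-bond distance from the preceding anchor C,
# preserving the current bond direction.
snapLoopStart <- function(s, loopRange) {
  lo <- loopRange[1]
  Cprev <- as.numeric(atomCoords(s, lo - 1L, "C"))
  N1 <- as.numeric(atomCoords(s, lo, "N"))
  dir <- N1 - Cprev
  if (vnorm(dir) < 1e-9)
    dir <- as.numeric(atomCoords(s, lo - 1L, "C")) -
      as.numeric(atomCoords(s, lo - 1L, "CA"))
  delta <- (Cprev + .idealGeom$bCN * unitv(dir)) - N1
  rows <- atomRows(loopRange[1]:loopRange[2])
  s@coords[rows, ] <- sweep(s@coords[rows, , drop = FALSE], 2, delta, `+`)
  s
}

#' Close a chain break by cyclic coordinate descent
#'
#' Re-closes the junction at the downstream end of a loop by iteratively
#' adjusting the loop's backbone phi/psi dihedrals, one pivot at a time,
#' each step taking the closed-form rotation angle that minimizes the
#' distance between the loop's moving chain end (a ghost backbone N built
#' beyond the last loop residue) and the fixed downstream anchor N.  The
#' upstream junction is first re-attached rigidly (bond-length snap).  Only
#' loop-residue coordinates change; flanking residues are never touched,
#' and all bond lengths and angles are preserved (only dihedrals move).
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param loopRange residue range \code{c(start, end)} of the loop, with
#'   fixed anchor residues on both sides and length >= 3.
#' @param config a \linkS4class{LoopRefineConfig}.
#' @return list with elements \code{structure}, \code{finalGap}
#'   (connectivity gap at the downstream junction, angstroms),
#'   \code{converged} (logical), and \code{gapHistory} (closure distance
#'   after each outer cycle; non-increasing).
#' @export
ccdClose <- function(s, loopRange, config = LoopRefineConfig()) {
  lo <- as.integer(loopRange[1]); hi <- as.integer(loopRange[2])
  n <- nResidues(s)
  if (lo < 2L || hi > n - 1L)
    stop("loop must lie strictly between fixed anchor residues")
  if (hi - lo + 1L < 3L) stop("loop too short for closure (need >= 3 residues)")

  target <- as.numeric(atomCoords(s, hi + 1L, "N"))
  # ghost dihedral frozen at the entry geometry so an already-closed chain
  # scores a zero closure distance immediately
  psi0 <- dihedralAngle(as.numeric(atomCoords(s, hi, "N")),
                        as.numeric(atomCoords(s, hi, "CA")),
                        as.numeric(atomCoords(s, hi, "C")),
                        target)
  closure <- function(st) vnorm(ghostN(st, hi, psi0) - target)

  if (closure(s) <= config@closureTolerance) {
    return(list(structure = s, finalGap = connectivityGap(s, hi),
                converged = TRUE, gapHistory = closure(s)))
  }

  s <- snapLoopStart(s, c(lo, hi))

  # rigid pre-alignment: rotate the loop about its first N so the moving
  # chain end points at the target.  This costs nothing (the upstream
  # bond is preserved) and spares the per-pivot descent from the slow
  # near-aligned regime classic CCD is prone to.
  N1 <- as.numeric(atomCoords(s, lo, "N"))
  u <- ghostN(s, hi, psi0) - N1
  v <- target - N1
  if (vnorm(u) > 1e-9 && vnorm(v) > 1e-9) {
    u <- unitv(u); v <- unitv(v)
    axis <- cross3(u, v)
    if (vnorm(axis) > 1e-9) {
      rows <- atomRows(lo:hi)
      s@coords[rows, ] <- rotateAbout(
        s@coords[rows, , drop = FALSE], N1, unitv(axis),
        acos(max(-1, min(1, sum(u * v)))))
    }
  }

  # pivot table: axis atoms and the downstream rows each dihedral moves
  pivots <- list()
  for (i in lo:hi) {
    down <- if (i < hi) atomRows((i + 1L):hi) else integer(0)
    # phi_i: rotation about N(i)-CA(i) moves C(i), O(i) and everything after
    pivots[[length(pivots) + 1L]] <- list(
      from = (i - 1L) * 4L + 1L, to = (i - 1L) * 4L + 2L,
      rows = c((i - 1L) * 4L + 3L, (i - 1L) * 4L + 4L, down))
    # psi_i (not for the last residue; the ghost dihedral is frozen):
    # rotation about CA(i)-C(i) moves O(i) and everything after
    if (i < hi) {
      pivots[[length(pivots) + 1L]] <- list(
        from = (i - 1L) * 4L + 2L, to = (i - 1L) * 4L + 3L,
        rows = c((i - 1L) * 4L + 4L, down))
    }
  }

  gapHistory <- numeric(0)
  converged <- FALSE
  for (outer in seq_len(config@maxOuterCycles)) {
    for (inner in seq_len(config@maxInnerCycles)) {
      for (pv in pivots) {
        o <- s@coords[pv$from, ]
        u <- s@coords[pv$to, ] - o
        if (vnorm(u) < 1e-9) next
        u <- unitv(u)
        M <- ghostN(s, hi, psi0)
        rel <- M - o
        center <- o + sum(rel * u) * u
        v <- M - center
        sv <- vnorm(v)
        if (sv < 1e-9) next
        vh <- v / sv
        f <- target - center
        theta <- atan2(sum(f * cross3(u, vh)), sum(f * vh))
        if (abs(theta) < 1e-12) next
        s@coords[pv$rows, ] <- rotateAbout(
          s@coords[pv$rows, , drop = FALSE], o, u, theta)
      }
    }
    g <- closure(s)
    gapHistory <- c(gapHistory, g)
    if (g <= config@closureTolerance) { converged <- TRUE; break }
  }
  list(structure = s, finalGap = connectivityGap(s, hi),
       converged = converged, gapHistory = gapHistory)
}

# Rigidly translate a terminal tail back onto its single junction.
snapTerminalLoop <- function(s, loopRange) {
  lo <- loopRange[1]; hi <- loopRange[2]; n <- nResidues(s)
  rows <- atomRows(lo:hi)
  if (lo == 1L && hi < n) {          # N-terminal tail: attach its end
    Nnext <- as.numeric(atomCoords(s, hi + 1L, "N"))
    Ce <- as.numeric(atomCoords(s, hi, "C"))
    dir <- Ce - Nnext
    if (vnorm(dir) < 1e-9) dir <- c(1, 0, 0)
    delta <- (Nnext + .idealGeom$bCN * unitv(dir)) - Ce
  } else if (hi == n && lo > 1L) {   # C-terminal tail: attach its start
    Cprev <- as.numeric(atomCoords(s, lo - 1L, "C"))
    N1 <- as.numeric(atomCoords(s, lo, "N"))
    dir <- N1 - Cprev
    if (vnorm(dir) < 1e-9) dir <- c(1, 0, 0)
    delta <- (Cprev + .idealGeom$bCN * unitv(dir)) - N1
  } else {
    stop("not a terminal loop")
  }
  s@coords[rows, ] <- sweep(s@coords[rows, , drop = FALSE], 2, delta, `+`)
  s
}

# Re-close every junction: terminal tails are snapped rigidly, interior
# loops closed by CCD.  Deterministic (no randomness).
closeAllJunctions <- function(s, topology, config = LoopRefineConfig()) {
  lp <- topology@loopRanges
  n <- nResidues(s)
  for (i in seq_len(nrow(lp))) {
    lo <- lp[i, 1]; hi <- lp[i, 2]
    if (lo == 1L || hi == n) {
      if (lo == 1L && hi == n) next
      s <- snapTerminalLoop(s, c(lo, hi))
    } else {
      s <- ccdClose(s, c(lo, hi), config)$structure
    }
  }
  s
}

#' Refine a randomly chosen loop
#'
#' Picks one loop uniformly at random and applies the configured closure
#' protocol to it: CCD closure for interior loops, a rigid re-attachment for
#' terminal tails.  With only CCD available the random choice is over loops,
#' not protocols.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param topology its \linkS4class{Topology}.
#' @param config a \linkS4class{LoopRefineConfig}.
#' @param rng a \code{\link{randomStream}}.
#' @param loops optional subset of loop indices (rows of
#'   \code{loopRanges(topology)}) to choose from; default all.
#' @return the refined structure.
#' @export
refineLoopsRandomly <- function(s, topology, config = LoopRefineConfig(),
                                rng, loops = NULL) {
  lp <- topology@loopRanges
  if (nrow(lp) == 0L) {
    warning("topology has no loops; nothing to refine")
    return(s)
  }
  if (is.null(loops)) loops <- seq_len(nrow(lp))
  pick <- loops[streamEval(rng, sample.int(length(loops), 1L))]
  lo <- lp[pick, 1]; hi <- lp[pick, 2]
  n <- nResidues(s)
  if (lo == 1L || hi == n) {
    if (lo == 1L && hi == n) return(s)
    snapTerminalLoop(s, c(lo, hi))
  } else {
    ccdClose(s, c(lo, hi), config)$structure
  }
}
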