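#' Synthetic bundle specification
#'
#' @param nHelices number of helices (7).
#' @param helixLength residues per helix (default 25).
#' @param loopLength residues per loop and per terminal tail (default 6).
#' @param ringRadius radius of the circle the helix axes sit on (angstroms,
#'   default 12).
#' @param risePerResidue helical rise (angstroms, default 1.5).
#' @param tiltAngle common helix tilt against the bundle normal (degrees,
#'   default 30, matching the refinement protocol's tilt prior).
#' @param seed generator seed (default 1).
#' @return a \linkS4class{BundleSpec}.
#' @export
BundleSpec <- function(nHelices = 7, helixLength = 25, loopLength = 6,
                       ringRadius = 12, risePerResidue = 1.5,
                       tiltAngle = 30, seed = 1) {
  new("BundleSpec", nHelices = as.integer(nHelices),
      helixLength = as.integer(helixLength),
      loopLength = as.integer(loopLength),
      ringRadius = as.numeric(ringRadius),
      risePerResidue = as.numeric(risePerResidue),
      tiltAngle = as.numeric(tiltAngle), seed = as.integer(seed))
}

# Build L residues forward from anchor backbone atoms (N, CA, C) using
# ideal peptide geometry; phis/psis in degrees, psiPrev is the dihedral
# placing the first new N.  Returns a 4L x 3 coordinate matrix.
buildChainForward <- function(anchorN, anchorCA, anchorC, L, phis, psis,
                              psiPrev) {
  g <- .idealGeom
  phis <- rep_len(phis, L); psis <- rep_len(psis, L)
  a <- anchorN; b <- anchorCA; c <- anchorC
  out <- matrix(NA_real_, 4L * L, 3L)
  for (j in seq_len(L)) {
    psiIn <- if (j == 1L) psiPrev else psis[j - 1L]
    Nj <- placeAtom(a, b, c, g$bCN, deg2rad(g$aCaCN), deg2rad(psiIn))
    CAj <- placeAtom(b, c, Nj, g$bNCa, deg2rad(g$aCNCa), deg2rad(g$omega))
    Cj <- placeAtom(c, Nj, CAj, g$bCaC, deg2rad(g$aNCaC), deg2rad(phis[j]))
    Oj <- placeAtom(Nj, CAj, Cj, g$bCO, deg2rad(g$aCaCO),
                    deg2rad(psis[j] - 180))
    out[(j - 1L) * 4L + 1:4, ] <- rbind(Nj, CAj, Cj, Oj)
    a <- Nj; b <- CAj; c <- Cj
  }
  out
}

# Build L residues backward from anchor backbone atoms (N, CA, C of the
# residue that follows the tail).  phiNext is the phi dihedral of the
# anchor residue (free; it does not move the anchor).  Returns a 4L x 3
# matrix in chain order (most N-terminal residue first).
buildChainBackward <- function(anchorN, anchorCA, anchorC, L, phis, psis,
                               phiNext) {
  g <- .idealGeom
  phis <- rep_len(phis, L); psis <- rep_len(psis, L)
  aN <- anchorN; aCA <- anchorCA; aC <- anchorC
  out <- matrix(NA_real_, 4L * L, 3L)
  for (j in seq_len(L)) {            # j-th residue before the anchor
    k <- L - j + 1L                  # its position within the tail
    phiIn <- if (j == 1L) phiNext else phis[k + 1L]
    Cj <- placeAtom(aC, aCA, aN, g$bCN, deg2rad(g$aCNCa), deg2rad(phiIn))
    CAj <- placeAtom(aCA, aN, Cj, g$bCaC, deg2rad(g$aCaCN), deg2rad(g$omega))
    Nj <- placeAtom(aN, Cj, CAj, g$bNCa, deg2rad(g$aNCaC), deg2rad(psis[k]))
    Oj <- placeAtom(Nj, CAj, Cj, g$bCO, deg2rad(g$aCaCO),
                    deg2rad(psis[k] - 180))
    out[(k - 1L) * 4L + 1:4, ] <- rbind(Nj, CAj, Cj, Oj)
    aN <- Nj; aCA <- CAj; aC <- Cj
  }
  out
}

# An ideal alpha-helix (phi = -57, psi = -47) of L residues with its axis
# along +z (N-to-C sense) and its CA centroid at the origin.
idealHelixTemplate <- function(L) {
  g <- .idealGeom
  N1 <- c(0, 0, 0)
  CA1 <- c(g$bNCa, 0, 0)
  C1 <- CA1 + g$bCaC * c(cos(pi - deg2rad(g$aNCaC)),
                         sin(pi - deg2rad(g$aNCaC)), 0)
  O1 <- placeAtom(N1, CA1, C1, g$bCO, deg2rad(g$aCaCO), deg2rad(-47 - 180))
  rest <- buildChainForward(N1, CA1, C1, L - 1L, -57, -47, -47)
  coords <- rbind(N1, CA1, C1, O1, rest)
  s <- BackboneStructure(coords)
  seg <- fitHelixAxis(s, c(1L, L))
  rotAxis <- cross3(seg@axis, c(0, 0, 1))
  theta <- acos(max(-1, min(1, seg@axis[3])))
  centered <- sweep(coords, 2, seg@centroid)
  if (vnorm(rotAxis) > 1e-9) {
    centered <- centered %*% t(rotationMatrix(rotAxis, theta))
  }
  ca <- centered[seq(2L, by = 4L, length.out = L), , drop = FALSE]
  sweep(centered, 2, colMeans(ca))
}

# Minimum CA-CA distance between loop residues and all residues at least
# 4 apart in sequence (clash screen for generated loops).
loopMinContact <- function(s, loopRange) {
  ca <- caCoords(s)
  idx <- loopRange[1]:loopRange[2]
  other <- setdiff(seq_len(nrow(ca)), integer(0))
  dmin <- Inf
  for (i in idx) {
    far <- other[abs(other - i) >= 4L]
    d <- sqrt(rowSums(sweep(ca[far, , drop = FALSE], 2, ca[i, ])^2))
    dmin <- min(dmin, min(d))
  }
  dmin
}

#' Generate an ideal seven-helix bundle
#'
#' Builds seven ideal alpha-helices (phi = -57, psi = -47 geometry) placed
#' on a ring, with axes alternating up/down along z and uniformly tilted
#' against the bundle normal in the tangential sense (a twisted bundle,
#' which preserves the seven-fold packing at every height), connected by
#' geometrically closed loops (CCD-closed, clash-screened) and capped by
#' short terminal tails.  The membrane normal is +z with the midplane at
#' the mean CA height, so the generated bundle sits fully inside the
#' default membrane slab, its packing area lies inside the default
#' calibrated band, and its helix tilts sit at the mean of the refinement
#' protocol's tilt prior: the energy's global-minimum neighborhood is known
#' by construction.
#'
#' @param spec a \linkS4class{BundleSpec}.
#' @return list with elements \code{structure}
#'   (\linkS4class{BackboneStructure}), \code{topology}
#'   (\linkS4class{Topology}), and \code{frame}
#'   (\linkS4class{MembraneFrame}).
#' @export
makeIdealBundle <- function(spec = BundleSpec()) {
  stopifnot(is(spec, "BundleSpec"))
  L <- spec@helixLength; LL <- spec@loopLength
  tmpl <- idealHelixTemplate(L)
  flip <- rotationMatrix(c(1, 0, 0), pi)
  tau <- deg2rad(spec@tiltAngle)
  helixCoords <- vector("list", 7L)
  for (i in seq_len(7L)) {
    ang <- 2 * pi * (i - 1L) / 7
    center <- c(spec@ringRadius * cos(ang), spec@ringRadius * sin(ang), 0)
    cc <- if (i %% 2L == 1L) tmpl else tmpl %*% t(flip)
    if (tau > 1e-12) {
      # lean the axis tangentially by the tilt angle: the whole bundle is
      # twisted uniformly, so neighbor spacing is preserved at every height
      that <- c(-sin(ang), cos(ang), 0)
      u <- cos(tau) * c(0, 0, 1) + sin(tau) * that
      cc <- cc %*% t(rotationMatrix(cross3(c(0, 0, 1), u),
                                    acos(max(-1, min(1, u[3])))))
    }
    helixCoords[[i]] <- sweep(cc, 2, center, `+`)
  }

  # chain layout: Nterm | TM1 | loop | TM2 | ... | TM7 | Cterm
  n <- 7L * L + 6L * LL + 2L * LL
  tm <- matrix(0L, 7L, 2L, dimnames = list(NULL, c("start", "end")))
  pos <- LL + 1L
  for (i in seq_len(7L)) {
    tm[i, ] <- c(pos, pos + L - 1L)
    pos <- pos + L + LL
  }
  topology <- Topology(tm, n)
  coords <- matrix(0, 4L * n, 3L)
  for (i in seq_len(7L)) coords[atomRows(tm[i, 1]:tm[i, 2]), ] <- helixCoords[[i]]

  rng <- randomStream(spec@seed)
  getAtoms <- function(i, cc = coords) {
    list(N = cc[(i - 1L) * 4L + 1L, ], CA = cc[(i - 1L) * 4L + 2L, ],
         C = cc[(i - 1L) * 4L + 3L, ])
  }

  # inter-helix loops: forward-built from the preceding helix end, then
  # CCD-closed onto the next helix start; restart from fresh random
  # dihedrals until closed and clash-screened.  Terminal tails are added
  # last, also restart-screened (no closure needed).
  closeCfg <- LoopRefineConfig(maxOuterCycles = 300, closureTolerance = 0.01)
  s <- BackboneStructure(coords)
  helixAxes <- lapply(seq_len(7L), function(i) .fitAxisRaw(s, tm[i, ]))
  # clearance of a candidate loop/tail from the non-flanking helix axes
  # (mirrors the loop-axis floor of the surrogate score, with margin)
  axisClearance <- function(st, rg, flanking) {
    P <- caCoords(st, rg[1]:rg[2])
    dmin <- Inf
    for (i in setdiff(seq_len(7L), flanking)) {
      h <- helixAxes[[i]]
      rel <- P - matrix(h$centroid, nrow(P), 3L, byrow = TRUE)
      tt <- pmin(h$halfLen, pmax(-h$halfLen, rel %*% h$axis))
      dmin <- min(dmin, sqrt(rowSums((rel - tt %*% t(h$axis))^2)))
    }
    dmin
  }
  for (i in seq_len(6L)) {
    lo <- tm[i, 2] + 1L; hi <- tm[i + 1L, 1] - 1L
    anchor <- getAtoms(tm[i, 2], s@coords)
    bestS <- NULL; bestScore <- -Inf
    for (try in seq_len(60L)) {
      draws <- streamEval(rng, list(phi = stats::runif(LL, -160, -40),
                                    psi = stats::runif(LL, -70, 170),
                                    psiPrev = stats::runif(1, -70, 170)))
      guess <- buildChainForward(anchor$N, anchor$CA, anchor$C, LL,
                                 draws$phi, draws$psi, draws$psiPrev)
      cand <- s
      cand@coords[atomRows(lo:hi), ] <- guess
      res <- ccdClose(cand, c(lo, hi), closeCfg)
      contact <- loopMinContact(res$structure, c(lo, hi))
      clear <- axisClearance(res$structure, c(lo, hi), c(i, i + 1L))
      if (res$converged && contact >= 4.3 && clear >= 7.3) {
        bestS <- res$structure; break
      }
      score <- min(contact, 4.3) + min(clear, 7.3) - 10 * res$finalGap
      if (score > bestScore) { bestS <- res$structure; bestScore <- score }
    }
    s <- bestS
  }

  for (tail in c("N", "C")) {
    bestC <- NULL; bestContact <- -Inf
    rg <- if (tail == "N") c(1L, LL) else c(n - LL + 1L, n)
    for (try in seq_len(60L)) {
      draws <- streamEval(rng, list(phi = stats::runif(LL, -160, -40),
                                    psi = stats::runif(LL, -70, 170),
                                    extra = stats::runif(1, -70, 170)))
      cc <- if (tail == "N") {
        a <- getAtoms(tm[1, 1], s@coords)
        buildChainBackward(a$N, a$CA, a$C, LL, draws$phi, draws$psi, -57)
      } else {
        a <- getAtoms(tm[7, 2], s@coords)
        buildChainForward(a$N, a$CA, a$C, LL, draws$phi, draws$psi,
                          draws$extra)
      }
      cand <- s
      cand@coords[atomRows(rg[1]:rg[2]), ] <- cc
      contact <- min(loopMinContact(cand, rg),
                     axisClearance(cand, rg,
                                   if (tail == "N") 1L else 7L) - 3)
      if (contact >= 4.3) { bestC <- cand; break }
      if (contact > bestContact) { bestC <- cand; bestContact <- contact }
    }
    s <- bestC
  }

  midZ <- mean(caCoords(s, regionResidues(topology, "TM"))[, 3])
  frame <- new("MembraneFrame", normal = c(0, 0, 1),
               midplanePoint = c(0, 0, midZ))
  list(structure = s, topology = topology, frame = frame)
}

#' Apply a recorded set of per-helix rigid perturbations
#'
#' Replays the exact move sequence recorded by \code{\link{perturbBundle}}:
#' per helix a rigid translation, a spin about the (current) helix axis,
#' and a tilt increment about the axis perpendicular to both helix axis and
#' membrane normal, followed by deterministic re-closure of all junctions.
#'
#' @param bundle list with \code{structure}, \code{topology}, \code{frame}
#'   (as returned by \code{\link{makeIdealBundle}}).
#' @param perturbations list of 7 per-helix records, each with elements
#'   \code{delta}, \code{spin}, \code{dTilt}.
#' @param loopConfig closure configuration for the re-closure pass.
#' @return the perturbed \linkS4class{BackboneStructure}.
#' @export
applyPerturbations <- function(bundle, perturbations,
                               loopConfig = LoopRefineConfig()) {
  s <- bundle$structure; topology <- bundle$topology; frame <- bundle$frame
  for (i in seq_len(7L)) {
    p <- perturbations[[i]]
    rg <- topology@tmRanges[i, ]
    s <- translateHelix(s, rg, p$delta)
    seg <- fitHelixAxis(s, rg, i)
    s <- spinHelix(s, seg, p$spin)
    seg <- fitHelixAxis(s, rg, i)
    m <- frame@normal
    if (sum(seg@axis * m) < 0) m <- -m
    r <- cross3(seg@axis, m)
    if (vnorm(r) > 1e-8) {
      rows <- atomRows(rg[1]:rg[2])
      s@coords[rows, ] <- rotateAbout(s@coords[rows, , drop = FALSE],
                                      seg@centroid, unitv(r),
                                      deg2rad(p$dTilt))
    }
  }
  closeAllJunctions(s, topology, loopConfig)
}

#' Randomly perturb a bundle's helices
#'
#' Gives every helix an independent random rigid perturbation (uniform
#' translation per axis, uniform spin, uniform tilt increment) within the
#' given bounds, then re-closes all junctions.  The applied ground-truth
#' perturbations are returned and reproduce the perturbed pose exactly when
#' re-applied to the original with \code{\link{applyPerturbations}}.
#'
#' @param bundle list with \code{structure}, \code{topology}, \code{frame}.
#' @param maxTranslation per-axis translation bound (angstroms, default 3).
#' @param maxSpin spin bound (degrees, default 30).
#' @param maxTilt tilt-increment bound (degrees, default 10).
#' @param rng a \code{\link{randomStream}}.
#' @param loopConfig closure configuration for the re-closure pass.
#' @return list with elements \code{structure} and \code{perturbations}.
#' @export
perturbBundle <- function(bundle, maxTranslation = 3, maxSpin = 30,
                          maxTilt = 10, rng,
                          loopConfig = LoopRefineConfig()) {
  perturbations <- lapply(seq_len(7L), function(i) {
    streamEval(rng, list(
      delta = stats::runif(3, -maxTranslation, maxTranslation),
      spin = stats::runif(1, -maxSpin, maxSpin),
      dTilt = stats::runif(1, -maxTilt, maxTilt)))
  })
  list(structure = applyPerturbations(bundle, perturbations, loopConfig),
       perturbations = perturbations)
}

#' Build complementary multi-template fixtures
#'
#' Template k keeps the helices of its subset near-native (light noise) and
#' heavily perturbs all other helices, so each template is individually
#' wrong somewhere while the templates are jointly correct everywhere --
#' the situation the helix-crossing step is designed to exploit.
#'
#' @param bundle list with \code{structure}, \code{topology}, \code{frame}.
#' @param split list of helix-index subsets partitioning 1..7 (default
#'   \code{list(1:4, 5:7)}).
#' @param noiseHigh translation bound for the wrong helices (angstroms,
#'   default 6, sized beyond the single-template refiner's basin of
#'   attraction so that template complementarity, not refinement alone,
#'   is the route to a jointly correct bundle); spins/tilts of wrong
#'   helices are drawn within 60/20 degrees.
#' @param noiseLow translation bound for the near-native helices
#'   (angstroms, default 0.3), with spins/tilts within 5/2 degrees.
#' @param rng a \code{\link{randomStream}}.
#' @param loopConfig closure configuration for the re-closure pass.
#' @return list of \linkS4class{BackboneStructure} templates, one per
#'   subset.
#' @export
makeComplementaryTemplates <- function(bundle, split = list(1:4, 5:7),
                                       noiseHigh = 6, noiseLow = 0.3, rng,
                                       loopConfig = LoopRefineConfig()) {
  all <- sort(unlist(split))
  if (!identical(as.integer(all), 1:7))
    stop("split subsets must partition helices 1..7")
  lapply(split, function(keep) {
    perturbations <- lapply(seq_len(7L), function(i) {
      high <- !(i %in% keep)
      tb <- if (high) noiseHigh else noiseLow
      sb <- if (high) 60 else 5
      ab <- if (high) 20 else 2
      streamEval(rng, list(delta = stats::runif(3, -tb, tb),
                           spin = stats::runif(1, -sb, sb),
                           dTilt = stats::runif(1, -ab, ab)))
    })
    applyPerturbations(bundle, perturbations, loopConfig)
  })
}
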