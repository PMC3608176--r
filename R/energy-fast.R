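# Internal fast paths for the whole-pose energy.  These avoid S4 object
# construction and full SVDs in the move-proposal loop; the exported
# totalEnergy() wraps the same numbers in the S4 report classes.

# Principal axis and centroid of the CA atoms of a residue range, sign
# fixed N -> C.  Returns list(axis, centroid).
.fitAxisRaw <- function(s, range) {
  ca <- caCoords(s, range[1]:range[2])
  cm <- colMeans(ca)
  X <- ca
  X[, 1] <- X[, 1] - cm[1]; X[, 2] <- X[, 2] - cm[2]; X[, 3] <- X[, 3] - cm[3]
  ev <- eigen(crossprod(X), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  nc <- ca[nrow(ca), ] - ca[1, ]
  if (sum(axis * nc) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  halfLen <- max(abs(X %*% axis))
  list(axis = axis, centroid = cm, halfLen = halfLen)
}

# Axis/midplane intersections, fan areas and totals for the 7-TM bundle.
# Returns list(intersections, areas, totalArea) or stops on a degenerate
# (in-plane) axis.  `axes` may carry precomputed .fitAxisRaw results.
.bundleGeomRaw <- function(s, topology, frame, axes = NULL) {
  m <- frame@normal; p0 <- frame@midplanePoint
  P <- matrix(0, 7L, 3L)
  for (i in seq_len(7L)) {
    h <- if (is.null(axes)) .fitAxisRaw(s, topology@tmRanges[i, ]) else axes[[i]]
    denom <- sum(h$axis * m)
    if (abs(denom) <= 1e-6)
      stop("degenerate intersection: helix ", i,
           " axis is parallel to the membrane plane")
    tt <- sum((p0 - h$centroid) * m) / denom
    P[i, ] <- h$centroid + tt * h$axis
  }
  O <- colMeans(P)
  A <- P - matrix(O, 7L, 3L, byrow = TRUE)
  B <- A[c(2:7, 1L), , drop = FALSE]
  cx <- A[, 2] * B[, 3] - A[, 3] * B[, 2]
  cy <- A[, 3] * B[, 1] - A[, 1] * B[, 3]
  cz <- A[, 1] * B[, 2] - A[, 2] * B[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  list(intersections = P, areas = areas, totalArea = sum(areas))
}

# Minimum distance between two finite 3D segments (standard clamped
# closest-point algorithm).
.segmentDistance <- function(p1, d1, l1, p2, d2, l2) {
  # segments: p +/- l * d, reparametrized to s, t in [-l, l]
  r <- p1 - p2
  a <- 1; b <- sum(d1 * d2); f <- sum(d2 * r); c0 <- sum(d1 * r)
  den <- 1 - b * b
  if (den > 1e-12) {
    s <- max(-l1, min(l1, (b * f - c0) / den))
  } else {
    s <- 0
  }
  t <- max(-l2, min(l2, b * s + f))
  s <- max(-l1, min(l1, b * t - c0))
  sqrt(sum((p1 + s * d1 - (p2 + t * d2))^2))
}

# Helix-helix excluded volume on the fitted axis segments: at backbone
# resolution a transmembrane helix is a rigid cylinder, so helix-helix
# clash is evaluated between axis segments (exactly spin-invariant; a
# backbone-level score cannot rank helix register) with a soft floor at
# dHelix, the family's adjacent axis spacing minus a small margin.
.cylinderClash <- function(axes, dHelix) {
  pen <- 0
  for (i in 1:6) {
    for (j in (i + 1):7) {
      d <- .segmentDistance(axes[[i]]$centroid, axes[[i]]$axis,
                            axes[[i]]$halfLen,
                            axes[[j]]$centroid, axes[[j]]$axis,
                            axes[[j]]$halfLen)
      pen <- pen + max(0, dHelix - d)^2
    }
  }
  pen
}

# Loop-vs-helix excluded volume: every loop residue CA must keep a floor
# distance from the axis segment of every helix that does not flank its
# loop (flanking helices are naturally close at the junctions).  Axis
# based, hence exactly spin-invariant, like the helix-helix term.
.flankCache <- new.env(parent = emptyenv())
.loopFlankMap <- function(topology) {
  key <- paste(topology@n, paste(topology@tmRanges, collapse = ","),
               paste(topology@loopRanges, collapse = ","), sep = "_")
  if (!exists(key, envir = .flankCache)) {
    lp <- topology@loopRanges; tm <- topology@tmRanges
    m <- lapply(seq_len(nrow(lp)), function(k) {
      f <- integer(0)
      for (i in seq_len(7L)) {
        if (lp[k, 2] + 1L == tm[i, 1] || lp[k, 1] - 1L == tm[i, 2])
          f <- c(f, i)
      }
      f
    })
    assign(key, m, envir = .flankCache)
  }
  get(key, envir = .flankCache)
}

.loopAxisClash <- function(s, topology, axes, dLoopAxis) {
  lp <- topology@loopRanges
  if (nrow(lp) == 0L) return(0)
  flank <- .loopFlankMap(topology)
  pen <- 0
  for (k in seq_len(nrow(lp))) {
    P <- caCoords(s, lp[k, 1]:lp[k, 2])
    for (i in setdiff(seq_len(7L), flank[[k]])) {
      h <- axes[[i]]
      rel <- P - matrix(h$centroid, nrow(P), 3L, byrow = TRUE)
      tt <- pmin(h$halfLen, pmax(-h$halfLen, rel %*% h$axis))
      d <- sqrt(rowSums((rel - tt %*% t(h$axis))^2))
      pen <- pen + sum(pmax(0, dLoopAxis - d)^2)
    }
  }
  pen
}

# Depth hinge on the fitted helix axis span: the two axis segment
# endpoints (centroid +/- halfLen * axis) must stay within the membrane
# slab.  Evaluating depth on the axis rather than on individual CA atoms
# makes the term exactly invariant under a spin about the helix axis -- a
# symmetry a backbone-level score should not break, since it cannot rank
# helix register.
.depthPenalty <- function(axes, frame, halfThickness) {
  m <- frame@normal; p0 <- frame@midplanePoint
  pen <- 0
  for (h in axes) {
    for (sgn in c(-1, 1)) {
      d <- sum((h$centroid + sgn * h$halfLen * h$axis - p0) * m)
      pen <- pen + max(0, abs(d) - halfThickness)^2
    }
  }
  pen
}

# Contact-maintenance hinge: adjacent helix axes (ring order, TM7 wraps
# to TM1) are intersected with planes at normal offsets -H, 0, +H from
# the midplane; separations beyond contactMax are penalized
# quadratically.  H sits inside the membrane leaflets so every
# transmembrane axis crosses all three planes.  At the leaflet stations
# the hinge is widened by the geometric flare of a uniformly twisted
# bundle, sqrt(1 + (H tan(tilt) / R)^2) for the reference family's
# 30-degree tilt on a 12-angstrom ring.
.CONTACT_STATION <- 12
.CONTACT_FLARE <- sqrt(1 + (.CONTACT_STATION * tan(pi / 6) / 12)^2)
.contactPenalty <- function(axes, frame, contactMax) {
  m <- frame@normal
  pen <- 0
  for (off in c(-.CONTACT_STATION, 0, .CONTACT_STATION)) {
    limit <- if (off == 0) contactMax else contactMax * .CONTACT_FLARE
    p0 <- frame@midplanePoint + off * m
    P <- matrix(0, 7L, 3L)
    for (i in seq_len(7L)) {
      h <- axes[[i]]
      denom <- sum(h$axis * m)
      if (abs(denom) <= 1e-6)
        stop("degenerate intersection: helix ", i,
             " axis is parallel to the membrane plane")
      tt <- sum((p0 - h$centroid) * m) / denom
      P[i, ] <- h$centroid + tt * h$axis
    }
    adj <- sqrt(rowSums((P - P[c(2:7, 1L), , drop = FALSE])^2))
    pen <- pen + sum(pmax(0, adj - limit)^2)
  }
  pen
}

# Piecewise band penalty without argument checking (vectorized).
.bandPenalty <- function(S, sMin, sMax) {
  ifelse(S < sMin, ((S - sMin) / sMin)^2,
         ifelse(S > sMax, ((S - sMax) / sMax)^2, 0))
}

# Total energy as a plain list(total, surrogate, packing, area).
.energyRaw <- function(s, ctx) {
  topology <- ctx$topology; frame <- ctx$frame; params <- ctx$params
  axes <- lapply(seq_len(7L), function(i) .fitAxisRaw(s, topology@tmRanges[i, ]))
  geom <- .bundleGeomRaw(s, topology, frame, axes = axes)
  ca <- caCoords(s)
  dv <- stats::dist(ca)
  viol <- pmax(0, ctx$dClash - dv[loopPairIdx(topology)])
  clash <- sum(viol^2) + .cylinderClash(axes, ctx$dHelix) +
    .loopAxisClash(s, topology, axes, ctx$dLoopAxis)
  depthPen <- .depthPenalty(axes, frame, ctx$halfThickness)
  shape <- 0
  if (ctx$shapeWeight > 0) {
    shape <- .contactPenalty(axes, frame, ctx$contactMax) +
      sum(.bandPenalty(7 * geom$areas, params@sMin, params@sMax))
  }
  surr <- ctx$clashWeight * clash + ctx$depthWeight * depthPen +
    ctx$shapeWeight * shape
  packing <- params@weight * .bandPenalty(geom$totalArea, params@sMin,
                                          params@sMax)
  list(total = surr + packing, surrogate = surr, packing = packing,
       area = geom$totalArea)
}

.asEnergyReport <- function(raw) {
  new("EnergyReport", total = raw$total, surrogateMembrane = raw$surrogate,
      packing = raw$packing, area = raw$area)
}
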