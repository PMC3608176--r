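mkSeg <- function(axis, centroid, idx = 1L)
  new("HelixSegment", index = idx, range = c(1L, 25L),
      axis = axis / sqrt(sum(axis^2)), centroid = centroid)

planeFrame <- new("MembraneFrame", normal = c(0, 0, 1),
                  midplanePoint = c(0, 0, 0))

sevenSegs <- function(one, rest = NULL) {
  if (is.null(rest))
    rest <- lapply(2:7, function(i)
      mkSeg(c(0, 0, 1), c(cos(2 * pi * i / 7), sin(2 * pi * i / 7), 0), i))
  c(list(one), rest)
}

test_that("axis/midplane intersections follow the closed-form line-plane solution", {
  # axis along the normal, centroid on the plane -> the centroid itself
  p <- membraneIntersections(sevenSegs(mkSeg(c(0, 0, 1), c(1, 2, 0))),
                             planeFrame)
  expect_lt(max(abs(p[1, ] - c(1, 2, 0))), 1e-9)

  # centroid 10 A above the plane -> projected along the normal
  p <- membraneIntersections(sevenSegs(mkSeg(c(0, 0, 1), c(1, 2, 10))),
                             planeFrame)
  expect_lt(max(abs(p[1, ] - c(1, 2, 0))), 1e-9)

  # axis tilted 30 degrees in the xz-plane, centroid at (0, 0, 5):
  # x-offset at the plane is -5 * tan(30 deg)
  a <- c(sin(pi / 6), 0, cos(pi / 6))
  p <- membraneIntersections(sevenSegs(mkSeg(a, c(0, 0, 5))), planeFrame)
  expect_equal(p[1, 1], -5 * tan(pi / 6), tolerance = 1e-9)

  # in-plane axis is degenerate
  expect_error(
    membraneIntersections(sevenSegs(mkSeg(c(1, 0, 0), c(0, 0, 5))),
                          planeFrame),
    "degenerate intersection")
})

test_that("fan areas match the closed form on a regular heptagon and scale as k^2", {
  ang <- 2 * pi * (0:6) / 7
  hept <- cbind(cos(ang), sin(ang), 0)
  geom <- packingAreas(hept)
  expect_equal(geom@areas, rep(0.5 * sin(2 * pi / 7), 7), tolerance = 1e-9)
  expect_equal(geom@totalArea, 3.5 * sin(2 * pi / 7), tolerance = 1e-9)

  for (k in c(0.5, 3, 12)) {
    expect_equal(packingAreas(k * hept)@totalArea,
                 k^2 * geom@totalArea, tolerance = 1e-9)
  }
  expect_equal(packingAreas(matrix(1, 7, 3))@totalArea, 0)
})

test_that("fan areas agree with an independent shoelace oracle on random sets", {
  set.seed(2024)
  for (rep in seq_len(1000)) {
    pts <- cbind(matrix(runif(14, -20, 20), 7, 2), 0)
    oracle <- shoelaceFanArea(pts[, 1:2])
    geom <- packingAreas(pts)
    expect_lt(max(abs(geom@areas - oracle$areas)), 1e-9)
    expect_lt(abs(geom@totalArea - oracle$total), 1e-9)
  }
})

test_that("the piecewise packing penalty follows its band definition", {
  pp <- PackingParams(100, 150)
  # inside the open band
  expect_identical(packingEnergyTerm(125, pp), 0)
  # closed-form substitutions below and above
  expect_equal(packingEnergyTerm(50, pp), 0.25, tolerance = 1e-12)
  expect_equal(packingEnergyTerm(300, pp), 1.0, tolerance = 1e-12)
  # continuity at both bounds
  eps <- 1e-8
  expect_lt(packingEnergyTerm(100 - eps, pp), 1e-9)
  expect_lt(packingEnergyTerm(150 + eps, pp), 1e-9)
  expect_identical(packingEnergyTerm(100, pp), 0)
  expect_identical(packingEnergyTerm(150, pp), 0)
  # strict monotonicity outside the band, non-negativity everywhere
  Sgrid <- seq(0, 400, by = 0.5)
  v <- packingEnergyTerm(Sgrid, pp)
  expect_true(all(v >= 0))
  below <- Sgrid < 100
  expect_true(all(diff(v[below]) < 0))
  above <- Sgrid > 150
  expect_true(all(diff(v[above]) > 0))
  expect_error(packingEnergyTerm(-1, pp), "non-negative")
  expect_error(PackingParams(150, 100), "sMax must exceed sMin")
})

test_that("packing term is invariant under in-plane rigid motion of the bundle", {
  s <- stdBundle$structure; top <- stdTopology; frame <- stdFrame
  pp <- defaultPackingParams()
  getS <- function(x) {
    helices <- lapply(1:7, function(i) fitHelixAxis(x, tmRanges(top)[i, ], i))
    packingAreas(membraneIntersections(helices, frame))@totalArea
  }
  S0 <- getS(s)
  for (seed in 1:5) {
    set.seed(seed)
    thet <- runif(1, -pi, pi)
    R <- TMRefine:::rotationMatrix(frame@normal, thet)
    tr <- c(runif(2, -30, 30), 0)
    s2 <- transformStructure(s, R, tr)
    expect_equal(packingEnergyTerm(getS(s2), pp),
                 packingEnergyTerm(S0, pp), tolerance = 1e-9)
    expect_equal(getS(s2), S0, tolerance = 1e-6)
  }
})

test_that("surrogate clash contributions match an explicit pairwise oracle", {
  s <- stdBundle$structure
  # clash-free, regularly packed, inside the slab: zero surrogate
  expect_equal(surrogateMembraneScore(s, stdTopology, stdFrame), 0)

  # independent oracle for the atom-level (loop-loop) clash term
  loopIdx <- TMRefine:::regionResidues(stdTopology, "loops")
  loopClashOracle <- function(x, dClash = 4) {
    ca <- caCoords(x)
    tot <- 0
    for (a in seq_along(loopIdx)) {
      for (b in seq_len(a - 1L)) {
        i <- loopIdx[a]; j <- loopIdx[b]
        if (abs(i - j) < 4L) next
        d <- TMRefine:::vnorm(ca[i, ] - ca[j, ])
        tot <- tot + max(0, dClash - d)^2
      }
    }
    tot
  }

  # residues 10 A apart contribute nothing at dClash = 4; coincident loop
  # CAs contribute dClash^2 to the pair term
  s2 <- s
  s2@coords[1:4, ] <- s@coords[TMRefine:::atomRows(5L), ]  # overlay 1 on 5
  expect_equal(TMRefine:::vnorm(caCoords(s2, 1) - caCoords(s2, 5)), 0)
  o1 <- loopClashOracle(s); o2 <- loopClashOracle(s2)
  expect_gte(o2 - o1, 16 - 1e-9)   # the (1, 5) pair alone adds dClash^2
  base <- surrogateMembraneScore(s, stdTopology, stdFrame, shapeParams = NULL)
  over <- surrogateMembraneScore(s2, stdTopology, stdFrame, shapeParams = NULL)
  expect_equal(over - base, o2 - o1, tolerance = 1e-9)
})

test_that("total energy combines surrogate and weighted packing linearly", {
  s <- stdBundle$structure
  pp0 <- PackingParams(350, 450, weight = 0)
  pp1 <- PackingParams(100, 120, weight = 1)   # band violated: S ~ 394
  pp2 <- PackingParams(100, 120, weight = 2)
  e0 <- totalEnergy(s, stdTopology, stdFrame, pp0)
  expect_equal(e0@total, e0@surrogateMembrane)
  e1 <- totalEnergy(s, stdTopology, stdFrame, pp1)
  e2 <- totalEnergy(s, stdTopology, stdFrame, pp2)
  expect_gt(e1@packing, 0)
  expect_equal(e2@total - e2@surrogateMembrane,
               2 * (e1@total - e1@surrogateMembrane), tolerance = 1e-9)
  # clash-free bundle with S inside the band and depth zero scores zero
  eIdeal <- totalEnergy(s, stdTopology, stdFrame, defaultPackingParams())
  expect_equal(eIdeal@total, 0)
})

test_that("area-bound calibration takes the min/max over references", {
  mk <- function(r) {
    b <- makeIdealBundle(BundleSpec(ringRadius = r, loopLength = 4,
                                    helixLength = 12, seed = 3))
    list(structure = b$structure, topology = b$topology, frame = b$frame)
  }
  refs <- lapply(c(11, 13, 12), mk)
  pp <- calibrateAreaBounds(refs)
  S <- vapply(refs, function(r) {
    helices <- lapply(1:7, function(i)
      fitHelixAxis(r$structure, tmRanges(r$topology)[i, ], i))
    packingAreas(membraneIntersections(helices, r$frame))@totalArea
  }, numeric(1))
  expect_equal(pp@sMin, min(S))
  expect_equal(pp@sMax, max(S))
  expect_error(calibrateAreaBounds(refs[1]), "at least 2")
  expect_error(calibrateAreaBounds(list(refs[[1]], refs[[1]])),
               "degenerate bounds")
})
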