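test_that("move samplers respect their ranges, moments and determinism", {
  ranges <- MoveRanges()
  rng <- randomStream(99)
  tr <- t(replicate(2000, sampleTranslation(ranges, rng)))
  expect_true(all(tr >= -5 & tr <= 5))
  expect_lt(abs(mean(tr)), 3 * (10 / sqrt(12)) / sqrt(length(tr)))

  sp <- replicate(2000, sampleSpin(ranges, rng))
  expect_true(all(sp >= -180 & sp <= 180))

  ti <- replicate(2000, sampleTilt(ranges, rng))
  expect_lt(abs(mean(ti) - 30), 3 * 5 / sqrt(2000))

  # identical seeds give identical draws
  a <- sampleTranslation(ranges, randomStream(5))
  b <- sampleTranslation(ranges, randomStream(5))
  expect_identical(a, b)
})

test_that("helix translation is rigid, exact and local", {
  s <- stdBundle$structure
  rg <- tmRanges(stdTopology)[2, ]
  expect_identical(translateHelix(s, rg, c(0, 0, 0))@coords, s@coords)

  moved <- translateHelix(s, rg, c(3, 4, 0))
  rows <- TMRefine:::atomRows(rg[1]:rg[2])
  disp <- sqrt(rowSums((moved@coords - s@coords)^2))
  expect_equal(unique(round(disp[rows], 9)), 5)       # Pythagoras
  expect_true(all(disp[-rows] == 0))                  # bit-identical outside

  # intra-helix pairwise distances preserved exactly
  d0 <- dist(s@coords[rows, ]); d1 <- dist(moved@coords[rows, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_error(translateHelix(s, c(0, 10), c(1, 0, 0)), "out of bounds")
})

test_that("spin preserves the axis, centroid and internal geometry", {
  s <- stdBundle$structure
  rg <- tmRanges(stdTopology)[4, ]
  seg0 <- fitHelixAxis(s, rg)

  expect_equal(spinHelix(s, rg, 0)@coords, s@coords, tolerance = 1e-12)

  # two 180-degree spins come back to the start
  full <- spinHelix(spinHelix(s, rg, 180), rg, 180)
  expect_lt(max(abs(full@coords - s@coords)), 1e-6)

  spun <- spinHelix(s, rg, 73)
  seg1 <- fitHelixAxis(spun, rg)
  expect_lt(max(abs(seg1@axis - seg0@axis)), 1e-6)
  expect_lt(max(abs(seg1@centroid - seg0@centroid)), 1e-6)
  rows <- TMRefine:::atomRows(rg[1]:rg[2])
  expect_lt(max(abs(dist(spun@coords[rows, ]) - dist(s@coords[rows, ]))), 1e-9)
  expect_error(spinHelix(s, rg, 200), "out of range")
})

test_that("tilt reaches the sampled target angle and stays rigid", {
  s <- stdBundle$structure
  frame <- stdFrame
  for (h in c(1, 3, 6)) {
    rg <- tmRanges(stdTopology)[h, ]
    # explicit target equal to the current tilt is the identity
    seg <- fitHelixAxis(s, rg)
    cur <- TMRefine:::helixTilt(seg@axis, frame@normal)
    same <- tiltHelix(s, rg, frame, randomStream(1), targetTilt = cur)
    expect_lt(max(abs(same$structure@coords - s@coords)), 1e-6)

    for (seed in 1:4) {
      out <- tiltHelix(s, rg, frame, randomStream(seed))
      segN <- fitHelixAxis(out$structure, rg)
      expect_equal(TMRefine:::helixTilt(segN@axis, frame@normal), out$tilt,
                   tolerance = 1e-6)
      rows <- TMRefine:::atomRows(rg[1]:rg[2])
      expect_lt(max(abs(dist(out$structure@coords[rows, ]) -
                          dist(s@coords[rows, ]))), 1e-9)
    }
  }
})

test_that("tilting an axis-parallel helix picks a deterministic rotation axis", {
  # free-standing vertical helix, normal along z
  s <- idealHelix25
  frame <- new("MembraneFrame", normal = c(0, 0, 1),
               midplanePoint = c(0, 0, 0))
  out1 <- tiltHelix(s, c(1, 25), frame, randomStream(8), targetTilt = 20)
  out2 <- tiltHelix(s, c(1, 25), frame, randomStream(8), targetTilt = 20)
  expect_identical(out1$structure@coords, out2$structure@coords)
  seg <- fitHelixAxis(out1$structure, c(1, 25))
  expect_equal(TMRefine:::helixTilt(seg@axis, frame@normal), 20,
               tolerance = 1e-6)
})

test_that("greedy acceptance is strict, tie-rejecting and non-finite-safe", {
  expect_true(as.logical(greedyAccept(10.0, 9.9)))
  expect_false(as.logical(greedyAccept(10.0, 10.0)))
  expect_false(as.logical(greedyAccept(10.0, 10.1)))
  # numerical ties are ties
  expect_false(as.logical(greedyAccept(10.0, 10.0 - 1e-12)))
  r <- greedyAccept(10.0, NaN)
  expect_false(as.logical(r))
  expect_true(attr(r, "nonfinite"))
})

test_that("random rigid moves never touch residues outside the range", {
  s <- stdBundle$structure
  rng <- randomStream(314)
  ranges <- MoveRanges()
  for (k in 1:60) {
    h <- streamEval(rng, sample.int(7, 1))
    rg <- tmRanges(stdTopology)[h, ]
    rows <- TMRefine:::atomRows(rg[1]:rg[2])
    kind <- streamEval(rng, sample.int(3, 1))
    out <- switch(kind,
      translateHelix(s, rg, sampleTranslation(ranges, rng)),
      spinHelix(s, rg, sampleSpin(ranges, rng)),
      tiltHelix(s, rg, stdFrame, rng, ranges)$structure)
    expect_identical(out@coords[-rows, ], s@coords[-rows, ])
    expect_lt(max(abs(dist(out@coords[rows, ]) - dist(s@coords[rows, ]))),
              1e-9)
  }
})
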