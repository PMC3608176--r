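test_that("PDB write/read round trip is the identity on coordinates", {
  s <- stdBundle$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDBBackbone(s, f)
  s2 <- readPDBBackbone(f, chain = "A")
  expect_equal(nResidues(s2), nResidues(s))
  expect_equal(s2@coords, s@coords, tolerance = 1e-3)
  # PDB stores 3 decimals: 4 lines per residue
  expect_equal(sum(grepl("^ATOM", readLines(f))), 4L * nResidues(s))
})

test_that("incomplete residues and missing chains are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # hand-written CA-only trace
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:3, 1:3, c(0, 3.8, 7.6), 0, 0)
  writeLines(c(lines, "END"), f)
  expect_error(readPDBBackbone(f, chain = "A"), "incomplete residue")
  expect_error(readPDBBackbone(f, chain = "B"), "chain not found")
})

test_that("a hand-written backbone block reads with the right residue count", {
  f <- withr::local_tempfile(fileext = ".pdb")
  n <- 10L
  rows <- character(0)
  k <- 0L
  for (i in seq_len(n)) {
    for (el in c("N", "CA", "C", "O")) {
      k <- k + 1L
      rows <- c(rows, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        k, el, i + 100L, i * 3.8, k %% 4, 0))
    }
  }
  writeLines(c(rows, "END"), f)
  s <- readPDBBackbone(f, chain = "A")
  expect_equal(nResidues(s), n)
  # author numbering kept, internal numbering normalized
  expect_equal(s@originalIds, 101:110)
})

test_that("writing an empty structure errors", {
  expect_error(BackboneStructure(matrix(numeric(0), 0, 3)), "no residues")
})

test_that("helix axis fitting recovers direction, orientation and equivariance", {
  seg <- fitHelixAxis(idealHelix25, c(1, 25))
  expect_lt(max(abs(seg@axis - c(0, 0, 1))), 1e-6)
  expect_lt(max(abs(seg@centroid)), 1e-6)

  # reversing the residue order of the coordinates flips the axis
  rev <- idealHelix25
  n <- nResidues(rev)
  revRows <- as.vector(t(outer((rev(seq_len(n)) - 1L) * 4L, 1:4, `+`)))
  rev@coords <- rev@coords[revRows, ]
  segRev <- fitHelixAxis(rev, c(1, 25))
  expect_lt(max(abs(segRev@axis - c(0, 0, -1))), 1e-6)

  # equivariance under a known rotation
  for (seed in 1:5) {
    R <- randomRotation(seed)
    segR <- fitHelixAxis(transformStructure(idealHelix25, R), c(1, 25))
    expect_lt(max(abs(segR@axis - as.numeric(R %*% seg@axis))), 1e-6)
  }
  expect_error(fitHelixAxis(idealHelix25, c(1, 4)), "degenerate helix")
})

test_that("Kabsch superposition is exact on rigid copies and matches oracles", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  expect_lt(kabschSuperpose(X, X)@rmsd, 1e-9)

  R <- randomRotation(3)
  Y <- sweep(X %*% t(R), 2, c(1, -2, 3), `+`)
  fit <- kabschSuperpose(X, Y)
  expect_lt(fit@rmsd, 1e-6)
  expect_equal(det(fit@rotation), 1, tolerance = 1e-9)

  # displaced-point case against a brute-force numeric optimizer
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  B <- A; B[4, 3] <- B[4, 3] + 2
  ours <- kabschSuperpose(A, B)@rmsd
  obj <- function(p) {
    Rz <- TMRefine:::rotationMatrix(c(0, 0, 1), p[1])
    Ry <- TMRefine:::rotationMatrix(c(0, 1, 0), p[2])
    Rx <- TMRefine:::rotationMatrix(c(1, 0, 0), p[3])
    M <- sweep(A %*% t(Rx %*% Ry %*% Rz), 2, p[4:6], `+`)
    sqrt(mean(rowSums((M - B)^2)))
  }
  best <- Inf
  for (st in 1:5) {
    set.seed(st)
    o <- optim(rnorm(6, sd = 0.5), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(ours, best, tolerance = 1e-6)

  # independent package oracle
  fit2 <- bio3d::fit.xyz(as.vector(t(B)), as.vector(t(A)),
                         fixed.inds = 1:12, mobile.inds = 1:12)
  oracle <- sqrt(mean(colSums(matrix(fit2 - as.vector(t(B)), 3)^2)))
  expect_equal(ours, oracle, tolerance = 1e-6)

  expect_error(kabschSuperpose(X[1:4, ], X[1:5, ]), "equal length")
  expect_error(kabschSuperpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("region RMSD is zero on identity, sees perturbations, matches Kabsch", {
  s <- stdBundle$structure; top <- stdTopology
  for (region in c("TM", "FL", "loops"))
    expect_lt(regionRMSD(s, s, region, top), 1e-9)

  moved <- translateHelix(s, tmRanges(top)[3, ], c(3, 0, 0))
  expect_gt(regionRMSD(moved, s, "TM", top), 0.5)
  # loops were not moved: loop RMSD is computed independently of the helices
  expect_lt(regionRMSD(moved, s, "loops", top), 1e-9)

  # full-length region equals a direct Kabsch fit on all CA atoms
  rngR <- randomRotation(11)
  m2 <- transformStructure(moved, rngR, c(4, 5, -6))
  expect_equal(regionRMSD(m2, s, "FL", top),
               kabschSuperpose(caCoords(m2), caCoords(s))@rmsd,
               tolerance = 1e-9)

  # invariance under a common rigid transform
  R <- randomRotation(5)
  sA <- transformStructure(moved, R, c(-2, 7, 1))
  sB <- transformStructure(s, R, c(-2, 7, 1))
  expect_equal(regionRMSD(sA, sB, "TM", top),
               regionRMSD(moved, s, "TM", top), tolerance = 1e-6)

  short <- BackboneStructure(s@coords[1:40, ])
  expect_error(regionRMSD(short, s, "TM", top), "differ in length")
})

test_that("topology construction derives loops and validates coverage", {
  tm <- cbind(seq(7, by = 31, length.out = 7),
              seq(31, by = 31, length.out = 7))
  top <- Topology(tm, n = 223)
  expect_equal(nrow(loopRanges(top)), 8L)   # two termini + six connectors
  expect_equal(sort(c(TMRefine:::regionResidues(top, "TM"),
                      TMRefine:::regionResidues(top, "loops"))), 1:223)
  expect_error(Topology(tm[1:6, ], n = 223), "7 TM ranges")
  expect_error(Topology(cbind(tm[, 1], tm[, 1] + 2L), n = 223),
               "at least 5")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeTopology(top, f)
  top2 <- readTopology(f)
  expect_equal(tmRanges(top2), tmRanges(top), ignore_attr = TRUE)
  expect_equal(loopRanges(top2), loopRanges(top), ignore_attr = TRUE)
})
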