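# Shared fixtures, built once per test run.

# the standard synthetic bundle used across test files
stdBundle <- makeIdealBundle(BundleSpec(seed = 42))

stdTopology <- stdBundle$topology
stdFrame <- stdBundle$frame
stdCtx <- energyContext(stdTopology, stdFrame)

# a small free-standing ideal helix (axis +z, centroid at origin)
idealHelix25 <- BackboneStructure(TMRefine:::idealHelixTemplate(25L))

# random proper rotation matrix from a seed
randomRotation <- function(seed) {
  set.seed(seed)
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a rigid transform to every atom of a structure
transformStructure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  s@coords <- sweep(s@coords %*% t(R), 2, t, `+`)
  s
}

# independent 2D shoelace triangle-fan oracle for planar point sets (z = 0)
shoelaceFanArea <- function(pts2d) {
  O <- colMeans(pts2d)
  n <- nrow(pts2d)
  areas <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    a <- pts2d[i, ] - O; b <- pts2d[j, ] - O
    0.5 * abs(a[1] * b[2] - a[2] * b[1])
  }, numeric(1))
  list(areas = areas, total = sum(areas))
}
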