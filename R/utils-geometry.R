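# Small vector-geometry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotationMatrix <- function(u, theta) {
  u <- unitv(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotate the rows of matrix X about an axis through `origin` with unit
# direction `u` by angle theta (radians).
rotateAbout <- function(X, origin, u, theta) {
  R <- rotationMatrix(u, theta)
  sweep(sweep(X, 2, origin) %*% t(R), 2, origin, `+`)
}

# Signed dihedral angle a-b-c-d in radians, standard atan2 convention.
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

# NeRF atom placement: position of atom d given the three preceding atoms
# a-b-c, the bond length c-d, the bond angle b-c-d and the dihedral a-b-c-d
# (angles in radians).
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  bc <- unitv(c - b)
  ab <- unitv(b - a)
  n <- unitv(cross3(ab, bc))
  p <- cross3(n, bc)
  c + bond * (-cos(angle) * bc +
                sin(angle) * (cos(dihedral) * p + sin(dihedral) * n))
}

# Ideal backbone geometry constants (angstroms / degrees); the peptide
# C-N bond length is also the target used by the chain-gap measure.
.idealGeom <- list(
  bNCa = 1.458, bCaC = 1.525, bCN = 1.33, bCO = 1.231,
  aNCaC = 111.2, aCaCN = 116.2, aCNCa = 121.7, aCaCO = 120.5,
  omega = 180)
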