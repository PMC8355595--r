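# Internal vector geometry helpers. All angles in degrees unless noted.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vec_norm <- function(v) sqrt(sum(v^2))

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) abort("cannot normalize a zero vector")
  v / n
}

# Angle at p2 formed by p1-p2-p3, degrees.
point_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  ct <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

# Signed dihedral p1-p2-p3-p4 in degrees, IUPAC sign convention.
point_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, b2 / vec_norm(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Wrap an angle difference into (-180, 180].
wrap180 <- function(d) ((d + 180) %% 360) - 180

rotation_z <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Random proper rotation from three seeded uniform draws (used in tests too).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vec_norm(q)
  quaternion_to_matrix(q)
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# Best-fit plane unit normal of an n x 3 matrix of points (n >= 3).
plane_normal <- function(m) {
  centered <- sweep(m, 2, colMeans(m))
  s <- svd(centered)
  s$v[, 3]
}

# Deterministic golden-section spiral on the unit sphere: n x 3 matrix.
# No RNG involved, so surface-area estimates are bit-stable across runs.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * (1 - 1 / ((1 + sqrt(5)) / 2)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Optimal least-squares superposition (Kabsch, SVD with reflection guard).
# Returns list(R = 3x3 rotation, t = translation) mapping `mov` onto `ref`,
# i.e. ref ~ mov %*% R + t.
kabsch_fit <- function(mov, ref) {
  cm <- colMeans(mov)
  cr <- colMeans(ref)
  a <- sweep(mov, 2, cm)
  b <- sweep(ref, 2, cr)
  h <- t(a) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$u %*% corr %*% t(s$v)
  list(R = rot, t = cr - as.numeric(cm %*% rot))
}

apply_rigid <- function(m, fit) sweep(m %*% fit$R, 2, fit$t, `+`)

# Build an orthonormal rotation that maps unit vector u1 -> v1 and aligns the
# component of u2 orthogonal to u1 with the component of v2 orthogonal to v1.
frame_rotation <- function(u1, u2, v1, v2) {
  e1 <- vec_unit(u1)
  e2 <- vec_unit(u2 - sum(u2 * e1) * e1)
  e3 <- vec_cross(e1, e2)
  f1 <- vec_unit(v1)
  f2 <- vec_unit(v2 - sum(v2 * f1) * f1)
  f3 <- vec_cross(f1, f2)
  from <- cbind(e1, e2, e3)
  to <- cbind(f1, f2, f3)
  to %*% t(from)
}
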