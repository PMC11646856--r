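# Internal 3D geometry helpers: vector ops, torsions, and an internal-coordinate
# (NeRF-style) backbone builder used by the synthetic-structure generator.

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle defined by four points
#'
#' Returns the signed dihedral angle p1-p2-p3-p4 in radians, in (-pi, pi].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

# Place atom D given positions of A, B, C and internal coordinates:
# bond |C-D|, angle B-C-D, torsion A-B-C-D.
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                 -sin(angle) * sin(torsion))
  as.vector(c + m %*% d2)
}

# Ideal backbone internal coordinates (Engh-Huber-like values, Angstrom/rad).
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.530,
  a_n_ca_c = 111.0 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.8 * pi / 180,
  a_n_ca_cb = 110.4 * pi / 180, t_c_n_ca_cb = 122.68 * pi / 180
)

# Build an n-residue backbone from phi/psi vectors (radians). omega fixed trans.
# Returns a list of per-residue lists with named 3-vectors N, CA, C, O, CB.
build_backbone <- function(phi, psi, omega = pi, with_cb = TRUE) {
  n <- length(psi)
  stopifnot(length(phi) == n, n >= 1)
  g <- .bb_geom
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  C <- CA + g$b_ca_c * c(cos(pi - g$a_n_ca_c), sin(pi - g$a_n_ca_c), 0)
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi[i] + pi)
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (with_cb) {
      atoms$CB <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_c_n_ca_cb)
    }
    res[[i]] <- atoms
    if (i < n) {
      Nn <- place_atom(N, CA, C, g$b_c_n, g$a_ca_c_n, psi[i])
      CAn <- place_atom(CA, C, Nn, g$b_n_ca, g$a_c_n_ca, omega)
      Cn <- place_atom(C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  res
}

# Random 3D rotation matrix (proper), seeded by the caller's RNG state.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (vnorm(q) > 1e-8) break
  }
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
axis_rotation <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              nrow = 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
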