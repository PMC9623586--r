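#' Signed dihedral angle of four points
#'
#' Computes the IUPAC signed torsion angle defined by four points: the
#' angle between the plane through (p1, p2, p3) and the plane through
#' (p2, p3, p4), measured about the p2-p3 bond.  The cis (eclipsed)
#' arrangement is 0 degrees and trans (anti) is 180 degrees; mirroring
#' the points negates the angle.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors, or `p1` may be
#'   a 4x3 matrix holding all four points as rows (the rest missing).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.matrix(p1) && missing(p2)) {
    stopifnot(nrow(p1) == 4L, ncol(p1) == 3L)
    p4 <- p1[4L, ]; p3 <- p1[3L, ]; p2 <- p1[2L, ]; p1 <- p1[1L, ]
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate dihedral geometry: collinear or coincident points")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  normalize_angle(atan2(y, x) * 180 / pi)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotate selected atoms about a bond
#'
#' Applies a right-handed rotation of `angle` degrees about the axis from
#' atom `j` to atom `k` to the atoms in `moving`.  Rotating the atoms
#' downstream of a bond by `angle` increases the dihedral about that bond
#' by `angle` while leaving all bond lengths, bond angles and other
#' dihedrals unchanged.
#'
#' @param xyz Coordinate matrix (n_atoms x 3).
#' @param j,k Atom indices defining the rotation axis (the j-k bond).
#' @param moving Integer vector of atom indices to rotate.
#' @param angle Rotation in degrees.
#' @return The rotated coordinate matrix.
#' @export
rotate_about_bond <- function(xyz, j, k, moving, angle) {
  axis <- xyz[k, ] - xyz[j, ]
  na <- sqrt(sum(axis^2))
  if (na < 1e-10) stop("rotation axis atoms are coincident")
  axis <- axis / na
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  # Rodrigues rotation about an axis through atom k
  origin <- xyz[k, ]
  v <- sweep(xyz[moving, , drop = FALSE], 2L, origin)
  dotp <- drop(v %*% axis)
  crossp <- cbind(axis[2L] * v[, 3L] - axis[3L] * v[, 2L],
                  axis[3L] * v[, 1L] - axis[1L] * v[, 3L],
                  axis[1L] * v[, 2L] - axis[2L] * v[, 1L])
  vrot <- v * ct + crossp * st + outer(dotp * (1 - ct), axis)
  xyz[moving, ] <- sweep(vrot, 2L, origin, `+`)
  xyz
}

#' Set a dihedral to a target value by rotating downstream atoms
#'
#' @param xyz Coordinate matrix (n_atoms x 3).
#' @param quad Integer length-4 vector (i, j, k, l) defining the dihedral.
#' @param downstream Atom indices moved by rotation about the j-k bond.
#' @param target Target dihedral in degrees.
#' @return The updated coordinate matrix.
#' @export
set_dihedral <- function(xyz, quad, downstream, target) {
  cur <- dihedral_angle(xyz[quad[1L], ], xyz[quad[2L], ],
                        xyz[quad[3L], ], xyz[quad[4L], ])
  rotate_about_bond(xyz, quad[2L], quad[3L], downstream,
                    angle_difference(target, cur))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame placement: returns the position `d`
#' such that |c-d| = `bond`, the angle b-c-d equals `angle`, and the
#' dihedral a-b-c-d equals `dihedral`.
#'
#' @param a,b,c Numeric length-3 reference positions.
#' @param bond Bond length (Angstrom).
#' @param angle Bond angle in degrees.
#' @param dihedral Dihedral in degrees.
#' @return Numeric length-3 position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference frame for atom placement")
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
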