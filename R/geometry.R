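## Low-level 3-D geometry: dihedrals, internal-coordinate atom placement,
## and Kabsch least-squares superposition. All angles in degrees, all
## distances in Angstrom.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle defined by four points
#'
#' Signed torsion angle about the b-c axis, using the standard IUPAC sign
#' convention (cis = 0, trans = 180), returned in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return Angle in degrees. Errors if any consecutive triple is collinear
#'   (the torsion is undefined).
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("dihedral undefined: collinear atoms", call. = FALSE)
  }
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -.rad2deg(atan2(y, x))   # IUPAC sign (cis 0, counterclockwise +)
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF-style) construction: given three reference
#' positions a-b-c, place atom d at distance \code{bond} from c, with angle
#' b-c-d equal to \code{angle} and torsion a-b-c-d equal to \code{torsion}.
#'
#' @param a,b,c reference positions (numeric 3-vectors).
#' @param bond bond length c-d, Angstrom.
#' @param angle bond angle b-c-d, degrees.
#' @param torsion dihedral a-b-c-d, degrees.
#' @return Position of d as a numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-9) stop("degenerate reference frame: collinear a, b, c",
                            call. = FALSE)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  ang <- .deg2rad(180 - angle)  # polar angle from the bc direction
  tor <- .deg2rad(torsion)
  d_local <- c(bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Kabsch superposition of paired coordinate sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired points, by SVD of the cross-covariance matrix with the usual
#' determinant correction so the rotation is never a reflection.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates, row-paired with
#'   \code{mobile}.
#' @return A \code{transform} object: list with \code{rotation} (3 x 3,
#'   det +1), \code{translation} (length 3) and \code{rmsd} (Angstrom).
#'   Apply with \code{\link{apply_transform}}.
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' tr <- kabsch_superpose(pts, pts)
#' tr$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 point pairs", call. = FALSE)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # collinearity check: rank of the centred sets
  if (qr(p, tol = 1e-9)$rank < 2 || qr(q, tol = 1e-9)$rank < 2) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  h <- crossprod(p, q)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$v %*% corr %*% t(sv$u)  # maps centred mobile -> centred reference
  moved <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  trans <- cr - as.numeric(rot %*% cm)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "transform")
}

#' Apply a rigid-body transform to coordinates
#'
#' @param transform a \code{transform} from \code{\link{kabsch_superpose}}
#'   or \code{\link{make_transform}}.
#' @param xyz n x 3 coordinate matrix (or a length-3 vector).
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, xyz) {
  vec <- is.null(dim(xyz))
  xyz <- matrix(xyz, ncol = 3)
  out <- xyz %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, `+`)
  if (vec) as.numeric(out) else out
}

#' Construct a rigid-body transform
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation, Angstrom.
#' @return A \code{transform} object.
#' @export
make_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation, rmsd = NA_real_),
            class = "transform")
}

#' Invert a rigid-body transform
#' @param transform a \code{transform} object.
#' @return The inverse \code{transform}.
#' @export
invert_transform <- function(transform) {
  rinv <- t(transform$rotation)
  make_transform(rinv, as.numeric(-rinv %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / vnorm(axis)
  th <- .deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' @export
print.transform <- function(x, ...) {
  cat("Rigid-body transform\n")
  cat("  rotation:\n")
  print(round(x$rotation, 4))
  cat("  translation:", paste(sprintf("%.3f", x$translation), collapse = " "),
      "\n")
  if (is.finite(x$rmsd)) cat("  fit rmsd:", sprintf("%.4f A", x$rmsd), "\n")
  invisible(x)
}
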