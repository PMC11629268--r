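#' @importFrom rlang %||% abort
#' @importFrom stats sd setNames rnorm runif
NULL

vnorm <- function(v) sqrt(sum(v^2))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitv <- function(v) v / vnorm(v)

#' Wrap angles into [-180, 180)
#' @param x angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Torsion angle over frames
#'
#' Computes the signed dihedral angle (IUPAC convention, degrees) defined by
#' four atom positions, vectorised over rows (one row per frame).
#'
#' @param p1,p2,p3,p4 n-by-3 matrices (or length-3 vectors) of positions.
#' @return numeric vector of angles in degrees, wrapped to \[-180, 180).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame placement: returns the position of atom
#' D given previously placed atoms A, B, C, the bond length C-D, the angle
#' B-C-D and the torsion A-B-C-D.
#'
#' @param a,b,c length-3 positions of the three reference atoms.
#' @param r bond length (nm), ang angle (deg), tor torsion (deg).
#' @param ang,tor angle and torsion in degrees.
#' @return length-3 position of the new atom.
#' @keywords internal
nerf_place <- function(a, b, c, r, ang, tor) {
  th <- ang * pi / 180
  ph <- tor * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `ref` using the rows given
#' by `fit_idx`, returning the transformed full coordinate set.
#'
#' @param mobile n-by-3 coordinate matrix to transform.
#' @param ref n_fit-by-3 reference coordinates (rows match `fit_idx`).
#' @param fit_idx integer rows of `mobile` used for the fit (default all).
#' @return n-by-3 matrix of transformed coordinates.
#' @export
kabsch_fit <- function(mobile, ref, fit_idx = seq_len(nrow(mobile))) {
  X <- mobile[fit_idx, , drop = FALSE]
  Y <- ref
  if (nrow(X) != nrow(Y)) abort("fit selections differ in size")
  if (nrow(X) < 3) abort("need at least 3 atoms for superposition")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(sweep(mobile, 2, cx) %*% t(R), 2, cy, "+")
}

#' Minimum-image displacement
#'
#' Applies the minimum-image convention to displacement vectors under an
#' orthorhombic box.  With `box = NULL` displacements pass through.
#'
#' @param d n-by-3 matrix (or length-3 vector) of displacements, nm.
#' @param box length-3 box vector, nm, or NULL.
#' @return displacements mapped to the nearest periodic image.
#' @export
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - sweep_box * round(d / sweep_box)
  } else {
    d - box * round(d / box)
  }
}

#' @keywords internal
pair_distance <- function(p1, p2, box = NULL) {
  d <- if (is.matrix(p1)) p2 - p1 else matrix(p2 - p1, ncol = 3)
  d <- min_image(d, box)
  sqrt(rowSums(d^2))
}

# rotate points about an axis (Rodrigues), axis through `origin`
#' @keywords internal
rotate_about_axis <- function(pts, origin, axis, angle_deg) {
  k <- unitv(axis)
  th <- angle_deg * pi / 180
  p <- sweep(pts, 2, origin)
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  sweep(p %*% t(R), 2, origin, "+")
}

#' @keywords internal
mass_com <- function(coords, masses) {
  colSums(coords * masses) / sum(masses)
}

#' @keywords internal
ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  sv <- svd(cc)
  list(centroid = centroid, normal = sv$v[, 3])
}

# standard error of the mean with n-1 denominator; NA for n < 2
#' @keywords internal
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
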