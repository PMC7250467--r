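# Pure geometric kernels shared by all descriptor families.  Interfaces use
# Angstroms and degrees; radians appear only inside function bodies.

DEG <- 180 / pi

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstroms).
#' @return Distance in Angstroms.
#' @export
vec_distance <- function(a, b) {
  d <- a - b
  sqrt(sum(d * d))
}

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at a vertex
#'
#' Angle between the rays vertex->a and vertex->c.
#'
#' @param a,vertex,c3 Numeric 3-vectors.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vec_angle <- function(a, vertex, c3) {
  u <- a - vertex
  v <- c3 - vertex
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: zero-length ray in angle computation",
         call. = FALSE)
  ct <- sum(u * v) / (nu * nv)
  ct <- max(-1, min(1, ct))
  acos(ct) * DEG
}

#' Signed dihedral angle
#'
#' IUPAC sign convention: cis = 0 degrees, trans = 180 degrees.  Computed with
#' the atan2 form, which is well conditioned near 0 and 180.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Signed angle in degrees, in (-180, 180\].
#' @export
vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10)
    stop("degenerate geometry: collinear points in dihedral", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(vec_cross(n1, n2) * b2) / vec_norm(b2)
  ang <- atan2(y, x) * DEG
  # map -180 to +180 so the range is (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares plane frame of an aromatic ring
#'
#' Builds the reference frame of a 5- or 6-membered ring: centroid, unit
#' normal from a least-squares plane fit (robust to slight puckering), and
#' the ring atoms expressed as 2-D coordinates in an orthonormal in-plane
#' basis.  The normal sign is chosen so the ring atoms wind counter-clockwise
#' when viewed from the +normal side.
#'
#' @param coords Numeric matrix, one row per ring atom (5 or 6 rows), columns
#'   x, y, z in Angstroms, in ring-bond order.
#' @return Object of class `ring_frame`: list with `centroid` (3-vector),
#'   `normal` (unit 3-vector), `basis` (3 x 2 matrix of in-plane axes) and
#'   `coords2d` (n x 2 matrix of in-plane ring coordinates).
#' @export
ring_frame <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!(n %in% c(5L, 6L))) stop("ring must have 5 or 6 atoms", call. = FALSE)
  centroid <- unname(colMeans(coords))
  centred <- sweep(coords, 2, centroid)
  sv <- svd(centred)
  if (sv$d[2] < 1e-8)
    stop("degenerate geometry: collinear ring atoms", call. = FALSE)
  normal <- sv$v[, 3]
  e1 <- sv$v[, 1]
  e2 <- sv$v[, 2]
  # enforce a right-handed (e1, e2, normal) frame so in-plane winding and
  # the normal direction are consistent
  if (sum(vec_cross(e1, e2) * normal) < 0) normal <- -normal
  xy <- centred %*% cbind(e1, e2)
  dimnames(xy) <- NULL
  # signed area of the projected polygon: positive means counter-clockwise
  i2 <- c(2:n, 1L)
  area2 <- sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])
  if (area2 < 0) {
    normal <- -normal
    e2 <- -e2
    xy[, 2] <- -xy[, 2]
  }
  structure(
    list(centroid = centroid, normal = normal,
         basis = cbind(e1, e2), coords2d = xy),
    class = "ring_frame")
}

# In-plane 2-D coordinates of an arbitrary point in a ring frame.
ring_project <- function(frame, point) {
  as.numeric(crossprod(frame$basis, point - frame$centroid))
}
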