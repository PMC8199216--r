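#' Geometric kernels for interaction detection
#'
#' Elementary geometry shared by all interaction detectors: ring centroids
#' and best-fit plane normals, normal/vector angles, Kabsch superposition
#' and plain (unfitted) RMSD. All coordinates are in Angstrom, all angles
#' in degrees.
#'
#' @name geometry
NULL

vnorm <- function(v) sqrt(sum(v * v))

#' Centroid, plane normal and planarity of an atom ring
#'
#' Computes the unweighted centroid of a set of ring atoms, the best-fit
#' plane normal (the direction of least variance of the centered
#' coordinates, i.e. the smallest principal axis), and the RMS
#' out-of-plane deviation of the ring atoms. Principal-axis fitting is
#' used rather than a two-edge cross product so that puckered rings get a
#' well-defined average plane.
#'
#' The sign of the normal is canonicalized: the component with the
#' largest absolute value is made positive (ties resolved x before y
#' before z). Downstream angle computations fold by absolute value, so
#' the sign never affects detector results.
#'
#' @param ring_coords numeric matrix (n x 3), n >= 3, ring atom
#'   coordinates in Angstrom.
#' @return list of class `ring_geometry` with elements `centroid`
#'   (3-vector), `normal` (unit 3-vector) and `planarity_rms` (Angstrom).
#' @examples
#' hexagon <- t(sapply(0:5, function(k)
#'   c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
#' ring_geometry(hexagon)
#' @export
ring_geometry <- function(ring_coords) {
  ring_coords <- as.matrix(ring_coords)
  if (nrow(ring_coords) < 3L || ncol(ring_coords) != 3L)
    stop_geometry("ring_geometry: need an n x 3 matrix with n >= 3, got %d x %d",
                  nrow(ring_coords), ncol(ring_coords))
  centroid <- colMeans(ring_coords)
  centered <- sweep(ring_coords, 2L, centroid)
  cov3 <- crossprod(centered) / nrow(centered)
  eig <- eigen(cov3, symmetric = TRUE)
  # collinear points: the two smallest eigenvalues both ~0 -> no plane
  if (eig$values[2L] <= 1e-12 * max(eig$values[1L], 1e-12))
    stop_geometry("ring_geometry: points are collinear or coincident; no plane is defined")
  normal <- eig$vectors[, 3L]
  normal <- normal / vnorm(normal)
  k <- which.max(abs(normal))          # ties: which.max takes the first (x<y<z)
  if (normal[k] < 0) normal <- -normal
  planarity_rms <- sqrt(mean(as.vector(centered %*% normal)^2))
  structure(list(centroid = centroid, normal = normal,
                 planarity_rms = planarity_rms),
            class = "ring_geometry")
}

#' Folded angle between a plane normal and a vector
#'
#' Returns `acos(|n . v_hat|)` in degrees, always in \[0, 90\]. Folding by
#' the absolute value of the dot product makes the result independent of
#' the (arbitrary) sign of the plane normal: 0 means the vector is along
#' the ring axis, 90 means it lies in the ring plane.
#'
#' @param normal unit 3-vector (plane normal).
#' @param v 3-vector, non-zero.
#' @return angle in degrees in \[0, 90\].
#' @export
angle_vector_to_normal <- function(normal, v) {
  nv <- vnorm(v)
  if (nv == 0) stop_geometry("angle_vector_to_normal: zero-length vector")
  nn <- vnorm(normal)
  if (nn == 0) stop_geometry("angle_vector_to_normal: zero-length normal")
  cosang <- abs(sum(normal * v)) / (nn * nv)
  acos(min(1, cosang)) * 180 / pi
}

#' Interior angle at a vertex (degrees)
#'
#' Angle a-b-c at vertex `b`, in \[0, 180\]. Used for the
#' donor-hydrogen-acceptor hydrogen-bond angle.
#' @param a,b,c 3-vectors.
#' @return angle in degrees.
#' @export
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0)
    stop_geometry("vertex_angle: coincident atoms give an undefined angle")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' RMSD between `mobile` and `reference`, by SVD of the cross-covariance
#' of the centered coordinate sets with the usual determinant-sign
#' correction. The fitted coordinates are
#' `sweep(mobile, 2, mobile_center) %*% rotation + reference_center`.
#'
#' @param mobile,reference numeric matrices (n x 3), n >= 3, matched rows.
#' @return list of class `kabsch_fit`: `rotation` (3 x 3, det +1),
#'   `translation` (3-vector: `fitted = mobile %*% rotation + translation`),
#'   `fitted` (n x 3 transformed mobile coordinates) and `rmsd`
#'   (post-fit RMSD, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop_geometry("kabsch_superpose: point counts differ (%d vs %d)",
                  nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3L)
    stop_geometry("kabsch_superpose: need at least 3 points, got %d", nrow(mobile))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2L, cm)
  y <- sweep(reference, 2L, cr)
  s <- svd(crossprod(x, y))            # H = X'Y ; R = U diag(1,1,d) V'
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- x %*% rot
  fitted <- sweep(fitted, 2L, cr, FUN = "+")
  trans <- as.vector(cr - cm %*% rot)
  structure(list(rotation = rot, translation = trans, fitted = fitted,
                 rmsd = rmsd_coords(fitted, reference)),
            class = "kabsch_fit")
}

#' Root-mean-square deviation of matched coordinates
#'
#' Plain RMSD over matched atom pairs: `sqrt(mean(|a_i - b_i|^2))`.
#' No superposition is performed; combine with [kabsch_superpose()] for
#' fitted RMSD.
#'
#' @param coords_a,coords_b numeric matrices (n x 3), matched rows.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)))
    stop_geometry("rmsd_coords: point counts differ (%d vs %d)",
                  nrow(coords_a), nrow(coords_b))
  if (nrow(coords_a) < 1L) stop_geometry("rmsd_coords: empty coordinate sets")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat("Ring geometry\n")
  cat(sprintf("  centroid:      (%.3f, %.3f, %.3f) A\n",
              x$centroid[1], x$centroid[2], x$centroid[3]))
  cat(sprintf("  normal:        (%.4f, %.4f, %.4f)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  planarity RMS: %.4f A\n", x$planarity_rms))
  invisible(x)
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("Kabsch superposition: %d atoms, fitted RMSD %.4f A\n",
              nrow(x$fitted), x$rmsd))
  invisible(x)
}
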