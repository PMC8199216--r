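# Shared fixtures: random rigid motions, ring builders, and independent
# straight-from-the-criteria oracle detectors used for dual-route checks.

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

apply_rigid <- function(coords, rot, trans) {
  sweep(as.matrix(coords) %*% t(rot), 2, trans, FUN = "+")
}

hexagon_at <- function(center = c(0, 0, 0), radius = 1.39) {
  t(sapply(0:5, function(k)
    center + c(radius * cos(k * pi / 3), radius * sin(k * pi / 3), 0)))
}

# planar ring with random placement/orientation; returns ring coords and
# its exact axis (unit normal) and centroid
random_planar_ring <- function() {
  rot <- random_rotation()
  cen <- runif(3, -10, 10)
  ring <- apply_rigid(hexagon_at(), rot, cen)
  list(ring = ring, centroid = cen, normal = rot %*% c(0, 0, 1))
}

deg <- function(rad) rad * 180 / pi

# ---- oracle detectors: literal transcriptions of the criteria -------------

oracle_hbond <- function(d, h, a, intramolecular = FALSE) {
  cutoff <- if (intramolecular) 3.5 else 3.0
  dda <- sqrt(sum((d - a)^2))
  u <- d - h; v <- a - h
  ang <- deg(acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
  (dda <= cutoff) && (ang >= 135)
}

oracle_salt_bridge <- function(oxy, nit) {
  dmin <- Inf
  for (i in seq_len(nrow(oxy)))
    for (j in seq_len(nrow(nit)))
      dmin <- min(dmin, sqrt(sum((oxy[i, ] - nit[j, ])^2)))
  dmin <= 4.0
}

# planar-ring oracle: normal from a two-edge cross product
oracle_ring_axis <- function(ring) {
  cen <- colMeans(ring)
  n <- pracma_cross(ring[1, ] - cen, ring[2, ] - cen)
  list(centroid = cen, normal = n / sqrt(sum(n^2)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

oracle_cation_pi <- function(cation, ring) {
  g <- oracle_ring_axis(ring)
  v <- cation - g$centroid
  d <- sqrt(sum(v^2))
  ang <- deg(acos(abs(sum(g$normal * v)) / d))
  (d <= 6.0) && (ang <= 45)
}

oracle_pi_pi <- function(ring_a, ring_b) {
  ga <- oracle_ring_axis(ring_a); gb <- oracle_ring_axis(ring_b)
  d <- sqrt(sum((ga$centroid - gb$centroid)^2))
  ang <- deg(acos(min(1, abs(sum(ga$normal * gb$normal)))))
  (d <= 5.5) && (ang <= 30)
}
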