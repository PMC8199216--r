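test_that("ring geometry of a regular hexagon is exact by symmetry", {
  hx <- hexagon_at(radius = 1.4)
  g <- ring_geometry(hx)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(g$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(g$planarity_rms, 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(g$normal^2)), 1, tolerance = 1e-9)

  g2 <- ring_geometry(sweep(hx, 2, c(5, 5, 5), FUN = "+"))
  expect_equal(g2$centroid, c(5, 5, 5), tolerance = 1e-12)
  expect_equal(abs(g2$normal), abs(g$normal), tolerance = 1e-12)
})

test_that("planarity RMS of a puckered ring matches a direct plane-fit oracle", {
  hx <- hexagon_at(radius = 1.4)
  hx[1, 3] <- hx[1, 3] + 0.1
  g <- ring_geometry(hx)
  # oracle: numerical minimization of RMS out-of-plane distance over
  # plane orientation (spherical angles), plane through the centroid
  cen <- colMeans(hx)
  centered <- sweep(hx, 2, cen)
  obj <- function(p) {
    n <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    sqrt(mean((centered %*% n)^2))
  }
  opt <- optim(c(0.01, 0.01), obj, control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(g$planarity_rms, opt$value, tolerance = 1e-9)
  expect_gt(g$planarity_rms, 0)
})

test_that("degenerate rings are rejected", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(ring_geometry(line), class = "plifr_geometry_error")
  expect_error(ring_geometry(hexagon_at()[1:2, ]), class = "plifr_geometry_error")
})

test_that("angle to normal is folded into [0, 90] and sign-blind", {
  n <- c(0, 0, 1)
  expect_equal(angle_vector_to_normal(n, c(0, 0, 3)), 0)
  expect_equal(angle_vector_to_normal(n, c(3, 0, 0)), 90)
  expect_equal(angle_vector_to_normal(n, c(3, 0, 3)), 45, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    v <- rnorm(3)
    a <- angle_vector_to_normal(n, v)
    expect_gte(a, 0); expect_lte(a, 90)
    expect_equal(angle_vector_to_normal(-n, v), a, tolerance = 1e-12)
  }
  expect_error(angle_vector_to_normal(n, c(0, 0, 0)),
               class = "plifr_geometry_error")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(21)
  x <- matrix(rnorm(30, sd = 3), ncol = 3)
  k0 <- kabsch_superpose(x, x)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(k0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(k0$rmsd, 0, tolerance = 1e-9)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
  y <- apply_rigid(x, rot90, c(2, -1, 4))
  k <- kabsch_superpose(x, y)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_equal(k$fitted, y, tolerance = 1e-9)
})

test_that("fitted RMSD on noisy clouds matches brute-force quaternion search", {
  set.seed(22)
  x <- matrix(rnorm(30, sd = 3), ncol = 3)
  y <- apply_rigid(x, random_rotation(), runif(3, -5, 5)) +
    matrix(rnorm(30, sd = 0.1), ncol = 3)
  k <- kabsch_superpose(x, y)

  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  obj <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; a <- q[2]; b <- q[3]; c <- q[4]
    R <- matrix(c(1 - 2 * (b^2 + c^2), 2 * (a * b - w * c), 2 * (a * c + w * b),
                  2 * (a * b + w * c), 1 - 2 * (a^2 + c^2), 2 * (b * c - w * a),
                  2 * (a * c - w * b), 2 * (b * c + w * a), 1 - 2 * (a^2 + b^2)),
                nrow = 3, byrow = TRUE)
    sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(100 + s)
    o <- optim(rnorm(4), obj, control = list(reltol = 1e-15, maxit = 10000))
    best <- min(best, o$value)
  }
  expect_equal(k$rmsd, best, tolerance = 1e-6)
  # independent library route must agree too
  fit <- bio3d::fit.xyz(fixed = as.vector(t(y)), mobile = as.vector(t(x)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(k$rmsd,
               sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - y)^2))),
               tolerance = 1e-8)
})

test_that("plain RMSD follows the direct formula", {
  x <- matrix(rnorm(15), ncol = 3)
  expect_equal(rmsd_coords(x, x), 0)
  expect_equal(rmsd_coords(x, sweep(x, 2, c(3, 4, 0), FUN = "+")), 5)
  set.seed(23)
  y <- matrix(rnorm(15), ncol = 3)
  expect_equal(rmsd_coords(x, y), sqrt(mean(rowSums((x - y)^2))))
  expect_error(rmsd_coords(x, y[1:3, ]), class = "plifr_geometry_error")
})

test_that("geometry kernels are invariant/equivariant under rigid motion", {
  set.seed(24)
  for (i in 1:20) {
    rot <- random_rotation(); tr <- runif(3, -20, 20)
    ring <- random_planar_ring()$ring
    ring[3, ] <- ring[3, ] + rnorm(3, sd = 0.05)   # slight pucker
    v <- rnorm(3)
    g1 <- ring_geometry(ring)
    g2 <- ring_geometry(apply_rigid(ring, rot, tr))
    expect_equal(g2$centroid, as.vector(apply_rigid(rbind(g1$centroid), rot, tr)),
                 tolerance = 1e-8)
    expect_equal(g2$planarity_rms, g1$planarity_rms, tolerance = 1e-8)
    expect_equal(angle_vector_to_normal(g2$normal, as.vector(rot %*% v)),
                 angle_vector_to_normal(g1$normal, v), tolerance = 1e-8)
    x <- matrix(rnorm(21), ncol = 3); y <- matrix(rnorm(21), ncol = 3)
    expect_equal(rmsd_coords(apply_rigid(x, rot, tr), apply_rigid(y, rot, tr)),
                 rmsd_coords(x, y), tolerance = 1e-8)
  }
})
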