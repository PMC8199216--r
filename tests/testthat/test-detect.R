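spec <- interaction_spec()

# place donor-H-acceptor with given D-A distance and D-H-A vertex angle
hbond_geom <- function(d_da, angle_deg) {
  h <- c(0, 0, 0)
  d <- c(0, 0, 1)
  # acceptor direction at `angle_deg` from the H->D direction, length set
  # so that |D - A| = d_da
  th <- angle_deg * pi / 180
  dir <- c(sin(th), 0, cos(th))
  # solve |d - r*dir| = d_da for r > 0
  b <- -2 * sum(d * dir); c0 <- sum(d * d) - d_da^2
  r <- (-b + sqrt(b^2 - 4 * c0)) / 2
  list(donor = d, hydrogen = h, acceptor = r * dir)
}

test_that("hydrogen-bond criterion: distance and angle both gate", {
  g <- hbond_geom(2.8, 160)
  expect_true(detect_hbond(g$donor, g$hydrogen, g$acceptor, spec))
  g <- hbond_geom(2.8, 120)
  expect_false(detect_hbond(g$donor, g$hydrogen, g$acceptor, spec))
  # 3.2 A fails the 3.0 A protein-ligand cutoff but passes the extended
  # 3.5 A intramolecular cutoff
  g <- hbond_geom(3.2, 170)
  expect_false(detect_hbond(g$donor, g$hydrogen, g$acceptor, spec,
                            intramolecular = FALSE))
  expect_true(detect_hbond(g$donor, g$hydrogen, g$acceptor, spec,
                           intramolecular = TRUE))
  expect_warning(
    detect_hbond(c(0, 0, 3), c(0, 0, 1), c(0, 0, 0), spec),
    "covalently plausible")
})

test_that("salt bridge takes the minimum over all O-N pairs, inclusive", {
  o <- rbind(c(0, 0, 0))
  expect_true(detect_salt_bridge(o, rbind(c(0, 0, 3.9)), spec))
  n2 <- rbind(c(0, 0, 4.5), c(0, 4.2, 0))
  expect_false(detect_salt_bridge(o, n2, spec))
  expect_true(detect_salt_bridge(o, rbind(n2, c(4.0, 0, 0)), spec))
  # both carboxylate oxygens vs both amidine nitrogens: brute-force min
  set.seed(41)
  for (i in 1:50) {
    oxy <- matrix(runif(6, -3, 3), ncol = 3)
    nit <- matrix(runif(6, -3, 3) + c(2, 0, 0), ncol = 3)
    expect_identical(detect_salt_bridge(oxy, nit, spec),
                     oracle_salt_bridge(oxy, nit))
  }
  expect_error(detect_salt_bridge(o[0, , drop = FALSE], n2),
               class = "plifr_config_error")
})

test_that("cation-pi applies distance and axis-angle criteria", {
  ring <- hexagon_at()
  expect_true(detect_cation_pi(c(0, 0, 3), ring, spec))       # on axis
  expect_false(detect_cation_pi(c(3, 0, 0), ring, spec))      # in plane: 90 deg
  # analytic 45 deg at distance sqrt(18): inclusive boundary
  expect_true(detect_cation_pi(c(3, 0, 3), ring, spec))
  expect_false(detect_cation_pi(c(0, 0, 6.5), ring, spec))    # too far
  expect_error(detect_cation_pi(c(0, 0, 3), ring[1:4, ], spec),
               class = "plifr_geometry_error")
})

test_that("pi-pi matches parallel stacks and rejects perpendicular or distant rings", {
  a <- hexagon_at()
  b <- hexagon_at(center = c(0, 0, 3.8))
  expect_true(detect_pi_pi(a, b, spec))
  perp <- apply_rigid(hexagon_at(),
                      matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, byrow = TRUE),
                      c(0, 0, 3.8))
  expect_false(detect_pi_pi(a, perp, spec))
  offset <- hexagon_at(center = c(6, 0, 0))
  expect_false(detect_pi_pi(a, offset, spec))
})

test_that("fused-ring roles OR-reduce: either ring may satisfy the criteria", {
  six <- hexagon_at()
  five <- apply_rigid(hexagon_at(center = c(12, 0, 0))[1:5, ], diag(3), c(0, 0, 0))
  cation <- c(0, 0, 3.5)   # satisfies only the six-ring
  expect_false(detect_cation_pi(cation, five, spec))
  expect_true(detect_cation_pi(cation, list(five, six), spec))
  expect_true(detect_cation_pi(cation, list(six, five), spec))
})

test_that("detectors are invariant under rigid motion of the whole frame", {
  set.seed(42)
  for (i in 1:40) {
    rot <- random_rotation(); tr <- runif(3, -15, 15)
    g <- hbond_geom(runif(1, 2.2, 4.2), runif(1, 100, 175))
    expect_identical(
      detect_hbond(g$donor, g$hydrogen, g$acceptor, spec),
      detect_hbond(as.vector(apply_rigid(rbind(g$donor), rot, tr)),
                   as.vector(apply_rigid(rbind(g$hydrogen), rot, tr)),
                   as.vector(apply_rigid(rbind(g$acceptor), rot, tr)), spec))
    ring <- random_planar_ring()
    cat1 <- ring$centroid + runif(1, 3, 8) * rnorm(3) / sqrt(3)
    expect_identical(
      detect_cation_pi(cat1, ring$ring, spec),
      detect_cation_pi(as.vector(apply_rigid(rbind(cat1), rot, tr)),
                       apply_rigid(ring$ring, rot, tr), spec))
  }
})

test_that("with angles fixed, growing separation can only turn events off", {
  ring <- hexagon_at()
  dists <- seq(2, 9, by = 0.25)
  res <- vapply(dists, function(d)
    detect_cation_pi(c(0, 0, d), ring, spec), logical(1))
  expect_false(any(diff(res) > 0))   # no FALSE -> TRUE as distance grows
  res_sb <- vapply(dists, function(d)
    detect_salt_bridge(rbind(c(0, 0, 0)), rbind(c(0, 0, d)), spec), logical(1))
  expect_false(any(diff(res_sb) > 0))
  res_hb <- vapply(dists, function(d) {
    g <- hbond_geom(d, 170)
    detect_hbond(g$donor, g$hydrogen, g$acceptor, spec)
  }, logical(1))
  expect_false(any(diff(res_hb) > 0))
})

test_that("evaluate_channel follows planted per-frame geometry", {
  atoms <- data.frame(serial = 1:2, name = c("OD1", "NH1"),
                      element = c("O", "N"), resname = c("ASP", "LIG"),
                      resno = c(184L, 1L), chain = "A",
                      stringsAsFactors = FALSE)
  z <- c(3.5, 4.6, 3.2, 5.0)   # alternate in/out of the 4 A cutoff
  xyz <- array(0, dim = c(2, 3, 4))
  for (f in 1:4) xyz[2, 3, f] <- z[f]
  traj <- trajectory(atoms, xyz)
  ch <- channel("salt_bridge", "sb", anion_oxygens = "ASP 184 OD1",
                cation_nitrogens = "LIG 1 NH1")
  expect_identical(evaluate_channel(traj, ch, spec), c(TRUE, FALSE, TRUE, FALSE))
  traj1 <- trajectory(atoms, xyz[, , 1, drop = FALSE])
  expect_identical(evaluate_channel(traj1, ch, spec), TRUE)
})

test_that("channel declarations validate their roles", {
  expect_error(channel("hbond", "x", donor = "a"), class = "plifr_config_error")
  expect_error(channel("salt_bridge", "x", anion_oxygens = "a",
                       cation_nitrogens = "b", bogus = "c"),
               class = "plifr_config_error")
  expect_error(channel("nope", "x"), "arg")
})
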