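test_that("toy complex reference geometry satisfies every channel with margin", {
  tpl <- make_toy_complex()
  traj <- trajectory(tpl$atoms, tpl$ref_coords)
  for (ch in tpl$channels)
    expect_true(evaluate_channel(traj, ch, tpl$spec), label = ch$label)
  m <- template_margins(tpl)
  expect_true(all(m$distance_margin >= 0.3))
  expect_true(all(m$angle_margin >= 5, na.rm = TRUE))
})

test_that("template survives a PDB round trip with identical detector results", {
  tpl <- make_toy_complex()
  traj <- simulate_trajectory(tpl, channel_plan(), n_frames = 25, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, f)
  back <- read_multimodel_pdb(f)
  for (ch in tpl$channels)
    expect_identical(evaluate_channel(back, ch, tpl$spec),
                     evaluate_channel(traj, ch, tpl$spec), label = ch$label)
})

test_that("planted probabilities 0 and 1 are recovered exactly", {
  tpl <- make_toy_complex()
  labels <- vapply(tpl$channels, function(ch) ch$label, character(1))
  p1 <- channel_plan(setNames(rep(1, length(labels)), labels))
  traj <- simulate_trajectory(tpl, p1, n_frames = 60, seed = 8)
  occ <- occupancy(build_event_matrix(traj, tpl$channels, tpl$spec))
  expect_equal(occ$occupancy_pct, rep(100, length(labels)), ignore_attr = TRUE)
  p0 <- channel_plan(setNames(rep(0, length(labels)), labels))
  traj0 <- simulate_trajectory(tpl, p0, n_frames = 60, seed = 8)
  occ0 <- occupancy(build_event_matrix(traj0, tpl$channels, tpl$spec))
  expect_equal(occ0$occupancy_pct, rep(0, length(labels)), ignore_attr = TRUE)
})

test_that("detected events equal the generator's planted states frame by frame", {
  tpl <- make_toy_complex()
  traj <- simulate_trajectory(tpl, channel_plan(), n_frames = 400, seed = 13)
  states <- attr(traj, "states")
  em <- build_event_matrix(traj, tpl$channels, tpl$spec)
  for (lab in colnames(states))
    expect_identical(unname(em[, lab]), unname(states[, lab]), label = lab)
})

test_that("planted occupancy converges to 100p on a probability grid", {
  tpl <- make_toy_complex()
  sb <- "amidine-Asp184 salt bridge"
  for (p in c(0.02, 0.31, 0.5, 0.94)) {
    traj <- simulate_trajectory(tpl, channel_plan(setNames(p, sb)),
                                n_frames = 10000, seed = 17)
    ev <- evaluate_channel(traj, tpl$channels[[3]], tpl$spec)
    se <- sqrt(p * (1 - p) / 10000) * 100
    expect_lt(abs(mean(ev) * 100 - 100 * p), 3 * se + 1e-9,
              label = sprintf("p = %.2f", p))
  }
})

test_that("generators are bitwise reproducible and order-stable by seed", {
  tpl <- make_toy_complex()
  t1 <- simulate_trajectory(tpl, channel_plan(), n_frames = 30, seed = 99)
  t2 <- simulate_trajectory(tpl, channel_plan(), n_frames = 30, seed = 99)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- simulate_trajectory(tpl, channel_plan(), n_frames = 30, seed = 100)
  expect_false(identical(t1$xyz, t3$xyz))
  # per-channel streams are keyed by label, not position: reordering the
  # plan leaves the realization unchanged
  pl <- channel_plan()
  pl_rev <- channel_plan(rev(pl$probs))
  t4 <- simulate_trajectory(tpl, pl_rev, n_frames = 30, seed = 99)
  expect_identical(t1$xyz, t4$xyz)

  expect_identical(simulate_scores(seed = 12), simulate_scores(seed = 12))
  expect_identical(simulate_dose_response(seed = 12),
                   simulate_dose_response(seed = 12))
  expect_false(identical(simulate_dose_response(seed = 12),
                         simulate_dose_response(seed = 13)))
})

test_that("OFF frames can never satisfy their channel", {
  tpl <- make_toy_complex()
  traj <- simulate_trajectory(tpl, channel_plan(), n_frames = 300, seed = 23)
  states <- attr(traj, "states")
  em <- build_event_matrix(traj, tpl$channels, tpl$spec)
  for (lab in colnames(states))
    expect_false(any(em[!states[, lab], lab]), label = lab)
})

test_that("score generator honors its planted means in the degenerate limit", {
  tab <- simulate_scores(sd_active = 1e-12, sd_inactive = 1e-12, seed = 2)
  gs <- group_summary(tab)
  expect_equal(gs$mean, c(-76.3, -60.35), tolerance = 1e-6)
  expect_equal(attr(gs, "gap"), 15.95, tolerance = 1e-6)
  empty <- simulate_scores(n_inactive = 0, seed = 2)
  expect_equal(sum(empty$activity == "inactive"), 0)
  expect_error(group_summary(empty), class = "plifr_data_error")
})

test_that("dose-response generator sits on the curve at zero noise", {
  d <- simulate_dose_response(noise_sd = 0, seed = 1)
  mu <- fourpl(d$concentration, 182.6e-9, 1, 100, 0)
  expect_equal(d$inhibition, mu, tolerance = 1e-12)
  # analytic midpoint at x = IC50
  expect_equal(fourpl(182.6e-9, 182.6e-9, 1, 100, 0), 50)
  d2 <- simulate_dose_response(seed = 31)
  fit <- fit_4pl(d2$concentration, d2$inhibition)
  expect_lt(abs(coef(fit)[["ic50"]] - 182.6e-9) / 182.6e-9, 0.10)
})

test_that("plans referencing unknown channels are rejected", {
  tpl <- make_toy_complex()
  expect_error(simulate_trajectory(tpl, channel_plan(c(nope = 0.5)), 10, 1),
               class = "plifr_config_error")
  expect_error(channel_plan(c(0.5)), class = "plifr_config_error")
  expect_error(channel_plan(c(a = 1.2)), class = "plifr_config_error")
})
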