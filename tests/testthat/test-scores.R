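tab_of <- function(act, ina, kind = "k") {
  score_table(compound = c(paste0("a", seq_along(act)), paste0("i", seq_along(ina))),
              score = c(act, ina),
              activity = rep(c("active", "inactive"), c(length(act), length(ina))),
              kind = kind)
}

test_that("group summary: means, gap and degenerate single-member groups", {
  gs <- group_summary(tab_of(c(-12, -13), c(-9, -10)))
  expect_equal(gs$mean, c(-12.5, -9.5))
  expect_equal(attr(gs, "gap"), 3)
  expect_true(all(gs$min <= gs$q1 & gs$q1 <= gs$median &
                    gs$median <= gs$q3 & gs$q3 <= gs$max))
  g1 <- group_summary(tab_of(-7.5, -3))
  expect_equal(unlist(g1[1, c("min", "q1", "median", "q3", "max")]),
               rep(-7.5, 5), ignore_attr = TRUE)
  expect_error(group_summary(tab_of(numeric(0), -3)), "active",
               class = "plifr_data_error")
})

test_that("quartiles agree with a rank-interpolation oracle", {
  set.seed(71)
  for (rep in 1:5) {
    act <- rnorm(20, -76, 4); ina <- rnorm(20, -60, 4)
    gs <- group_summary(tab_of(act, ina))
    for (g in 1:2) {
      x <- sort(if (g == 1) act else ina)
      n <- length(x)
      oracle_q <- function(p) {         # type-7: h = (n-1)p + 1
        h <- (n - 1) * p + 1
        lo <- floor(h)
        x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
      }
      expect_equal(gs$q1[g], oracle_q(0.25), tolerance = 1e-12)
      expect_equal(gs$median[g], oracle_q(0.5), tolerance = 1e-12)
      expect_equal(gs$q3[g], oracle_q(0.75), tolerance = 1e-12)
    }
  }
})

test_that("separation scan: clean splits, identical groups, interleaving", {
  sep <- separation_assessment(tab_of(c(-12, -13, -11), c(-9, -8)))
  expect_equal(sep$misclassified, 0L)
  expect_false(sep$overlap)
  expect_lt(sep$threshold, -9)
  expect_gt(sep$threshold, -11)

  same <- tab_of(c(-5, -6, -7), c(-5, -6, -7) + 1e-9)
  sep2 <- separation_assessment(tab_of(c(-5, -6, -7), c(-5, -6, -7)))
  expect_equal(sep2$misclassified, 3L)   # smaller group size
  expect_true(sep2$overlap)

  sep3 <- separation_assessment(tab_of(c(-5, -4), c(-4.5, -3)))
  expect_equal(sep3$misclassified, 1L)
})

test_that("separation scan equals brute-force enumeration over all thresholds", {
  set.seed(72)
  for (rep in 1:20) {
    n_a <- sample(2:20, 1); n_i <- sample(2:20, 1)
    act <- round(rnorm(n_a, -10, 3), 2); ina <- round(rnorm(n_i, -7, 3), 2)
    tab <- tab_of(act, ina)
    sep <- separation_assessment(tab)
    thr_grid <- seq(min(tab$score) - 1, max(tab$score) + 1, length.out = 4001)
    dir_below <- mean(act) <= mean(ina)
    mis <- vapply(thr_grid, function(t) {
      if (dir_below) sum(act > t) + sum(ina <= t)
      else sum(act < t) + sum(ina >= t)
    }, numeric(1))
    expect_equal(sep$misclassified, as.integer(min(mis)))
    expect_identical(sep$overlap, min(mis) > 0)
  }
})

test_that("gap, separation and overlap are shift-invariant", {
  set.seed(73)
  act <- rnorm(10, -76, 4); ina <- rnorm(4, -60, 4)
  base_gs <- group_summary(tab_of(act, ina))
  base_sep <- separation_assessment(tab_of(act, ina))
  for (k in c(-20, 13.7, 100)) {
    gs <- group_summary(tab_of(act + k, ina + k))
    sep <- separation_assessment(tab_of(act + k, ina + k))
    expect_equal(attr(gs, "gap"), attr(base_gs, "gap"), tolerance = 1e-9)
    expect_equal(sep$misclassified, base_sep$misclassified)
    expect_identical(sep$overlap, base_sep$overlap)
  }
})

test_that("score kinds are ranked by separation first, then gap", {
  sep_tab <- tab_of(c(-80, -75, -78), c(-62, -60), kind = "BFE")
  ovl_tab <- tab_of(c(-11.3, -11.0, -11.4), c(-11.2, -11.1), kind = "DS")
  cmp <- compare_score_kinds(list(BFE = sep_tab, DS = ovl_tab))
  expect_equal(cmp$kind, c("BFE", "DS"))
  expect_equal(cmp$rank, c(1L, 2L))
  # identical tables under two names: tie kept in input order, flagged
  cmp2 <- compare_score_kinds(list(first = sep_tab,
                                   second = { t2 <- sep_tab; t2$kind <- "k2"; t2 }))
  expect_equal(cmp2$kind[1], "BFE")
  expect_true(cmp2$tied_with_next[1])
  expect_error(compare_score_kinds(list(sep_tab)), class = "plifr_data_error")
})

test_that("two-Gaussian synthetic tables reproduce the BFE-vs-DS contrast", {
  bfe <- simulate_scores(seed = 4, kind = "BFE")        # gap ~ 15.95
  ds <- simulate_scores(mean_active = -11.37, mean_inactive = -11.22,
                        sd_active = 0.4, sd_inactive = 0.4,
                        seed = 4, kind = "DS")
  cmp <- compare_score_kinds(rbind(bfe, ds))
  expect_equal(cmp$kind[1], "BFE")
  expect_lt(cmp$misclassified[1], cmp$misclassified[2] + 1)
  expect_gt(cmp$gap[1], cmp$gap[2])
})

test_that("score tables validate labels and activities", {
  expect_error(score_table("a", -1, "maybe"), class = "plifr_data_error")
  expect_error(score_table(c("a", "a"), c(-1, -2), c("active", "inactive")),
               class = "plifr_data_error")
})
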