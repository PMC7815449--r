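test_that("2x2 tables cross-tabulate type against exposure correctly", {
  # 8 labelled nodes, statuses enumerated by hand
  ann <- data.frame(id = paste0("v", 1:8),
                    vaccine_related = c(T, T, T, F, F, F, F, F),
                    stance = c("anti", "pro", "pro", rep("none", 5)))
  net <- rec_network(ann)
  exposed <- setNames(c(T, T, F, T, F, F, F, F), ann$id)
  tab <- build_table(net, "vaccine_related", exposed)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 4))
  expect_equal(tab$a + tab$b + tab$c + tab$d, n_nodes(net))
  expect_warning(t0 <- build_table(net, "source=news", exposed), "no node")
  expect_equal(c(t0$a, t0$b), c(0, 0))
  t1 <- build_table(net, function(d) rep(TRUE, nrow(d)), exposed)
  expect_equal(c(t1$c, t1$d), c(0, 0))
})

test_that("odds ratio follows ad/bc with zero-cell conventions", {
  expect_equal(odds_ratio(two_by_two(5, 5, 5, 5)), 1)
  expect_equal(odds_ratio(two_by_two(10, 5, 2, 20)), 20)
  expect_equal(odds_ratio(two_by_two(0, 3, 15, 265)), 0)
  expect_equal(odds_ratio(two_by_two(3, 0, 15, 265)), Inf)
  expect_error(odds_ratio(two_by_two(0, 0, 5, 5)), "undefined")
  expect_error(two_by_two(-1, 2, 3, 4), "nonnegative")
})

test_that("Woolf interval matches the closed form evaluated by hand", {
  ci <- woolf_ci(two_by_two(10, 5, 2, 20))
  # ln 20 +/- 1.959964 * sqrt(1/10 + 1/5 + 1/2 + 1/20), evaluated beforehand
  expect_equal(ci$or_point, 20)
  expect_equal(ci$ci_low, 3.282925, tolerance = 1e-5)
  expect_equal(ci$ci_high, 121.842568, tolerance = 1e-5)
  expect_error(woolf_ci(two_by_two(0, 5, 2, 20)), "exact_ci")
})

test_that("Woolf interval is log-symmetric and shrinks with counts", {
  ci <- woolf_ci(two_by_two(100, 100, 100, 100))
  expect_equal(log(ci$ci_low), -log(ci$ci_high), tolerance = 1e-12)
  small <- woolf_ci(two_by_two(5, 5, 5, 5))
  big <- woolf_ci(two_by_two(50, 50, 50, 50))
  expect_gt(big$ci_low, small$ci_low)
  expect_lt(big$ci_high, small$ci_high)
})

test_that("exact conditional limits agree with the independent oracle", {
  set.seed(404)
  for (i in 1:25) {
    cells <- c(sample(0:8, 1), sample(1:10, 3))
    ci <- exact_ci(do.call(two_by_two, as.list(cells)))
    orc <- oracle_exact_limits(cells[1], cells[2], cells[3], cells[4])
    if (orc[["low"]] == 0) expect_equal(ci$ci_low, 0)
    else expect_equal(ci$ci_low, orc[["low"]], tolerance = 1e-6)
    if (is.finite(orc[["high"]]))
      expect_equal(ci$ci_high, orc[["high"]], tolerance = 1e-6)
    else expect_equal(ci$ci_high, Inf)
  }
})

test_that("exact conditional limits agree with fisher.test's inversion", {
  set.seed(11)
  for (i in 1:10) {
    cells <- sample(1:15, 4, replace = TRUE)
    ci <- exact_ci(do.call(two_by_two, as.list(cells)))
    ft <- fisher.test(matrix(cells[c(1, 2, 3, 4)], 2, byrow = TRUE))
    # fisher.test roots at its default (looser) tolerance, so compare
    # log-limits loosely; tightness against the grid oracle is tested above
    expect_equal(log(ci$ci_low), log(ft$conf.int[1]), tolerance = 1e-2)
    expect_equal(log(ci$ci_high), log(ft$conf.int[2]), tolerance = 1e-2)
  }
})

test_that("zero-cell tables get one-sided exact limits", {
  ci <- exact_ci(two_by_two(0, 3, 15, 265))
  expect_identical(ci$ci_low, 0)
  expect_true(is.finite(ci$ci_high) && ci$ci_high > 0)
  expect_equal(ci$or_point, 0)
  ci2 <- exact_ci(two_by_two(3, 0, 15, 265))
  expect_identical(ci2$ci_high, Inf)
  expect_true(ci2$ci_low > 0)
  expect_error(exact_ci(two_by_two(0, 0, 3, 4)), "row total")
  expect_error(exact_ci(two_by_two(0, 3, 0, 4)), "column total")
})

test_that("a 1/1/1/1 table yields an interval containing 1", {
  ci <- exact_ci(two_by_two(1, 1, 1, 1))
  expect_lt(ci$ci_low, 1)
  expect_gt(ci$ci_high, 1)
})

test_that("the exact interval contains the conditional MLE", {
  set.seed(77)
  for (i in 1:15) {
    cells <- sample(1:12, 4, replace = TRUE)
    tab <- do.call(two_by_two, as.list(cells))
    psi_hat <- conditional_mle(tab)
    ci <- exact_ci(tab)
    expect_gte(psi_hat, ci$ci_low)
    expect_lte(psi_hat, ci$ci_high)
  }
})

test_that("swapping rows or columns inverts the odds ratio", {
  set.seed(8)
  for (i in 1:10) {
    cells <- sample(1:20, 4, replace = TRUE)
    or <- odds_ratio(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    or_rows <- odds_ratio(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    or_cols <- odds_ratio(two_by_two(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(or * or_rows, 1, tolerance = 1e-12)
    expect_equal(or * or_cols, 1, tolerance = 1e-12)
  }
})

test_that("Woolf and exact limits converge on large tables", {
  set.seed(31)
  for (i in 1:8) {
    cells <- sample(50:400, 4, replace = TRUE)
    tab <- do.call(two_by_two, as.list(cells))
    w <- woolf_ci(tab); e <- exact_ci(tab)
    expect_lt(abs(log(w$ci_low) - log(e$ci_low)) /
                max(abs(log(e$ci_low)), 0.1), 0.05)
    expect_lt(abs(log(w$ci_high) - log(e$ci_high)) /
                max(abs(log(e$ci_high)), 0.1), 0.05)
  }
})

test_that("the Cornfield approximation tracks the exact limits", {
  for (cells in list(c(10, 5, 2, 20), c(8, 12, 6, 30), c(15, 15, 15, 15))) {
    tab <- do.call(two_by_two, as.list(cells))
    cf <- cornfield_ci(tab); e <- exact_ci(tab)
    expect_lt(abs(log(cf$ci_low) - log(e$ci_low)), 0.15)
    expect_lt(abs(log(cf$ci_high) - log(e$ci_high)), 0.15)
    expect_lt(cf$ci_low, cf$or_point)
    expect_gt(cf$ci_high, cf$or_point)
  }
  # zero cell: lower limit 0, finite upper
  cf0 <- cornfield_ci(two_by_two(0, 3, 15, 265))
  expect_identical(cf0$ci_low, 0)
  expect_true(is.finite(cf0$ci_high))
})

test_that("mid-P intervals are narrower than the exact equal-tail ones", {
  tab <- two_by_two(10, 5, 2, 20)
  e <- exact_ci(tab); m <- exact_ci(tab, midp = TRUE)
  expect_gt(m$ci_low, e$ci_low)
  expect_lt(m$ci_high, e$ci_high)
})

test_that("or_ci dispatches on the requested method", {
  tab <- two_by_two(10, 5, 2, 20)
  expect_equal(or_ci(tab)$method, "exact_conditional")
  expect_equal(or_ci(tab, "woolf")$method, "woolf")
  expect_equal(or_ci(tab, "cornfield_approx")$method, "cornfield_approx")
})
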