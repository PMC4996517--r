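test_that("GIDS reproduces hand-derived worked values", {
  expect_equal(compute_gids(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)), 1.0)
  expect_equal(compute_gids(matrix(c(4, 6, 2, 3), 2, byrow = TRUE)), 0.0)
  expect_equal(compute_gids(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.5)
  expect_equal(compute_gids(diag(3) * 2), 1.0)  # J = 3 perfect separation
  expect_error(compute_gids(matrix(c(3, 4, 0, 0), 2)), "degenerate phenotype")
})

test_that("IDS reproduces worked values and rejects bad tables", {
  expect_equal(compute_ids(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.5)
  expect_equal(compute_ids(independence_table()), 0.0)
  expect_equal(compute_ids(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)), 1.0)
  expect_error(compute_ids(diag(3)), "exactly two")
  expect_error(compute_ids(matrix(c(3, 1, 0, 0), 2)), "non-empty")
})

test_that("risk statuses follow the cross-product rule with ties to HIGH", {
  m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE, dimnames = list(NULL, c("case", "control")))
  expect_equal(unname(assign_risk_status(m, "case")), c("H", "L"))
  # row ratio exactly equal to the overall ratio -> HIGH
  m_tie <- matrix(c(2, 2, 3, 3), 2, byrow = TRUE)
  expect_equal(unname(assign_risk_status(m_tie, 1)), c("H", "H"))
  # zero controls in a row is well defined
  m_zero <- matrix(c(5, 0, 1, 4), 2, byrow = TRUE)
  expect_equal(unname(assign_risk_status(m_zero, 1))[1], "H")
})

test_that("confusion counts pool rows by risk and conserve class totals", {
  m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  cc <- confusion_counts(m, case_column = 1)
  expect_equal(cc, c(TP = 3, TN = 3, FN = 1, FP = 1))
  all_high <- confusion_counts(m, risk = c("H", "H"), case_column = 1)
  expect_equal(unname(all_high[c("FN", "TN")]), c(0, 0))
  all_low <- confusion_counts(m, risk = c("L", "L"), case_column = 1)
  expect_equal(unname(all_low[c("TP", "FP")]), c(0, 0))
  for (i in 1:20) {
    m <- random_two_class_table()
    cc <- confusion_counts(m, case_column = 2)
    expect_equal(unname(cc["TP"] + cc["FN"]), sum(m[, 2]))
    expect_equal(unname(cc["TN"] + cc["FP"]), sum(m[, 1]))
  }
})

test_that("balanced accuracy matches worked values", {
  expect_equal(compute_ba(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.75)
  expect_equal(compute_ba(independence_table()), 0.5)
  expect_equal(compute_ba(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)), 1.0)
})

test_that("chi-squared statistic matches worked values and is non-negative", {
  expect_equal(chi_square_statistic(matrix(c(4, 6, 2, 3), 2, byrow = TRUE)), 0.0)
  expect_equal(chi_square_statistic(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)), 20.0)
  for (i in 1:20) expect_gte(chi_square_statistic(random_two_class_table()), 0)
  # cross-check against the base implementation (no continuity correction)
  set.seed(3)
  for (i in 1:10) {
    m <- random_two_class_table(3) + 1
    expect_equal(chi_square_statistic(m),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = FALSE))$statistic))
  }
})

test_that("GIDS, IDS and 2*BA - 1 coincide on random two-class tables", {
  set.seed(17)
  for (i in 1:300) {
    m <- random_two_class_table(nrow = sample(2:9, 1))
    g <- compute_gids(m)
    d <- compute_ids(m)
    b <- compute_ba(m)
    expect_lt(abs(g - d), 1e-12)
    expect_lt(abs(d - (2 * b - 1)), 1e-12)
    expect_true(g >= 0 && g <= 1)
  }
})

test_that("GIDS is zero exactly at independence and invariant to permutation and scaling", {
  expect_equal(compute_gids(independence_table(c(1, 2, 5), c(3, 1))), 0)
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(sample(0:15, 12, replace = TRUE), 4, 3)
    if (any(sum(m) == 0) || sum(colSums(m) > 0) < 2) next
    g <- compute_gids(m)
    if (g == 0) expect_equal(unclass(expected_counts(m)), m, ignore_attr = TRUE)
    expect_equal(compute_gids(m[sample(4), ]), g)
    expect_equal(compute_gids(m[, sample(3)]), g)
    expect_equal(compute_gids(m * 7L), g)
  }
})
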