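printed_uum_table <- function() {
  # pupa types I-III against collapsed adult outcome, from the published
  # counts: 5/21, 18/23, 15/16 intersex adults
  new_contingency(matrix(c(16, 5, 5, 18, 1, 15), nrow = 3, byrow = TRUE,
                         dimnames = list(c("I", "II", "III"),
                                         c("normal", "intersex"))),
                  row_var = "pupa_type", col_var = "outcome")
}

test_that("contingency tables count collapsed record pairs exactly", {
  recs <- records_from_counts(list(I = c(5, 21), II = c(18, 23), III = c(15, 16)))
  tab <- build_contingency(recs, "pupa_type", "adult_class",
                           col_collapse = list(normal = 1:2, intersex = 3:5),
                           row_levels = c("I", "II", "III"),
                           col_levels = c("normal", "intersex"))
  expect_equal(unname(rowSums(tab$observed)), c(21, 23, 16))
  expect_equal(tab$observed, printed_uum_table()$observed, ignore_attr = TRUE)

  expect_error(build_contingency(recs[0, ], "pupa_type", "adult_class"),
               "empty")
  expect_error(build_contingency(recs, "pupa_type", "nope"), "nope")
})

test_that("missing adult records are excluded from tables", {
  recs <- records_from_counts(list(I = c(2, 5)))
  recs$adult_class[1] <- NA_integer_
  tab <- build_contingency(recs, "pupa_type", "adult_class",
                           col_collapse = list(normal = 1:2, intersex = 3:5))
  expect_equal(sum(tab$observed), 4)
})

test_that("row proportions reproduce the published percentages", {
  tab <- printed_uum_table()
  expect_equal(proportion(tab, "I", "intersex"), 23.81)
  expect_equal(proportion(tab, "II", "intersex"), 78.26)
  expect_equal(proportion(tab, "III", "intersex"), 93.75)
  expect_equal(proportion(tab, "I", "normal"), 76.19)
  zero <- new_contingency(matrix(c(0, 7, 3, 2), 2,
                                 dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(proportion(zero, "a", "x"), 0)
  expect_error(proportion(zero, "c", "x"), "no row")
})

test_that("Pearson X2 matches direct O/E arithmetic and an independent implementation", {
  o <- matrix(c(5, 16, 18, 5, 15, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("I", "II", "III"), c("x", "y")))
  tab <- new_contingency(o)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  hand <- sum((o - e)^2 / e)
  res <- pearson_chi2(tab)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  ref <- suppressWarnings(chisq.test(o, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-10)

  # O = E -> zero statistic, p = 1
  flat <- new_contingency(matrix(10, 2, 2))
  expect_equal(pearson_chi2(flat)$statistic, 0)
  expect_equal(pearson_chi2(flat)$p.value, 1)

  # homogeneity: doubling all cells doubles X2
  expect_equal(pearson_chi2(new_contingency(2 * o))$statistic,
               2 * res$statistic, tolerance = 1e-12)
})

test_that("G statistic matches its formula and agrees with X2 asymptotically", {
  o <- matrix(c(5, 16, 18, 5, 15, 1), nrow = 3, byrow = TRUE)
  tab <- new_contingency(o)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  hand <- 2 * sum(o * log(o / e))
  res <- g_test(tab)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(g_test(new_contingency(matrix(10, 2, 2)))$statistic, 0)

  set.seed(14)
  for (i in 1:10) {
    probs <- c(0.3, 0.2, 0.25, 0.25) + runif(4, 0, 0.15)
    probs <- probs / sum(probs)
    big <- matrix(rmultinom(1, 40000, probs), 2)
    tb <- new_contingency(big)
    g <- g_test(tb)$statistic
    x2 <- pearson_chi2(tb)$statistic
    if (x2 > 1) expect_lt(abs(g - x2) / x2, 0.05)
  }
})

test_that("test p-values match an independent chi-square CDF to 1e-8", {
  o <- matrix(c(5, 16, 18, 5, 15, 1), nrow = 3, byrow = TRUE)
  for (res in list(pearson_chi2(new_contingency(o)), g_test(new_contingency(o)))) {
    # chi-square(df) upper tail via the gamma distribution
    p_gamma <- stats::pgamma(res$statistic, shape = res$df / 2, rate = 1 / 2,
                             lower.tail = FALSE)
    expect_lt(abs(res$p.value - p_gamma), 1e-8)
  }
})

test_that("statistics are invariant to row/column permutation and df guards hold", {
  o <- matrix(c(5, 16, 18, 5, 15, 1), nrow = 3, byrow = TRUE)
  perm <- o[c(3, 1, 2), c(2, 1)]
  expect_equal(pearson_chi2(new_contingency(perm))$statistic,
               pearson_chi2(new_contingency(o))$statistic, tolerance = 1e-12)
  expect_equal(g_test(new_contingency(perm))$statistic,
               g_test(new_contingency(o))$statistic, tolerance = 1e-12)
  expect_error(pearson_chi2(new_contingency(matrix(c(3, 4), 1))), "2x2")
})

test_that("tidy and glance methods expose test results and table shape", {
  tab <- printed_uum_table()
  td <- tidy(g_test(tab))
  expect_equal(names(td), c("statistic", "df", "p.value", "method"))
  long <- tidy(tab)
  expect_equal(nrow(long), 6)
  expect_true(all(c("pupa_type", "outcome", "observed", "row_prop") %in% names(long)))
  expect_equal(glance(tab)$n, 60)
})
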