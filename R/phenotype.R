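#' Build a contingency table from phenotype records
#'
#' Counts non-missing (row, column) pairs, optionally after restricting the
#' rows and collapsing column categories into super-categories (e.g.
#' germline classes 3-5 into "intersex").
#'
#' @param records Tibble of per-individual records.
#' @param row_var,col_var Column names of the two categorical variables.
#' @param row_subset Optional vector of row categories to keep.
#' @param col_collapse Optional named list mapping a super-category to the
#'   original values it absorbs, e.g.
#'   `list(normal = 1:2, intersex = 3:5)`. Unmapped values keep their own
#'   label.
#' @param row_levels,col_levels Optional orderings for the table margins.
#' @return A list of class `ix_contingency`: integer matrix `observed`,
#'   numeric matrix `expected` (row x col margins / n), and the variable
#'   names.
#' @export
build_contingency <- function(records, row_var, col_var, row_subset = NULL,
                              col_collapse = NULL, row_levels = NULL,
                              col_levels = NULL) {
  records <- as_tibble(records)
  for (v in c(row_var, col_var)) {
    if (!v %in% names(records)) abort(paste0("no column '", v, "' in records"))
  }
  r <- records[[row_var]]
  c_ <- records[[col_var]]
  keep <- !is.na(r) & !is.na(c_)
  if (!is.null(row_subset)) keep <- keep & r %in% row_subset
  r <- as.character(r[keep])
  c_ <- c_[keep]
  if (!is.null(col_collapse)) {
    cc <- as.character(c_)
    for (super in names(col_collapse)) {
      cc[c_ %in% col_collapse[[super]]] <- super
    }
    c_ <- cc
  }
  c_ <- as.character(c_)
  if (length(r) == 0) abort("contingency table is empty (no usable records)")
  if (is.null(row_levels)) row_levels <- unique(r)
  if (is.null(col_levels)) col_levels <- unique(c_)
  observed <- table(factor(r, levels = row_levels),
                    factor(c_, levels = col_levels))
  observed <- unclass(observed)
  new_contingency(observed, row_var, col_var)
}

#' Construct a contingency object from an observed matrix
#'
#' @param observed Non-negative integer matrix of observed counts.
#' @param row_var,col_var Optional variable names for labeling.
#' @return An `ix_contingency`.
#' @export
new_contingency <- function(observed, row_var = "row", col_var = "col") {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed))) {
    abort("observed counts must be non-negative integers")
  }
  n <- sum(observed)
  if (n == 0) abort("contingency table has zero total")
  expected <- outer(rowSums(observed), colSums(observed)) / n
  structure(list(observed = observed, expected = expected,
                 row_var = row_var, col_var = col_var, n = n),
            class = "ix_contingency")
}

check_testable <- function(t) {
  stopifnot(inherits(t, "ix_contingency"))
  if (nrow(t$observed) < 2 || ncol(t$observed) < 2) {
    abort("association tests need at least a 2x2 table (df would be 0)")
  }
  invisible(t)
}

#' Pearson chi-square test of independence
#'
#' X^2 = sum (O - E)^2 / E with df = (rows - 1)(cols - 1) and an upper-tail
#' chi-square p-value. No continuity correction is applied; cells with zero
#' expectation are dropped from the sum with a warning.
#'
#' @param t An `ix_contingency`.
#' @return An `ix_ctest` (statistic, df, p.value, method); see [tidy()].
#' @export
pearson_chi2 <- function(t) {
  check_testable(t)
  o <- t$observed; e <- t$expected
  zero_e <- e == 0
  if (any(zero_e)) {
    warn(paste0(sum(zero_e), " cell(s) with zero expected count dropped from X^2"))
  }
  stat <- sum(((o - e)^2 / e)[!zero_e])
  df <- (nrow(o) - 1) * (ncol(o) - 1)
  new_ctest(stat, df, "Pearson chi-square")
}

#' Likelihood-ratio G-test of independence
#'
#' G = 2 sum O * ln(O / E) over cells with O > 0, with the same df and
#' p-value mapping as the Pearson test.
#'
#' @param t An `ix_contingency`.
#' @return An `ix_ctest`.
#' @export
g_test <- function(t) {
  check_testable(t)
  o <- t$observed; e <- t$expected
  pos <- o > 0
  stat <- 2 * sum((o * log(o / e))[pos])
  df <- (nrow(o) - 1) * (ncol(o) - 1)
  new_ctest(stat, df, "Likelihood-ratio G")
}

new_ctest <- function(stat, df, method) {
  structure(list(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = method),
            class = "ix_ctest")
}

#' @export
print.ix_ctest <- function(x, ...) {
  cat(x$method, " test: statistic = ", format(x$statistic, digits = 6),
      ", df = ", x$df, ", p = ", format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Row-wise percentage from a contingency table
#'
#' 100 x (sum of the selected cells) / (row total), reported to two
#' decimals — the form in which the pupa-to-adult feminization proportions
#' are quoted (e.g. 5 of 21 Type I pupae giving intersex adults = 23.81%).
#'
#' @param t An `ix_contingency`.
#' @param row Row label.
#' @param cols Column label(s) to sum.
#' @return Percentage, rounded to 2 decimals.
#' @export
proportion <- function(t, row, cols) {
  stopifnot(inherits(t, "ix_contingency"))
  o <- t$observed
  if (!row %in% rownames(o)) abort(paste0("no row '", row, "' in table"))
  bad <- setdiff(cols, colnames(o))
  if (length(bad) > 0) {
    abort(paste0("no column(s) ", paste(bad, collapse = ", "), " in table"))
  }
  total <- sum(o[row, ])
  if (total == 0) abort(paste0("row '", row, "' has zero total"))
  round(100 * sum(o[row, cols]) / total, 2)
}
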