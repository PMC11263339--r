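#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an association test result
#'
#' @param x An `ix_ctest`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @method tidy ix_ctest
#' @export
tidy.ix_ctest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @rdname tidy.ix_ctest
#' @method glance ix_ctest
#' @export
glance.ix_ctest <- function(x, ...) tidy(x, ...)

#' Tidy a contingency table into long counts
#'
#' @param x An `ix_contingency`.
#' @param ... Unused.
#' @return Tibble: row label, column label, `observed`, `expected`,
#'   `row_prop` (share of the row total).
#' @method tidy ix_contingency
#' @export
tidy.ix_contingency <- function(x, ...) {
  o <- x$observed
  out <- tidyr::expand_grid(row = rownames(o), col = colnames(o))
  out <- mutate(out,
                observed = as.integer(o[cbind(.data$row, .data$col)]),
                expected = x$expected[cbind(.data$row, .data$col)])
  grp <- group_by(out, .data$row)
  out <- ungroup(mutate(grp, row_prop = .data$observed / sum(.data$observed)))
  names(out)[1:2] <- c(x$row_var, x$col_var)
  out
}

#' @rdname tidy.ix_contingency
#' @method glance ix_contingency
#' @export
glance.ix_contingency <- function(x, ...) {
  tibble(n = x$n, rows = nrow(x$observed), cols = ncol(x$observed))
}

#' One-row summary of a DE comparison
#'
#' @param x An `ix_de` table.
#' @param t Thresholds used for the significance tally.
#' @param ... Unused.
#' @return Tibble: `comparison`, `n_genes`, `n_significant` (FDR at or below
#'   the cutoff and |log2FC| above the fold threshold), `n_all_zero`.
#' @method glance ix_de
#' @export
glance.ix_de <- function(x, t = thresholds(), ...) {
  tibble(comparison = attr(x, "comparison") %||% NA_character_,
         n_genes = nrow(x),
         n_significant = sum(x$fdr <= t$fdr & abs(x$log2fc) > t$lfc),
         n_all_zero = if ("all_zero" %in% names(x)) sum(x$all_zero) else NA_integer_)
}
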