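#' The five normal-versus-intersex comparisons
#'
#' For a tissue and a reference sex, the pattern analysis uses (in order):
#' U vs UUM, M vs UUM, UUM vs UUMix, U vs UUMix, M vs UUMix, where U and M
#' are the pure species, UUM the normal backcross of the reference sex and
#' UUMix the intersex backcross individuals. Orientation is second-listed
#' over first-listed, so in the last three comparisons positive log2 FC
#' means higher in intersexes.
#'
#' @param tissue `"reproductive"` or `"carcass"`.
#' @param reference_sex `"female"` or `"male"`: the normal sex whose samples
#'   anchor the comparisons (female-associated gene groups are profiled
#'   against normal females, male-associated against normal males).
#' @return Tibble: `slot` (1-5), `comparison_id`, `group_a`, `group_b`.
#' @export
pattern_plan <- function(tissue = c("reproductive", "carcass"),
                         reference_sex = c("female", "male")) {
  tissue <- match.arg(tissue)
  reference_sex <- match.arg(reference_sex)
  u <- group_id("U", reference_sex, tissue)
  m <- group_id("M", reference_sex, tissue)
  uum <- group_id("UUM", reference_sex, tissue)
  ix <- group_id("UUM", "intersex", tissue)
  plan <- tibble(slot = 1:5,
                 group_a = c(u, m, uum, u, m),
                 group_b = c(uum, uum, ix, ix, ix))
  mutate(plan, comparison_id = paste0(.data$group_b, "_over_", .data$group_a))
}

#' Elementary differential-expression call for one comparison
#'
#' `no_change` when -lfc < log2FC < lfc regardless of FDR, or |log2FC| >= lfc
#' with FDR above the cutoff; `up` when log2FC >= lfc with FDR at or below
#' the cutoff; `down` when log2FC <= -lfc with FDR at or below the cutoff.
#'
#' @param log2fc,fdr Numeric vectors (recycled together).
#' @param t An `ix_thresholds`.
#' @return Character vector of calls.
#' @export
classify_single <- function(log2fc, fdr, t = thresholds()) {
  if (any(is.na(log2fc)) || any(is.na(fdr))) {
    abort("classify_single: log2fc and fdr must not contain NA")
  }
  dplyr::case_when(
    log2fc > -t$lfc & log2fc < t$lfc ~ "no_change",
    fdr > t$fdr ~ "no_change",
    log2fc >= t$lfc ~ "up",
    TRUE ~ "down"
  )
}

#' Combine five elementary calls into a pattern label
#'
#' `no_change` when all five comparisons are no-change; `upregulation` /
#' `downregulation` when the first two (pure species vs normal backcross)
#' are no-change and the last three (normal vs intersex) are unanimously up
#' or down; `other` in every remaining case.
#'
#' @param calls Character vector of five calls, or a genes-by-5 matrix, in
#'   [pattern_plan()] slot order.
#' @return Character vector of pattern labels.
#' @export
classify_pattern <- function(calls) {
  if (is.null(dim(calls))) {
    if (length(calls) != 5) abort("exactly five elementary calls are required")
    calls <- matrix(calls, nrow = 1)
  }
  if (ncol(calls) != 5) abort("exactly five elementary calls are required")
  first_ok <- calls[, 1] == "no_change" & calls[, 2] == "no_change"
  last <- calls[, 3:5, drop = FALSE]
  all_nc <- rowSums(last == "no_change") == 3
  all_up <- rowSums(last == "up") == 3
  all_down <- rowSums(last == "down") == 3
  dplyr::case_when(
    first_ok & all_nc ~ "no_change",
    first_ok & all_up ~ "upregulation",
    first_ok & all_down ~ "downregulation",
    TRUE ~ "other"
  )
}

#' Per-gene pattern labels over a comparison set
#'
#' @param de_tables Named list of `ix_de` tables containing at least the
#'   five comparisons of `plan`.
#' @param plan A [pattern_plan()].
#' @param genes Optional gene ids to classify (e.g. one gene group); genes
#'   absent from any of the five tables are dropped with a warning.
#' @param t An `ix_thresholds`.
#' @return Tibble: `gene_id`, `call_1` .. `call_5`, `pattern`.
#' @export
classify_patterns <- function(de_tables, plan, genes = NULL, t = thresholds()) {
  missing <- setdiff(plan$comparison_id, names(de_tables))
  if (length(missing) > 0) {
    abort(paste0("missing DE table(s): ", paste(missing, collapse = ", ")))
  }
  tabs <- de_tables[plan$comparison_id]
  universe <- Reduce(intersect, lapply(tabs, function(x) x$gene_id))
  if (is.null(genes)) genes <- universe
  absent <- setdiff(genes, universe)
  if (length(absent) > 0) {
    warn(paste0("excluding ", length(absent),
                " gene(s) missing from at least one DE table: ",
                paste(head(absent, 5), collapse = ", ")))
    genes <- intersect(genes, universe)
  }
  calls <- vapply(tabs, function(tab) {
    i <- match(genes, tab$gene_id)
    classify_single(tab$log2fc[i], tab$fdr[i], t)
  }, character(length(genes)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(genes))
  out <- tibble(gene_id = genes)
  for (k in 1:5) out[[paste0("call_", k)]] <- calls[, k]
  out$pattern <- classify_pattern(calls)
  out
}

#' Count pattern labels within a gene group
#'
#' @param group_genes Character vector of gene ids (one gene group).
#' @param de_tables,plan,t See [classify_patterns()].
#' @return Tibble: `pattern`, `n` over the four labels (zeros included);
#'   the counts sum to the number of classifiable group members.
#' @export
summarize_patterns <- function(group_genes, de_tables, plan, t = thresholds()) {
  labels <- c("no_change", "upregulation", "downregulation", "other")
  if (length(group_genes) == 0) {
    return(tibble(pattern = labels, n = 0L))
  }
  pat <- classify_patterns(de_tables, plan, genes = group_genes, t = t)
  counts <- table(factor(pat$pattern, levels = labels))
  tibble(pattern = labels, n = as.integer(counts))
}
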