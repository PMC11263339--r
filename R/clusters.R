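#' Categorize genes of one pairwise comparison
#'
#' The threshold decision tree applied to each gene of a DE table:
#' \enumerate{
#'   \item both group-mean FPKM below `fpkm_low` -> `low`;
#'   \item otherwise, FDR above `fdr` or |log2 FC| at or below `lfc` ->
#'     `unbiased`;
#'   \item otherwise, the lower group mean below `fpkm_low` -> `specific`
#'     towards the higher group;
#'   \item otherwise -> `biased` towards the higher group.
#' }
#' Orientation only sets the direction, never the label.
#'
#' @param de An `ix_de` table (or any data frame with `gene_id`, `log2fc`,
#'   `fdr`, `mean_fpkm_a`, `mean_fpkm_b`).
#' @param t An `ix_thresholds`.
#' @param a_label,b_label Semantic names of the two sides (e.g. `"male"`,
#'   `"female"`), used to name the direction of specific/biased calls.
#' @return Tibble: `gene_id`, `category` (`low`/`unbiased`/`specific`/
#'   `biased`), `high` (the winning side's label, NA for low/unbiased).
#' @export
categorize_pair <- function(de, t = thresholds(), a_label = "A", b_label = "B") {
  de <- as_tibble(de)
  needed <- c("gene_id", "log2fc", "fdr", "mean_fpkm_a", "mean_fpkm_b")
  missing <- setdiff(needed, names(de))
  if (length(missing) > 0) {
    abort(paste0("DE table missing column(s): ", paste(missing, collapse = ", ")))
  }
  big_fc <- abs(de$log2fc) > t$lfc
  if (any(is.na(de$fdr) & big_fc)) {
    abort(paste0("missing FDR with |log2FC| above threshold for gene(s): ",
                 paste(head(de$gene_id[is.na(de$fdr) & big_fc], 5), collapse = ", ")))
  }
  lower <- pmin(de$mean_fpkm_a, de$mean_fpkm_b)
  upper <- pmax(de$mean_fpkm_a, de$mean_fpkm_b)
  category <- dplyr::case_when(
    upper < t$fpkm_low ~ "low",
    de$fdr > t$fdr | abs(de$log2fc) <= t$lfc ~ "unbiased",
    lower < t$fpkm_low ~ "specific",
    TRUE ~ "biased"
  )
  high <- ifelse(category %in% c("specific", "biased"),
                 ifelse(de$log2fc > 0, b_label, a_label), NA_character_)
  tibble(gene_id = de$gene_id, category = category, high = high)
}

#' The comparison plan behind the five expression clusters
#'
#' Pure-species samples only. REPRODUCTIVE_SEX and CARCASS_SEX compare males
#' with females within each species (two comparisons each);
#' REPRODUCTIVE_SPECIES and CARCASS_SPECIES compare the two species within
#' each sex (two each); TISSUE compares reproductive organs with carcass
#' within each species-by-sex combination (four).
#'
#' @return Tibble: `cluster`, `comparison_id`, `group_a`, `group_b`,
#'   `a_label`, `b_label`.
#' @export
cluster_plan <- function() {
  rows <- list()
  for (sp in c("U", "M")) {
    for (ti in .tissue_levels) {
      cl <- if (ti == "reproductive") "REPRODUCTIVE_SEX" else "CARCASS_SEX"
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl,
        group_a = group_id(sp, "male", ti), group_b = group_id(sp, "female", ti),
        a_label = "male", b_label = "female")
    }
  }
  for (sx in c("male", "female")) {
    for (ti in .tissue_levels) {
      cl <- if (ti == "reproductive") "REPRODUCTIVE_SPECIES" else "CARCASS_SPECIES"
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl,
        group_a = group_id("U", sx, ti), group_b = group_id("M", sx, ti),
        a_label = "U", b_label = "M")
    }
  }
  for (sp in c("U", "M")) {
    for (sx in c("male", "female")) {
      rows[[length(rows) + 1]] <- tibble(
        cluster = "TISSUE",
        group_a = group_id(sp, sx, "reproductive"),
        group_b = group_id(sp, sx, "carcass"),
        a_label = "reproductive", b_label = "carcass")
    }
  }
  plan <- bind_rows(rows)
  mutate(plan, comparison_id = paste0(.data$group_b, "_over_", .data$group_a))
}

#' Combine a cluster's pairwise categories into a membership subtype
#'
#' A gene called `low` in every constituent comparison is `low` and excluded
#' from the cluster entirely. Comparisons that call the gene `low` are
#' otherwise uninformative (the gene is unexpressed on both sides there, as
#' happens for the silent sex's tissue comparisons of a sex-specific gene)
#' and are ignored. Over the informative comparisons the default
#' all-consistent rule gives `<label>_specific` when every one calls the
#' gene specific towards the same side, `<label>_biased` when every one
#' calls it specific or biased towards the same side with at least one
#' biased call, and `none` otherwise; conflicting directions always yield
#' `none`. The `any` rule instead requires only that at least one
#' informative comparison is specific/biased (none unbiased directions
#' conflicting).
#'
#' @param pair_categories Named list of [categorize_pair()] outputs, one per
#'   constituent comparison.
#' @param rule `"all"` (all-consistent, default) or `"any"` (any-one).
#' @return Tibble: `gene_id`, `subtype`.
#' @export
build_cluster <- function(pair_categories, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(length(pair_categories) >= 1)
  genes <- pair_categories[[1]]$gene_id
  for (pc in pair_categories) {
    if (!identical(sort(pc$gene_id), sort(genes))) {
      abort("pair categories cover different gene sets")
    }
  }
  cat_m <- vapply(pair_categories, function(pc)
    pc$category[match(genes, pc$gene_id)], character(length(genes)))
  high_m <- vapply(pair_categories, function(pc)
    pc$high[match(genes, pc$gene_id)], character(length(genes)))
  if (is.null(dim(cat_m))) {
    cat_m <- matrix(cat_m, ncol = length(pair_categories))
    high_m <- matrix(high_m, ncol = length(pair_categories))
  }
  subtype <- vapply(seq_along(genes), function(i) {
    cats <- cat_m[i, ]
    highs <- high_m[i, ]
    if (all(cats == "low")) return("low")
    informative <- cats != "low"
    cats <- cats[informative]
    highs <- highs[informative]
    qual <- cats %in% c("specific", "biased")
    dirs <- unique(highs[qual])
    if (length(dirs) > 1) return("none")
    if (rule == "all") {
      if (!all(qual)) return("none")
    } else {
      if (!any(qual)) return("none")
    }
    label <- dirs[1]
    if (all(cats[qual] == "specific")) paste0(label, "_specific")
    else paste0(label, "_biased")
  }, character(1))
  tibble(gene_id = genes, subtype = subtype)
}

#' Build the full five-cluster membership table
#'
#' @param de_tables Named list of `ix_de` tables keyed by `comparison_id`
#'   (see [cluster_plan()]); typically produced by [run_comparisons()].
#' @param t An `ix_thresholds`.
#' @param rule Combine rule, see [build_cluster()].
#' @return Long tibble of class `ix_membership`: `gene_id`, `cluster`,
#'   `subtype`.
#' @export
build_all_clusters <- function(de_tables, t = thresholds(), rule = "all") {
  plan <- cluster_plan()
  missing <- setdiff(plan$comparison_id, names(de_tables))
  if (length(missing) > 0) {
    abort(paste0("missing DE table(s) for comparison(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- purrr::map(unique(plan$cluster), function(cl) {
    sub <- filter(plan, .data$cluster == cl)
    pcs <- purrr::pmap(sub, function(comparison_id, a_label, b_label, ...) {
      categorize_pair(de_tables[[comparison_id]], t,
                      a_label = a_label, b_label = b_label)
    })
    mutate(build_cluster(pcs, rule = rule), cluster = cl)
  })
  out <- select(bind_rows(out), "gene_id", "cluster", "subtype")
  class(out) <- c("ix_membership", class(out))
  out
}

#' Run every comparison of a plan
#'
#' Maps [compare_groups()] over the distinct (group_a, group_b) pairs of a
#' comparison plan and returns the tables keyed by `comparison_id`.
#'
#' @param counts `ix_counts`.
#' @param design `ix_design`.
#' @param plan Tibble with `group_a`, `group_b`, `comparison_id` (e.g. from
#'   [cluster_plan()] or [pattern_plan()]).
#' @param gene_lengths,library_sizes,dispersion Passed to [compare_groups()].
#' @return Named list of `ix_de` tables.
#' @export
run_comparisons <- function(counts, design, plan, gene_lengths = NULL,
                            library_sizes = NULL, dispersion = NULL) {
  pairs <- distinct(plan, .data$comparison_id, .data$group_a, .data$group_b)
  tabs <- purrr::pmap(pairs, function(comparison_id, group_a, group_b) {
    compare_groups(counts, design, group_a, group_b,
                   gene_lengths = gene_lengths, dispersion = dispersion,
                   library_sizes = library_sizes)
  })
  setNames(tabs, pairs$comparison_id)
}
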