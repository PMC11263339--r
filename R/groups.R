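#' Intersect cluster subtypes into the six sex-by-tissue gene groups
#'
#' For a chosen sex and tissue, crosses the gene's subtype in the
#' tissue-matched sex cluster (REPRODUCTIVE_SEX or CARCASS_SEX) with its
#' subtype in the TISSUE cluster: sex-specific or sex-biased towards the
#' chosen sex, by tissue-specific / tissue-biased towards the chosen tissue
#' or tissue-unbiased. "Tissue-unbiased" means the gene sits in no TISSUE
#' subtype while not being low across the TISSUE comparisons — the reading
#' that makes the six groups exhaustive over the non-low sex-associated
#' genes. Genes whose TISSUE subtype points at the other tissue are
#' out-group here and excluded.
#'
#' @param membership `ix_membership` long table from [build_all_clusters()].
#' @param sex `"female"` or `"male"`.
#' @param tissue `"reproductive"` or `"carcass"`.
#' @return Tibble: `gene_id`, `sex_axis` (`specific`/`biased`),
#'   `tissue_axis` (`specific`/`biased`/`unbiased`), `group` (e.g.
#'   `"female-specific/reproductive-specific"`).
#' @export
intersect_groups <- function(membership, sex = c("female", "male"),
                             tissue = c("reproductive", "carcass")) {
  sex <- match.arg(sex)
  tissue <- match.arg(tissue)
  m <- as_tibble(membership)
  sex_cluster <- if (tissue == "reproductive") "REPRODUCTIVE_SEX" else "CARCASS_SEX"

  sex_part <- filter(m, .data$cluster == sex_cluster,
                     .data$subtype %in% paste0(sex, c("_specific", "_biased")))
  sex_part <- mutate(sex_part,
                     sex_axis = sub(paste0("^", sex, "_"), "", .data$subtype))
  tis <- filter(m, .data$cluster == "TISSUE")
  tis <- mutate(tis, tissue_axis = dplyr::case_when(
    .data$subtype == paste0(tissue, "_specific") ~ "specific",
    .data$subtype == paste0(tissue, "_biased") ~ "biased",
    .data$subtype == "none" ~ "unbiased",
    TRUE ~ NA_character_  # low, or specific/biased towards the other tissue
  ))
  out <- inner_join(select(sex_part, "gene_id", "sex_axis"),
                    select(tis, "gene_id", "tissue_axis"), by = "gene_id")
  out <- filter(out, !is.na(.data$tissue_axis))
  mutate(out, group = paste0(sex, "-", .data$sex_axis, "/",
                             tissue, "-", .data$tissue_axis))
}

#' Members of one named gene group
#'
#' @param membership `ix_membership`.
#' @param group Group name as produced by [intersect_groups()], e.g.
#'   `"female-specific/reproductive-specific"`.
#' @return Character vector of gene ids.
#' @export
group_members <- function(membership, group) {
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort("group must look like '<sex>-<axis>/<tissue>-<axis>'")
  }
  sx <- strsplit(parts[1], "-", fixed = TRUE)[[1]]
  ti <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  all_groups <- intersect_groups(membership, sex = sx[1], tissue = ti[1])
  pull(filter(all_groups, .data$group == !!group), "gene_id")
}

#' Write the six group lists as TSV files
#'
#' One file per group (`gene_id`, `sex_axis`, `tissue_axis`), named after
#' the group with `/` replaced by `__`.
#'
#' @param groups Output of [intersect_groups()].
#' @param dir Destination directory (created if absent).
#' @return The written paths, invisibly.
#' @export
write_group_lists <- function(groups, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(unique(groups$group), function(g) {
    fn <- file.path(dir, paste0(gsub("/", "__", g), ".tsv"))
    readr::write_tsv(filter(groups, .data$group == g), fn)
    fn
  })
  invisible(paths)
}
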