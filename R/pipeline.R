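#' Configure a full pipeline run
#'
#' @param counts Path to a count TSV, or an `ix_counts` tibble.
#' @param sample_sheet Path to a sample-sheet CSV, or an `ix_design`.
#' @param out_dir Output directory (created if absent).
#' @param gene_lengths Optional path to a length TSV, or a length table.
#' @param de_dir Optional directory of precomputed DE tables named
#'   `<comparison_id>.tsv`; when present those comparisons are ingested
#'   instead of recomputed.
#' @param phenotypes Optional path to a phenotype-record CSV, or a tibble.
#' @param t An `ix_thresholds`.
#' @param combine_rule Cluster combine rule (`"all"` or `"any"`).
#' @param group_sex,group_tissue Which sex-by-tissue setting to build gene
#'   groups and patterns for.
#' @param seed Integer seed echoed into the manifest (the analysis itself is
#'   deterministic; the seed matters when the config is used with simulated
#'   inputs).
#' @return A list of class `ix_config`.
#' @export
pipeline_config <- function(counts, sample_sheet, out_dir,
                            gene_lengths = NULL, de_dir = NULL,
                            phenotypes = NULL, t = thresholds(),
                            combine_rule = "all",
                            group_sex = "female",
                            group_tissue = "reproductive",
                            seed = 1L) {
  structure(list(counts = counts, sample_sheet = sample_sheet,
                 out_dir = out_dir, gene_lengths = gene_lengths,
                 de_dir = de_dir, phenotypes = phenotypes, t = t,
                 combine_rule = combine_rule, group_sex = group_sex,
                 group_tissue = group_tissue, seed = as.integer(seed)),
            class = "ix_config")
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full classification pipeline
#'
#' Quantifies FPKM, runs (or ingests) every pairwise comparison needed by
#' the five expression clusters and the five-comparison intersex pattern
#' analysis, builds cluster membership and the six sex-by-tissue gene
#' groups, summarizes intersex patterns per group, computes phenotype
#' association statistics when records are supplied, writes every table
#' under `out_dir` and a JSON manifest echoing the configuration.
#'
#' @param cfg An `ix_config` from [pipeline_config()].
#' @return Invisibly, a list with elements `fpkm`, `de_tables`,
#'   `membership`, `groups`, `patterns`, `pattern_summaries`, `phenotype`,
#'   `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ix_config"))
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  counts <- stage("read_counts", {
    if (is.character(cfg$counts)) read_counts(cfg$counts) else cfg$counts
  })
  design <- stage("read_sample_sheet", {
    d <- if (is.character(cfg$sample_sheet)) {
      read_sample_sheet(cfg$sample_sheet)
    } else design_spec(cfg$sample_sheet)
    check_samples_match(counts, d)
    d
  })
  lengths <- stage("gene_lengths", {
    if (is.character(cfg$gene_lengths)) read_gene_lengths(cfg$gene_lengths)
    else cfg$gene_lengths
  })

  fpkm <- stage("fpkm", compute_fpkm(counts, lengths))
  stage("write_fpkm", write_fpkm(fpkm, file.path(out_dir, "fpkm.tsv")))

  ref_sex <- if (cfg$group_sex == "female") "female" else "male"
  ppl <- pattern_plan(cfg$group_tissue, ref_sex)
  plan <- bind_rows(
    select(cluster_plan(), "comparison_id", "group_a", "group_b"),
    select(ppl, "comparison_id", "group_a", "group_b"))
  plan <- distinct(plan, .data$comparison_id, .keep_all = TRUE)

  de_tables <- stage("differential_expression", {
    precomputed <- list()
    if (!is.null(cfg$de_dir)) {
      files <- list.files(cfg$de_dir, pattern = "\\.tsv$", full.names = TRUE)
      precomputed <- setNames(lapply(files, read_de_table),
                              sub("\\.tsv$", "", basename(files)))
    }
    todo <- filter(plan, !(.data$comparison_id %in% names(precomputed)))
    computed <- run_comparisons(counts, design, todo, gene_lengths = lengths)
    c(precomputed, computed)
  })
  de_out <- file.path(out_dir, "de")
  if (!dir.exists(de_out)) dir.create(de_out)
  for (id in names(de_tables)) {
    write_de_table(de_tables[[id]], file.path(de_out, paste0(id, ".tsv")))
  }

  membership <- stage("clusters",
                      build_all_clusters(de_tables, cfg$t, rule = cfg$combine_rule))
  stage("write_membership",
        write_membership(membership, file.path(out_dir, "membership.tsv")))

  groups <- stage("gene_groups",
                  intersect_groups(membership, cfg$group_sex, cfg$group_tissue))
  stage("write_groups", write_group_lists(groups, file.path(out_dir, "groups")))

  patterns <- stage("patterns", {
    genes <- unique(groups$gene_id)
    if (length(genes) > 0) {
      classify_patterns(de_tables, ppl, genes = genes, t = cfg$t)
    } else {
      tibble(gene_id = character(0))
    }
  })
  readr::write_tsv(patterns, file.path(out_dir, "patterns.tsv"))
  pattern_summaries <- stage("pattern_summaries", {
    purrr::map(setNames(nm = sort(unique(groups$group))), function(g) {
      summarize_patterns(groups$gene_id[groups$group == g], de_tables, ppl, cfg$t)
    })
  })
  jsonlite::write_json(
    purrr::map(pattern_summaries, ~ setNames(as.list(.x$n), .x$pattern)),
    file.path(out_dir, "pattern_summary.json"), auto_unbox = TRUE)

  phenotype <- NULL
  if (!is.null(cfg$phenotypes)) {
    phenotype <- stage("phenotype_association", {
      recs <- if (is.character(cfg$phenotypes)) read_phenotypes(cfg$phenotypes)
              else cfg$phenotypes
      tab <- build_contingency(recs, "pupa_type", "adult_class",
                               col_collapse = list(normal = 1:2, intersex = 3:5))
      res <- bind_rows(tidy(pearson_chi2(tab)), tidy(g_test(tab)))
      readr::write_tsv(res, file.path(out_dir, "phenotype_tests.tsv"))
      list(table = tab, tests = res)
    })
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    config = list(seed = cfg$seed, combine_rule = cfg$combine_rule,
                  group_sex = cfg$group_sex, group_tissue = cfg$group_tissue,
                  thresholds = unclass(cfg$t)),
    n_genes = nrow(counts), n_samples = nrow(design),
    comparisons = names(de_tables),
    groups = sort(unique(groups$group)),
    outputs = sort(c("fpkm.tsv", "membership.tsv", "patterns.tsv",
                     "pattern_summary.json",
                     if (!is.null(phenotype)) "phenotype_tests.tsv")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fpkm = fpkm, de_tables = de_tables, membership = membership,
                 groups = groups, patterns = patterns,
                 pattern_summaries = pattern_summaries, phenotype = phenotype,
                 manifest_path = manifest_path))
}
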