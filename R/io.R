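#' Read a gene-level count matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. Cells must be non-negative integers; duplicate gene ids and ragged
#' rows are rejected with the offending id / line number.
#'
#' @param path File path.
#' @return An `ix_counts` tibble (`gene_id` + one integer column per sample).
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("count file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != ncol)
  if (length(ragged) > 0) {
    abort(paste0("ragged row(s) in count file at line(s): ",
                 paste(head(ragged, 5), collapse = ", ")))
  }
  counts <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  names(counts)[1] <- "gene_id"
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  samp <- setdiff(names(counts), "gene_id")
  if (any(duplicated(samp))) abort("duplicate sample ids in count header")
  for (s in samp) {
    v <- counts[[s]]
    bad <- !grepl("^[0-9]+$", v)
    if (any(bad)) {
      abort(paste0("non-integer or negative count in sample '", s, "', gene '",
                   counts$gene_id[which(bad)[1]], "': ", v[which(bad)[1]]))
    }
    counts[[s]] <- as.integer(v)
  }
  class(counts) <- c("ix_counts", class(counts))
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts `ix_counts` tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  m <- counts_tbl_to_matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' Read a sample sheet into a validated design
#'
#' @param path CSV with columns `sample_id`, `species`, `sex`, `tissue`,
#'   `replicate`.
#' @param counts Optional count matrix; if given, the sample sets must match
#'   exactly and the difference is reported otherwise.
#' @return An `ix_design` tibble.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), species = readr::col_character(),
    sex = readr::col_character(), tissue = readr::col_character(),
    replicate = readr::col_integer()))
  if (nrow(sheet) == 0) abort("sample sheet is empty")
  design <- design_spec(sheet)
  if (!is.null(counts)) check_samples_match(counts, design)
  design
}

#' @rdname read_sample_sheet
#' @param design An `ix_design` to write.
#' @export
write_sample_sheet <- function(design, path) {
  readr::write_csv(select(as_tibble(design), -any_of("group")), path)
  invisible(path)
}

check_samples_match <- function(counts, design) {
  cs <- setdiff(names(as_tibble(counts)), "gene_id")
  only_counts <- setdiff(cs, design$sample_id)
  only_sheet <- setdiff(design$sample_id, cs)
  if (length(only_counts) > 0 || length(only_sheet) > 0) {
    abort(paste0(
      "sample sets differ between counts and sheet.",
      if (length(only_counts) > 0)
        paste0(" Only in counts: ", paste(only_counts, collapse = ", "), ".") else "",
      if (length(only_sheet) > 0)
        paste0(" Only in sheet: ", paste(only_sheet, collapse = ", "), ".") else ""))
  }
  invisible(TRUE)
}

#' Read a gene length table
#'
#' Two-column TSV (`gene_id`, `length_bp`). Lengths must be positive.
#'
#' @param path File path.
#' @return Tibble (`gene_id`, `length_bp`).
#' @export
read_gene_lengths <- function(path) {
  len <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), length_bp = readr::col_double()))
  if (any(len$length_bp <= 0)) abort("gene lengths must be > 0")
  if (any(duplicated(len$gene_id))) abort("duplicate gene id in length table")
  len
}

#' @rdname read_gene_lengths
#' @param lengths Tibble (`gene_id`, `length_bp`).
#' @export
write_gene_lengths <- function(lengths, path) {
  readr::write_tsv(lengths[, c("gene_id", "length_bp")], path)
  invisible(path)
}

#' Derive gene lengths from a GTF/GFF annotation
#'
#' Sums exon widths per gene (overlaps merged), the conventional
#' union-exon length used for FPKM.
#'
#' @param path GTF/GFF file.
#' @param attribute Attribute holding the gene identifier (default
#'   `"gene_id"`).
#' @return Tibble (`gene_id`, `length_bp`).
#' @export
gene_lengths_from_gtf <- function(path, attribute = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GTF ingestion requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  ids <- S4Vectors::mcols(gr)[[attribute]]
  if (is.null(ids)) abort(paste0("attribute '", attribute, "' not found in GTF"))
  by_gene <- split(gr, ids)
  widths <- vapply(by_gene, function(g)
    sum(BiocGenerics::width(GenomicRanges::reduce(g))), numeric(1))
  tibble(gene_id = names(widths), length_bp = unname(widths))
}

#' Read or write a differential-expression table
#'
#' The on-disk schema is `gene_id`, `log2fc`, `pvalue`, `fdr`,
#' `mean_fpkm_a`, `mean_fpkm_b`, `comparison_id`; `col_map` renames
#' arbitrary source columns onto it so externally produced DE tables (e.g. a
#' study's supplementary files) can be ingested.
#'
#' @param path TSV path.
#' @param col_map Named character vector mapping schema names to source
#'   column names, e.g. `c(log2fc = "logFC", fdr = "FDR")`.
#' @return A tibble of class `ix_de`, carrying the comparison orientation
#'   (B over A) in attribute `comparison`.
#' @export
read_de_table <- function(path, col_map = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols())
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(tab)) {
        abort(paste0("mapped column '", col_map[[nm]], "' not present"))
      }
      names(tab)[names(tab) == col_map[[nm]]] <- nm
    }
  }
  required <- c("gene_id", "log2fc", "pvalue", "fdr", "mean_fpkm_a", "mean_fpkm_b")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("DE table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE)) abort("fdr outside [0, 1]")
  if (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE)) abort("pvalue outside [0, 1]")
  cmp <- if ("comparison_id" %in% names(tab)) tab$comparison_id[1] else NA_character_
  new_de_table(tab, comparison = cmp)
}

#' @rdname read_de_table
#' @param de An `ix_de` table.
#' @export
write_de_table <- function(de, path) {
  out <- as_tibble(de)
  if (!"comparison_id" %in% names(out)) {
    out$comparison_id <- attr(de, "comparison") %||% NA_character_
  }
  readr::write_tsv(out, path)
  invisible(path)
}

new_de_table <- function(tab, comparison = NA_character_) {
  tab <- as_tibble(tab)
  attr(tab, "comparison") <- comparison
  class(tab) <- c("ix_de", setdiff(class(tab), "ix_de"))
  tab
}

#' Write cluster membership in presence/absence form
#'
#' One row per gene; a `label` column per cluster naming the subtype
#' (`none` when the gene is in no subtype) and one 0/1 indicator column per
#' (cluster, subtype) pair observed in the data.
#'
#' @param membership Long tibble (`gene_id`, `cluster`, `subtype`) as
#'   returned by [build_all_clusters()].
#' @param path TSV destination.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path) {
  m <- as_tibble(membership)
  wide <- tidyr::pivot_wider(m, id_cols = "gene_id",
                             names_from = "cluster", values_from = "subtype",
                             names_glue = "label_{cluster}")
  ind <- filter(m, .data$subtype != "none")
  if (nrow(ind) > 0) {
    ind <- mutate(ind, col = paste(.data$cluster, .data$subtype, sep = "."),
                  value = 1L)
    indw <- tidyr::pivot_wider(select(ind, "gene_id", "col", "value"),
                               names_from = "col", values_from = "value",
                               values_fill = 0L)
    wide <- left_join(wide, indw, by = "gene_id")
    wide <- mutate(wide, across(-c("gene_id", dplyr::starts_with("label_")),
                                ~ tidyr::replace_na(.x, 0L)))
  }
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read back a membership file written by [write_membership()]
#'
#' @param path TSV path.
#' @return Long tibble (`gene_id`, `cluster`, `subtype`).
#' @export
read_membership <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols())
  label_cols <- grep("^label_", names(wide), value = TRUE)
  long <- tidyr::pivot_longer(wide[, c("gene_id", label_cols)],
                              cols = all_of(label_cols),
                              names_to = "cluster", values_to = "subtype")
  long <- mutate(long, cluster = sub("^label_", "", .data$cluster))
  ind_cols <- setdiff(names(wide), c("gene_id", label_cols))
  for (col in ind_cols) {
    if (!all(wide[[col]] %in% c(0L, 1L))) {
      abort(paste0("indicator column '", col, "' contains values other than 0/1"))
    }
  }
  arrange(long, .data$gene_id, .data$cluster)
}

#' Read per-individual phenotype records
#'
#' @param path CSV with the columns of [simulate_phenotypes()] output.
#' @return Tibble of records.
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    pupa_type = readr::col_character(),
    adult_class = readr::col_integer(),
    mag_count = readr::col_integer(),
    spermatheca_count = readr::col_integer(),
    .default = readr::col_character()))
}

#' @rdname read_phenotypes
#' @param records Phenotype record tibble.
#' @export
write_phenotypes <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
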