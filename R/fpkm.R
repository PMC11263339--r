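#' Compute FPKM from counts and gene lengths
#'
#' FPKM_gs = c_gs * 1e9 / (L_g * N_s), with L_g the transcript length in bp
#' and N_s the library size. By default N_s is the per-sample total over the
#' supplied gene universe, which makes the matrix self-contained; an explicit
#' `library_sizes` vector (e.g. total mapped fragments) can be passed when
#' the denominator should not depend on the gene universe.
#'
#' Genes absent from the length table are dropped with a warning rather than
#' silently defaulted, since a wrong length corrupts FPKM.
#'
#' @param counts `ix_counts` tibble.
#' @param gene_lengths Two-column data frame (`gene_id`, `length_bp`), named
#'   vector, or NULL for a uniform 1,000 bp.
#' @param library_sizes Optional named numeric vector of per-sample
#'   denominators; defaults to column sums.
#' @return A tibble (class `ix_fpkm`): `gene_id` + one numeric column per
#'   sample.
#' @export
compute_fpkm <- function(counts, gene_lengths = NULL, library_sizes = NULL) {
  m <- counts_tbl_to_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  if (is.data.frame(gene_lengths)) {
    known <- intersect(rownames(m), gene_lengths$gene_id)
    dropped <- setdiff(rownames(m), known)
    if (length(dropped) > 0) {
      warn(paste0("dropping ", length(dropped),
                  " gene(s) with no length entry: ",
                  paste(head(dropped, 5), collapse = ", "),
                  if (length(dropped) > 5) ", ..." else ""))
      m <- m[known, , drop = FALSE]
    }
  }
  len <- resolve_lengths(gene_lengths, rownames(m))
  if (is.null(library_sizes)) {
    n_s <- colSums(m)
  } else {
    missing <- setdiff(colnames(m), names(library_sizes))
    if (length(missing) > 0) {
      abort(paste0("no library size for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    n_s <- library_sizes[colnames(m)]
  }
  zero <- colnames(m)[n_s <= 0]
  if (length(zero) > 0) {
    abort(paste0("zero library size for sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  fpkm <- sweep(m * 1e9 / len, 2, n_s, "/")
  out <- bind_cols(tibble(gene_id = rownames(m)),
                   as_tibble(fpkm, .name_repair = "minimal"))
  class(out) <- c("ix_fpkm", class(out))
  out
}

#' Per-group arithmetic mean FPKM
#'
#' Averages FPKM over the replicates of each (species, sex, tissue) group.
#' Single-replicate groups pass through unchanged.
#'
#' @param fpkm `ix_fpkm` tibble from [compute_fpkm()].
#' @param design `ix_design` covering every FPKM sample.
#' @return Tibble: `gene_id` + one numeric column per group id.
#' @export
group_mean_fpkm <- function(fpkm, design) {
  design <- design_spec(design)
  samp <- setdiff(names(as_tibble(fpkm)), "gene_id")
  unassigned <- setdiff(samp, design$sample_id)
  if (length(unassigned) > 0) {
    abort(paste0("sample(s) not in design: ", paste(unassigned, collapse = ", ")))
  }
  m <- counts_tbl_to_matrix(fpkm)
  groups <- unique(design$group[design$sample_id %in% samp])
  gm <- vapply(groups, function(g) {
    ids <- intersect(samples_of_group(design, g), samp)
    if (length(ids) == 0) abort(paste0("empty group '", g, "'"))
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(m), dimnames = list(rownames(m), groups))
  bind_cols(tibble(gene_id = rownames(m)),
            as_tibble(gm, .name_repair = "minimal"))
}

#' Write an FPKM matrix as TSV (6 decimal places)
#'
#' @param fpkm `ix_fpkm` tibble.
#' @param path Destination.
#' @export
write_fpkm <- function(fpkm, path) {
  out <- as_tibble(fpkm)
  num <- setdiff(names(out), "gene_id")
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  readr::write_tsv(out, path)
  invisible(path)
}
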