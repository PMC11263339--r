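#' Classification thresholds
#'
#' The three knobs of the rule-based classification: the low-expression
#' floor (group-mean FPKM below which a gene counts as unexpressed, default
#' 1), the fold-change threshold on |log2 FC| (default 2, i.e. four-fold)
#' and the BH-adjusted significance level (default 0.05).
#'
#' @param fpkm_low Low-expression FPKM floor.
#' @param lfc |log2 fold change| threshold.
#' @param fdr BH-adjusted significance level.
#' @return A list of class `ix_thresholds`.
#' @export
thresholds <- function(fpkm_low = 1, lfc = 2, fdr = 0.05) {
  if (fpkm_low <= 0 || lfc <= 0 || fdr <= 0) {
    abort("all thresholds must be > 0")
  }
  structure(list(fpkm_low = fpkm_low, lfc = lfc, fdr = fdr),
            class = "ix_thresholds")
}

#' Moment-based shrinkage dispersion estimate for a two-group comparison
#'
#' Per gene, a method-of-moments estimate on library-size-normalized counts,
#' phi_g = max(0, (s^2 - m) / m^2), pooling within-group variances across the
#' two groups, then shrunk towards the common (mean) dispersion:
#' phi* = w * phi_bar + (1 - w) * phi_g. The shrinkage stabilizes the very
#' noisy per-gene moments at typical replicate numbers while letting
#' strongly gene-specific variability through.
#'
#' @param counts `ix_counts` tibble.
#' @param design `ix_design`.
#' @param groups Character vector of two group ids.
#' @param weight Shrinkage weight w towards the common dispersion
#'   (default 0.7).
#' @return A list of class `ix_dispersion`: `table` (tibble `gene_id`,
#'   `phi_gene`, `phi_shrunk`), `common`, `weight`.
#' @export
estimate_dispersion <- function(counts, design, groups, weight = 0.7) {
  design <- design_spec(design)
  stopifnot(length(groups) == 2)
  norm <- normalized_group_counts(counts, design, groups)
  na <- length(norm$idx_a); nb <- length(norm$idx_b)
  if (na < 2 && nb < 2) {
    abort(paste0("both groups have a single replicate; dispersion cannot be ",
                 "estimated from the data. Pass a fixed dispersion to the ",
                 "test instead."))
  }
  m <- norm$norm
  stats_for <- function(idx) {
    x <- m[, idx, drop = FALSE]
    list(mean = rowMeans(x),
         var = if (length(idx) >= 2) apply(x, 1, var) else rep(NA_real_, nrow(x)),
         df = max(length(idx) - 1, 0))
  }
  a <- stats_for(norm$idx_a); b <- stats_for(norm$idx_b)
  tot_df <- a$df + b$df
  pool_var <- (ifelse(is.na(a$var), 0, a$var) * a$df +
               ifelse(is.na(b$var), 0, b$var) * b$df) / tot_df
  mean_all <- (a$mean + b$mean) / 2
  phi_gene <- unname(ifelse(mean_all > 0,
                            pmax(0, (pool_var - mean_all) / mean_all^2), 0))
  common <- mean(phi_gene[mean_all > 0])
  if (!is.finite(common)) common <- 0
  phi_shrunk <- weight * common + (1 - weight) * phi_gene
  structure(list(table = tibble(gene_id = rownames(m), phi_gene = phi_gene,
                                phi_shrunk = phi_shrunk),
                 common = common, weight = weight),
            class = "ix_dispersion")
}

# Rescale the two groups' samples to the geometric-mean library size and
# round, so the exact test's conditioning on totals is defensible.
normalized_group_counts <- function(counts, design, groups) {
  m <- counts_tbl_to_matrix(counts)
  ids_a <- samples_of_group(design, groups[1])
  ids_b <- samples_of_group(design, groups[2])
  if (length(intersect(ids_a, ids_b)) > 0) {
    abort("the two groups share samples; comparisons must be disjoint")
  }
  ids <- c(ids_a, ids_b)
  missing <- setdiff(ids, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("sample(s) missing from counts: ", paste(missing, collapse = ", ")))
  }
  sub <- m[, ids, drop = FALSE]
  n_s <- colSums(sub)
  if (any(n_s <= 0)) {
    abort(paste0("zero library size for sample(s): ",
                 paste(ids[n_s <= 0], collapse = ", ")))
  }
  n_ref <- exp(mean(log(n_s)))
  norm <- round(sweep(sub, 2, n_ref / n_s, "*"))
  list(norm = norm, idx_a = seq_along(ids_a),
       idx_b = length(ids_a) + seq_along(ids_b))
}

# Conditional log-pmf of group-A's total a (a = 0..t) given the overall
# total t, for n_a and n_b NB replicates sharing dispersion phi. The group
# sums are NB with sizes n_a/phi, n_b/phi and the conditional distribution
# is free of the mean (negative hypergeometric); phi = 0 is the Poisson
# limit, a binomial split.
cond_split_logpmf <- function(t, n_a, n_b, phi) {
  a <- 0:t
  if (phi <= 0) {
    return(stats::dbinom(a, t, n_a / (n_a + n_b), log = TRUE))
  }
  r_a <- n_a / phi
  r_b <- n_b / phi
  lp <- lgamma(a + r_a) - lgamma(a + 1) + lgamma(t - a + r_b) - lgamma(t - a + 1)
  lp - max(lp) - log(sum(exp(lp - max(lp))))
}

#' Two-sided NB exact test for a two-group comparison
#'
#' For each gene, conditions on the gene's total (after equalizing library
#' sizes by total-count scaling) and sums the probabilities of all splits
#' between the groups that are as likely or less likely than the observed
#' one, under a negative binomial model with the gene's shrunk dispersion.
#' All-zero genes get p = 1 and are flagged.
#'
#' @param counts `ix_counts` tibble.
#' @param design `ix_design`.
#' @param groups Character vector of two group ids (A, B).
#' @param dispersion An `ix_dispersion`, or a single number used as a fixed
#'   dispersion for every gene, or NULL to estimate.
#' @return Tibble: `gene_id`, `pvalue`, `all_zero`.
#' @export
nb_exact_test <- function(counts, design, groups, dispersion = NULL) {
  design <- design_spec(design)
  norm <- normalized_group_counts(counts, design, groups)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, design, groups)
  }
  genes <- rownames(norm$norm)
  phi <- if (inherits(dispersion, "ix_dispersion")) {
    tab <- dispersion$table
    if (!all(genes %in% tab$gene_id)) {
      abort("dispersion estimate does not cover all genes")
    }
    tab$phi_shrunk[match(genes, tab$gene_id)]
  } else {
    rep(as.numeric(dispersion), length(genes))
  }
  n_a <- length(norm$idx_a); n_b <- length(norm$idx_b)
  y_a <- rowSums(norm$norm[, norm$idx_a, drop = FALSE])
  y_b <- rowSums(norm$norm[, norm$idx_b, drop = FALSE])
  tot <- y_a + y_b
  p <- vapply(seq_along(genes), function(i) {
    t <- tot[i]
    if (t == 0) return(1)
    lp <- cond_split_logpmf(t, n_a, n_b, phi[i])
    obs <- lp[y_a[i] + 1]
    sum(exp(lp[lp <= obs + 1e-10]))
  }, numeric(1))
  tibble(gene_id = genes, pvalue = pmin(p, 1), all_zero = tot == 0)
}

#' Two-group differential expression table
#'
#' Computes per-gene log2 fold change on prior-damped group-mean FPKM
#' (log2((mean_B + c0) / (mean_A + c0)), c0 = 0.25 FPKM), the NB exact-test
#' p-value, and the BH-adjusted FDR over the genes of this one comparison.
#' Orientation is B over A: positive log2 FC means higher in group B.
#'
#' @param counts `ix_counts` tibble.
#' @param design `ix_design`.
#' @param group_a,group_b Group ids.
#' @param gene_lengths Gene length table/vector (default uniform 1,000 bp).
#' @param dispersion See [nb_exact_test()].
#' @param prior_fpkm Prior count c0 added to both means before the ratio.
#' @param library_sizes Optional explicit FPKM denominators.
#' @return An `ix_de` tibble: `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `mean_fpkm_a`, `mean_fpkm_b`, `comparison_id`.
#' @export
compare_groups <- function(counts, design, group_a, group_b,
                           gene_lengths = NULL, dispersion = NULL,
                           prior_fpkm = 0.25, library_sizes = NULL) {
  design <- design_spec(design)
  if (identical(group_a, group_b)) {
    abort("group_a and group_b must differ")
  }
  fpkm <- compute_fpkm(counts, gene_lengths, library_sizes = library_sizes)
  ids <- c(samples_of_group(design, group_a), samples_of_group(design, group_b))
  gm <- group_mean_fpkm(fpkm[, c("gene_id", ids)],
                        filter(design, .data$sample_id %in% ids))
  test <- nb_exact_test(counts, design, c(group_a, group_b), dispersion)
  out <- tibble(gene_id = gm$gene_id,
                mean_fpkm_a = gm[[group_a]],
                mean_fpkm_b = gm[[group_b]])
  out <- left_join(out, test, by = "gene_id")
  out <- mutate(out,
                log2fc = log2((.data$mean_fpkm_b + prior_fpkm) /
                              (.data$mean_fpkm_a + prior_fpkm)),
                fdr = p.adjust(.data$pvalue, method = "BH"),
                comparison_id = paste0(group_b, "_over_", group_a))
  out <- select(out, "gene_id", "log2fc", "pvalue", "fdr",
                "mean_fpkm_a", "mean_fpkm_b", "comparison_id", "all_zero")
  new_de_table(out, comparison = out$comparison_id[1])
}
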