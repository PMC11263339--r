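# Shared fixtures, built in code. The heavier simulated dataset is memoised
# so several test files can reuse one simulation + DE pass.

two_group_design <- function(nrep = 3, sexes = c("male", "female")) {
  design_spec(tibble::tibble(
    sample_id = paste0("s", seq_len(2 * nrep)),
    species = "U",
    sex = rep(sexes, each = nrep),
    tissue = "reproductive",
    replicate = rep(seq_len(nrep), 2)))
}

flat_truth <- function(n_genes, mu = 100, phi = 0.1) {
  truth_table(tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)), class = "unbiased",
    direction = NA_character_, mu = mu, fold_change = 1, dispersion = phi))
}

# Counts table from an explicit matrix (genes x samples) plus a design over
# two groups; used for hand-built exact-test cases.
counts_from_matrix <- function(m, design) {
  stopifnot(ncol(m) == nrow(design))
  out <- tibble::tibble(gene_id = rownames(m))
  for (i in seq_len(ncol(m))) out[[design$sample_id[i]]] <- as.integer(m[, i])
  out
}

# Brute-force conditional-split oracle for the NB exact test: enumerate all
# per-sample count vectors with the given total, weight by the product of
# iid NB pmfs, and accumulate the group-A-sum distribution. Independent of
# the closed-form conditional used by the implementation; the result must
# not depend on mu.
enumerate_compositions <- function(t, n) {
  if (n == 1) return(matrix(t, ncol = 1))
  do.call(rbind, lapply(0:t, function(k) cbind(k, enumerate_compositions(t - k, n - 1))))
}

oracle_split_p <- function(ya, yb, n_a, n_b, phi, mu = 5) {
  t <- ya + yb
  combs <- enumerate_compositions(t, n_a + n_b)
  lp <- matrix(stats::dnbinom(combs, size = 1 / phi, mu = mu, log = TRUE),
               nrow = nrow(combs))
  pr <- exp(rowSums(lp))
  a_sum <- rowSums(combs[, seq_len(n_a), drop = FALSE])
  split_pmf <- tapply(pr, a_sum, sum)
  split_pmf <- split_pmf / sum(split_pmf)
  obs <- split_pmf[as.character(ya)]
  sum(split_pmf[split_pmf <= obs * (1 + 1e-9)])
}

# Exact-test p for explicit group sums, via the package, using equal-library
# samples (a filler gene keeps every library at the same size so the
# total-count normalization is a no-op).
package_split_p <- function(ya, yb, n_a, n_b, phi) {
  spread <- function(tot, n) {
    base <- tot %/% n
    v <- rep(base, n)
    k <- tot %% n
    if (k > 0) v[seq_len(k)] <- v[seq_len(k)] + 1
    v
  }
  cells <- c(spread(ya, n_a), spread(yb, n_b))
  m <- rbind(g = cells, fill = 1000 - cells)
  design <- design_spec(tibble::tibble(
    sample_id = paste0("s", seq_len(n_a + n_b)), species = "U",
    sex = rep(c("male", "female"), c(n_a, n_b)), tissue = "reproductive",
    replicate = c(seq_len(n_a), seq_len(n_b))))
  res <- nb_exact_test(counts_from_matrix(m, design), design,
                       c("U_male_reproductive", "U_female_reproductive"),
                       dispersion = phi)
  res$pvalue[res$gene_id == "g"]
}

# Phenotype records matching a named intersex/normal split per pupa type:
# k_intersex adults in germline classes 3-5, the rest in classes 1-2.
records_from_counts <- function(split) {
  rows <- lapply(names(split), function(type) {
    k <- split[[type]][1]; n <- split[[type]][2]
    tibble::tibble(
      pupa_type = type,
      adult_class = as.integer(c(rep(4, k), rep(1, n - k))))
  })
  out <- dplyr::bind_rows(rows)
  out$individual_id <- sprintf("i%03d", seq_len(nrow(out)))
  out$mag_count <- 2L
  out$spermatheca_count <- 0L
  out$rotation_24h <- "yes"
  out$rotation_48h <- "n/a"
  out
}

# Memoised strong-effect simulation with the full 14-group design, its DE
# tables over the cluster + pattern comparisons, and the derived membership.
.sim_cache <- new.env(parent = emptyenv())

planted_pipeline_fixture <- function() {
  if (!is.null(.sim_cache$fix)) return(.sim_cache$fix)
  design <- default_design()
  truth <- plant_truth(n_genes = 800,
                       n_low = 30, n_sex_specific = 60, n_sex_biased = 60,
                       n_species_specific = 20, n_species_biased = 20,
                       n_tissue_specific = 30, n_tissue_biased = 30,
                       intersex_behaviors = c("no_change", "down", "other"))
  counts <- simulate_counts(design, truth, target_library_size = 1.5e6, seed = 101)
  plan <- dplyr::bind_rows(
    cluster_plan()[, c("comparison_id", "group_a", "group_b")],
    pattern_plan("reproductive", "female")[, c("comparison_id", "group_a", "group_b")],
    pattern_plan("reproductive", "male")[, c("comparison_id", "group_a", "group_b")])
  plan <- dplyr::distinct(plan)
  de <- run_comparisons(counts, design, plan)
  membership <- build_all_clusters(de)
  .sim_cache$fix <- list(design = design, truth = truth, counts = counts,
                         de = de, membership = membership)
  .sim_cache$fix
}
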