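test_that("default design has 14 groups of 3 replicates and guards its invariants", {
  d <- default_design()
  expect_equal(nrow(d), 42)
  expect_equal(length(unique(d$group)), 14)
  expect_equal(unname(table(d$group)), rep(3L, 14), ignore_attr = TRUE)

  sheet <- tibble::tibble(sample_id = c("a", "b"), species = c("U", "U"),
                          sex = c("male", "intersex"),
                          tissue = "reproductive", replicate = 1:2)
  expect_error(design_spec(sheet), "intersex samples must have species UUM")
  sheet$sex <- c("male", "male")
  sheet$sample_id <- c("a", "a")
  expect_error(design_spec(sheet), "duplicate sample id")
  sheet$sample_id <- c("a", "b")
  sheet$species <- c("U", "Q")
  expect_error(design_spec(sheet), "unknown species")
})

test_that("truth validation rejects malformed plants, naming the gene", {
  base <- tibble::tibble(gene_id = "g1", class = "sex_specific",
                         direction = "female", mu = 100, fold_change = 64,
                         dispersion = 0.1)
  expect_s3_class(truth_table(base), "ix_truth")
  bad <- base; bad$direction <- "reproductive"
  expect_error(truth_table(bad), "g1")
  bad <- base; bad$class <- "sex_biased"; bad$fold_change <- 3
  expect_error(truth_table(bad), "log2 fold change")
  bad <- base; bad$specific_fpkm <- 2
  expect_error(truth_table(bad), "silent-side")
})

test_that("zero planted means give an all-zero matrix and seeds are reproducible", {
  d <- two_group_design(2)
  tr <- flat_truth(5, mu = 0, phi = 0.1)
  cts <- simulate_counts(d, tr, target_library_size = 1e6, seed = 1)
  expect_true(all(as.matrix(cts[, -1]) == 0))

  tr2 <- flat_truth(50, mu = 100, phi = 0.1)
  a <- simulate_counts(d, tr2, target_library_size = 1e5, seed = 9)
  b <- simulate_counts(d, tr2, target_library_size = 1e5, seed = 9)
  c_ <- simulate_counts(d, tr2, target_library_size = 1e5, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c_))
})

test_that("simulated counts match NB moments at 10,000 draws", {
  d <- design_spec(tibble::tibble(
    sample_id = paste0("r", 1:10000), species = "U", sex = "male",
    tissue = "reproductive", replicate = 1:10000))
  tr <- truth_table(tibble::tibble(
    gene_id = "g1", class = "unbiased", direction = NA_character_,
    mu = 100, fold_change = 1, dispersion = 0.2))
  cts <- simulate_counts(d, tr, target_library_size = 1e6, seed = 6)
  x <- as.numeric(cts[1, -1])
  mu <- 100       # FPKM 100 at L = 1 kb, N = 1e6 gives mean count 100
  v <- mu + 0.2 * mu^2
  expect_lt(abs(mean(x) - mu) / mu, 0.02)
  expect_lt(abs(var(x) - v) / v, 0.10)
})

test_that("per-group mean of recomputed FPKM concentrates on the planted value", {
  n_rep <- 300
  d <- design_spec(tibble::tibble(
    sample_id = paste0("s", seq_len(n_rep)), species = "U", sex = "male",
    tissue = "reproductive", replicate = seq_len(n_rep)))
  tr <- flat_truth(1000, mu = 100, phi = 0.1)
  n_lib <- 1e6
  cts <- simulate_counts(d, tr, target_library_size = n_lib, seed = 5)
  fp <- compute_fpkm(cts, library_sizes = setNames(rep(n_lib, n_rep), d$sample_id))
  gm <- group_mean_fpkm(fp, d)
  expect_gte(mean(abs(gm$U_male_reproductive - 100) / 100 <= 0.05), 0.95)
})

test_that("expected intersex group means follow the planted behavior", {
  d <- default_design()
  tr <- truth_table(tibble::tibble(
    gene_id = paste0("g", 1:4), class = "sex_specific", direction = "female",
    mu = 200, fold_change = 64, dispersion = 0.05,
    intersex_behavior = c("no_change", "down", "up", "other"),
    intersex_reference = "female"))
  m <- expected_group_fpkm(tr, d)
  ref <- m[, "UUM_female_reproductive"]
  ix <- m[, "UUM_intersex_reproductive"]
  expect_equal(ix[["g1"]], ref[["g1"]])
  expect_equal(ix[["g2"]], ref[["g2"]] / 64)
  expect_equal(ix[["g3"]], ref[["g3"]] * 64)
  # 'other' perturbs the normal backcross reference instead
  expect_equal(ref[["g4"]], m[["g4", "U_female_reproductive"]] * 64)
})

test_that("phenotype generator honors counts, degenerate and empty cases", {
  gen0 <- phenotype_generator(pupa_counts = c(I = 0, II = 0, III = 0))
  expect_equal(nrow(simulate_phenotypes(gen0, seed = 1)), 0)

  gen <- phenotype_generator()
  recs <- simulate_phenotypes(gen, seed = 2)
  expect_equal(unname(table(recs$pupa_type)[c("I", "II", "III")]),
               c(21L, 23L, 16L), ignore_attr = TRUE)

  deg <- phenotype_generator(
    pupa_counts = c(III = 50),
    class_probs = matrix(c(0, 0, 0, 0, 1), nrow = 1,
                         dimnames = list("III", NULL)))
  expect_true(all(simulate_phenotypes(deg, seed = 3)$adult_class == 5L))

  expect_error(phenotype_generator(pupa_counts = c(I = -1)), ">= 0")
  expect_error(phenotype_generator(
    pupa_counts = c(I = 2),
    class_probs = matrix(c(0.5, 0.2, 0.1, 0.1, 0.3), nrow = 1)),
    "sum to 1")
})

test_that("phenotype class frequencies converge to the requested distribution", {
  n <- 10000
  gen <- phenotype_generator(pupa_counts = c(I = n, II = n, III = n))
  recs <- simulate_phenotypes(gen, seed = 4)
  p_ix <- c(I = 5 / 21, II = 18 / 23, III = 15 / 16)
  for (type in names(p_ix)) {
    emp <- mean(recs$adult_class[recs$pupa_type == type] >= 3)
    bound <- 3 * sqrt(p_ix[[type]] * (1 - p_ix[[type]]) / n)
    expect_lt(abs(emp - p_ix[[type]]), bound)
  }
})
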