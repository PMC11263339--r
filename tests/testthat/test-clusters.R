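pair_row <- function(a, b, lfc, fdr) {
  tibble::tibble(gene_id = "g", log2fc = lfc, fdr = fdr,
                 mean_fpkm_a = a, mean_fpkm_b = b)
}

test_that("the pair decision tree reproduces its defining cases", {
  t <- thresholds()
  # both means under the floor -> low, whatever the fold change
  expect_equal(categorize_pair(pair_row(0.5, 0.8, 5, 1e-9), t)$category, "low")
  # significant but under the fold threshold -> unbiased
  expect_equal(categorize_pair(pair_row(10, 28, 1.49, 0.001), t)$category, "unbiased")
  # strong fold with one side silent -> specific towards the high side (A here)
  res <- categorize_pair(pair_row(12, 0.3, -5, 1e-6), t, "A", "B")
  expect_equal(res$category, "specific")
  expect_equal(res$high, "A")
  # strong fold, both sides expressed -> biased
  res <- categorize_pair(pair_row(40, 5, -3, 0.001), t, "A", "B")
  expect_equal(res$category, "biased")
  expect_equal(res$high, "A")
  # non-significant strong fold -> unbiased
  expect_equal(categorize_pair(pair_row(40, 2, -4, 0.3), t)$category, "unbiased")
})

test_that("pair categories partition classifiable genes and direction is coherent", {
  set.seed(7)
  grid <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    mean_fpkm_a = runif(200, 0, 50),
    mean_fpkm_b = runif(200, 0, 50),
    log2fc = runif(200, -8, 8),
    fdr = runif(200))
  res <- categorize_pair(grid)
  expect_true(all(res$category %in% c("low", "unbiased", "specific", "biased")))
  expect_true(all(is.na(res$high) == (res$category %in% c("low", "unbiased"))))
})

test_that("raising the low floor never moves a low gene to specific/biased", {
  set.seed(8)
  grid <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    mean_fpkm_a = runif(200, 0, 3),
    mean_fpkm_b = runif(200, 0, 3),
    log2fc = runif(200, -8, 8),
    fdr = runif(200, 0, 0.04))
  lo <- categorize_pair(grid, thresholds(fpkm_low = 1))
  hi <- categorize_pair(grid, thresholds(fpkm_low = 2))
  was_low <- lo$category == "low"
  expect_true(all(hi$category[was_low] == "low"))
})

test_that("flipping comparison orientation flips direction but not label", {
  set.seed(9)
  grid <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    mean_fpkm_a = runif(100, 0, 40),
    mean_fpkm_b = runif(100, 0, 40),
    log2fc = runif(100, -8, 8),
    fdr = runif(100))
  fwd <- categorize_pair(grid, a_label = "male", b_label = "female")
  flipped <- grid
  flipped$mean_fpkm_a <- grid$mean_fpkm_b
  flipped$mean_fpkm_b <- grid$mean_fpkm_a
  flipped$log2fc <- -grid$log2fc
  rev <- categorize_pair(flipped, a_label = "female", b_label = "male")
  expect_equal(fwd$category, rev$category)
  expect_equal(fwd$high, rev$high)
})

test_that("missing FDR with a large fold change cannot be classified", {
  expect_error(categorize_pair(pair_row(10, 200, 4, NA)), "missing FDR")
})

test_that("the combine rule follows consistency, low-exclusion and conflicts", {
  pc <- function(cat, high = NA_character_) {
    tibble::tibble(gene_id = "g", category = cat, high = high)
  }
  comb <- function(...) build_cluster(list(...))$subtype
  expect_equal(comb(pc("specific", "female"), pc("specific", "female")),
               "female_specific")
  expect_equal(comb(pc("specific", "female"), pc("unbiased")), "none")
  expect_equal(comb(pc("specific", "female"), pc("biased", "female")),
               "female_biased")
  expect_equal(comb(pc("biased", "female"), pc("biased", "male")), "none")
  expect_equal(comb(pc("low"), pc("low")), "low")
  # low comparisons are uninformative, not disqualifying
  expect_equal(comb(pc("specific", "female"), pc("low")), "female_specific")
  # any-one rule admits a single qualifying comparison
  expect_equal(build_cluster(list(pc("specific", "U"), pc("unbiased")),
                             rule = "any")$subtype, "U_specific")
  # four consistent biased tissue calls
  expect_equal(comb(pc("biased", "reproductive"), pc("biased", "reproductive"),
                    pc("biased", "reproductive"), pc("biased", "reproductive")),
               "reproductive_biased")
})

test_that("build_all_clusters names any missing comparison table", {
  expect_error(build_all_clusters(list()), "U_female_reproductive_over_U_male_reproductive")
})

test_that("planted cluster labels are recovered on the strong-effect simulation", {
  fix <- planted_pipeline_fixture()
  tr <- fix$truth
  mem <- fix$membership

  sub_of <- function(gene, cluster) {
    mem$subtype[mem$gene_id == gene & mem$cluster == cluster]
  }
  # sex-class genes judged in the sex cluster of their expressed tissue(s)
  sex_genes <- tr[tr$class %in% c("sex_specific", "sex_biased"), ]
  ok <- vapply(seq_len(nrow(sex_genes)), function(i) {
    g <- sex_genes[i, ]
    suffix <- sub("sex_", "", g$class)
    want <- paste0(g$direction, "_", suffix)
    cl <- if (is.na(g$tissue_direction) || g$tissue_class == "unbiased") {
      c("REPRODUCTIVE_SEX", "CARCASS_SEX")
    } else if (g$tissue_direction == "reproductive") "REPRODUCTIVE_SEX" else "CARCASS_SEX"
    all(vapply(cl, function(x) identical(sub_of(g$gene_id, x), want), logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # species and tissue classes
  for (cls in c("species_specific", "species_biased")) {
    genes <- tr[tr$class == cls, ]
    want <- paste0(genes$direction, "_", sub("species_", "", cls))
    got_r <- mem$subtype[match(paste0(genes$gene_id, "REPRODUCTIVE_SPECIES"),
                               paste0(mem$gene_id, mem$cluster))]
    got_c <- mem$subtype[match(paste0(genes$gene_id, "CARCASS_SPECIES"),
                               paste0(mem$gene_id, mem$cluster))]
    expect_gte(mean(got_r == want & got_c == want), 0.9)
  }
  for (cls in c("tissue_specific", "tissue_biased")) {
    genes <- tr[tr$class == cls, ]
    want <- paste0(genes$direction, "_", sub("tissue_", "", cls))
    got <- mem$subtype[match(paste0(genes$gene_id, "TISSUE"),
                             paste0(mem$gene_id, mem$cluster))]
    expect_gte(mean(got == want), 0.9)
  }

  # low-expression genes never reach any subtype
  low_genes <- tr$gene_id[tr$class == "low"]
  low_sub <- mem$subtype[mem$gene_id %in% low_genes]
  expect_true(all(low_sub %in% c("low", "none")))
})

test_that("an all-null simulation yields almost no specific/biased members", {
  d <- default_design()
  tr <- flat_truth(400, mu = 100, phi = 0.05)
  cts <- simulate_counts(d, tr, target_library_size = 3e5, seed = 55)
  de <- run_comparisons(cts, d, cluster_plan())
  mem <- build_all_clusters(de)
  frac_member <- mean(!mem$subtype %in% c("none", "low"))
  expect_lt(frac_member, 0.01)
})
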