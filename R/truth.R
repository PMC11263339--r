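#' Planted gene classes for simulation
#'
#' The simulator plants each gene into one expression class mirroring the
#' categories used by the classification rules: genes expressed below the
#' FPKM detection floor everywhere (`low`), genes with no differential
#' expression (`unbiased`), and genes specific to or biased towards one level
#' of sex, species or tissue.
#'
#' @name truth-table
#' @keywords internal
NULL

.truth_classes <- c("low", "unbiased",
                    "sex_specific", "sex_biased",
                    "species_specific", "species_biased",
                    "tissue_specific", "tissue_biased")
.intersex_behaviors <- c("no_change", "down", "up", "other")

#' Construct and validate a planted-truth table
#'
#' @param truth Data frame with one row per gene and columns:
#'   `gene_id`; `class` (one of `low`, `unbiased`, `sex_specific`,
#'   `sex_biased`, `species_specific`, `species_biased`, `tissue_specific`,
#'   `tissue_biased`); `direction` (the high side: a sex, species or tissue
#'   level, `NA` for low/unbiased); `mu` (expected FPKM on the high side);
#'   `fold_change` (linear, >= 1; high/low ratio for biased genes and for the
#'   intersex shift); `dispersion` (NB dispersion phi, var = mu + phi mu^2);
#'   `specific_fpkm` (expected FPKM on the silent side of specific genes,
#'   < 1); `intersex_behavior` (`no_change`, `down`, `up`, `other`);
#'   `intersex_reference` (`female` or `male`: which normal sex the intersex
#'   mean is derived from); `tissue_class` / `tissue_direction` (optional
#'   secondary tissue axis for sex-class genes: `specific`, `biased`,
#'   `unbiased`).
#' @return A validated tibble of class `ix_truth`.
#' @export
truth_table <- function(truth) {
  truth <- as_tibble(truth)
  required <- c("gene_id", "class", "direction", "mu", "fold_change",
                "dispersion")
  missing <- setdiff(required, names(truth))
  if (length(missing) > 0) {
    abort(paste0("truth table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"specific_fpkm" %in% names(truth)) truth$specific_fpkm <- 0.1
  if (!"intersex_behavior" %in% names(truth)) truth$intersex_behavior <- "no_change"
  if (!"intersex_reference" %in% names(truth)) truth$intersex_reference <- "female"
  if (!"tissue_class" %in% names(truth)) truth$tissue_class <- NA_character_
  if (!"tissue_direction" %in% names(truth)) truth$tissue_direction <- NA_character_

  dup <- truth$gene_id[duplicated(truth$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s) in truth table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(truth$class), .truth_classes)
  if (length(bad) > 0) {
    abort(paste0("unknown planted class(es): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(truth$intersex_behavior), .intersex_behaviors)
  if (length(bad) > 0) {
    abort(paste0("unknown intersex behavior(s): ", paste(bad, collapse = ", ")))
  }
  if (any(truth$mu < 0)) abort("planted mu must be >= 0")
  if (any(truth$fold_change < 1)) abort("fold_change must be >= 1 (linear scale)")
  if (any(truth$dispersion < 0)) abort("dispersion must be >= 0")

  # Direction must name a level of the varied factor, else downstream group
  # lookup is undefined; reject naming the offending gene.
  dir_ok <- function(cls, dir) {
    ifelse(cls %in% c("low", "unbiased"), TRUE,
    ifelse(cls %in% c("sex_specific", "sex_biased"), dir %in% c("male", "female"),
    ifelse(cls %in% c("species_specific", "species_biased"), dir %in% c("U", "M"),
           dir %in% .tissue_levels)))
  }
  bad_dir <- !dir_ok(truth$class, truth$direction)
  if (any(bad_dir)) {
    abort(paste0("truth direction does not name a known group level for gene(s): ",
                 paste(head(truth$gene_id[bad_dir], 5), collapse = ", ")))
  }
  spec_cls <- truth$class %in% c("sex_specific", "species_specific", "tissue_specific")
  if (any(spec_cls & truth$specific_fpkm >= 1)) {
    abort("specific classes require silent-side expected FPKM < 1")
  }
  biased_cls <- truth$class %in% c("sex_biased", "species_biased", "tissue_biased")
  if (any(biased_cls & log2(truth$fold_change) <= 2)) {
    abort("biased classes require log2 fold change > 2")
  }
  if (any(biased_cls & truth$mu / truth$fold_change < 1)) {
    abort("biased classes require both sides >= 1 FPKM")
  }
  class(truth) <- c("ix_truth", setdiff(class(truth), "ix_truth"))
  truth
}

#' Plant a truth table with the standard class mix
#'
#' Builds a deterministic truth table for a given design: a block of each
#' planted class with directions cycling over the factor levels, the rest of
#' the genes unbiased background. The background mean is calibrated so that
#' the expected library composition satisfies the FPKM identity
#' (sum of FPKM x length over genes = 1e9 per sample), making planted FPKM
#' values recoverable from the simulated counts themselves.
#'
#' Sex-class genes also carry a secondary tissue axis (cycling
#' specific / biased / unbiased) so that the six sex-by-tissue gene groups
#' all receive planted members, and an intersex behavior recycled from
#' `intersex_behaviors`.
#'
#' @param n_genes Total number of genes.
#' @param n_low,n_sex_specific,n_sex_biased,n_species_specific,
#'   n_species_biased,n_tissue_specific,n_tissue_biased Genes per planted
#'   class; the remainder is unbiased background.
#' @param mu_high Expected FPKM on the high side of planted effects.
#' @param fold_change Linear fold change for biased genes and the intersex
#'   up/down shift (default 64, i.e. |log2 FC| = 6).
#' @param specific_fpkm Expected FPKM on the silent side of specific genes.
#' @param low_mu Expected FPKM of `low` genes (everywhere).
#' @param dispersion NB dispersion phi shared by all genes.
#' @param intersex_behaviors Character vector recycled over sex-class genes.
#' @param gene_length Uniform transcript length in bp used for calibration.
#' @param design Design used for background calibration.
#' @return An `ix_truth` tibble.
#' @export
plant_truth <- function(n_genes = 2000,
                        n_low = 50,
                        n_sex_specific = 60,
                        n_sex_biased = 60,
                        n_species_specific = 30,
                        n_species_biased = 30,
                        n_tissue_specific = 40,
                        n_tissue_biased = 40,
                        mu_high = 400,
                        fold_change = 64,
                        specific_fpkm = 0.1,
                        low_mu = 0.3,
                        dispersion = 0.05,
                        intersex_behaviors = "no_change",
                        gene_length = 1000,
                        design = default_design()) {
  n_special <- n_low + n_sex_specific + n_sex_biased + n_species_specific +
    n_species_biased + n_tissue_specific + n_tissue_biased
  if (n_special > n_genes) {
    abort("class counts exceed n_genes")
  }
  n_bg <- n_genes - n_special
  mk <- function(cls, n, dirs) {
    if (n == 0) return(NULL)
    tibble(class = cls, direction = rep_len(dirs, n))
  }
  truth <- bind_rows(
    mk("low", n_low, NA_character_),
    mk("sex_specific", n_sex_specific, c("female", "male")),
    mk("sex_biased", n_sex_biased, c("female", "male")),
    mk("species_specific", n_species_specific, c("U", "M")),
    mk("species_biased", n_species_biased, c("U", "M")),
    mk("tissue_specific", n_tissue_specific, .tissue_levels),
    mk("tissue_biased", n_tissue_biased, .tissue_levels),
    mk("unbiased", n_bg, NA_character_)
  )
  truth <- mutate(truth,
                  gene_id = sprintf("G%05d", seq_len(nrow(truth))),
                  mu = ifelse(.data$class == "low", low_mu, mu_high),
                  fold_change = fold_change,
                  dispersion = dispersion,
                  specific_fpkm = specific_fpkm)

  is_sex <- truth$class %in% c("sex_specific", "sex_biased")
  truth$tissue_class <- NA_character_
  truth$tissue_direction <- NA_character_
  truth$tissue_class[is_sex] <- rep_len(c("specific", "biased", "unbiased"),
                                        sum(is_sex))
  truth$tissue_direction[is_sex] <-
    ifelse(truth$tissue_class[is_sex] == "unbiased", NA_character_,
           rep_len(.tissue_levels, sum(is_sex)))
  truth$intersex_behavior <- "no_change"
  truth$intersex_behavior[is_sex] <- rep_len(intersex_behaviors, sum(is_sex))
  # Intersex profiling compares against the sex whose program the gene
  # belongs to; background genes default to the female reference.
  truth$intersex_reference <- ifelse(is_sex, truth$direction, "female")

  truth <- truth_table(select(truth, "gene_id", dplyr::everything()))

  # Calibrate background mean so expected sum(FPKM * L) = 1e9 per sample.
  if (n_bg > 0) {
    fpkm <- expected_group_fpkm(truth, design)
    bg <- truth$class == "unbiased"
    other_total <- mean(colSums(fpkm[!bg, , drop = FALSE])) * gene_length
    mu_bg <- (1e9 - other_total) / (n_bg * gene_length)
    if (mu_bg <= 0) {
      abort("cannot calibrate background: planted effects exceed the library budget")
    }
    truth$mu[bg] <- mu_bg
  }
  truth
}

#' Expected per-group FPKM matrix implied by a truth table
#'
#' Applies the planted effects multiplicatively over the design's groups:
#' the silent side of a specific gene sits at `specific_fpkm`, the low side
#' of a biased gene at `mu / fold_change`; species effects distinguish the
#' two pure species only (the backcross inherits the high side); intersex
#' group means are derived from the same-tissue backcross mean of the
#' reference sex according to `intersex_behavior` (`no_change` copies it,
#' `down`/`up` divide/multiply by `fold_change`, `other` keeps the intersex
#' mean at the reference but perturbs the normal backcross mean so the
#' pure-species-versus-backcross comparisons deviate).
#'
#' @param truth An `ix_truth` table.
#' @param design An `ix_design`.
#' @return Numeric matrix, genes x groups (dimnames set), of expected FPKM.
#' @export
expected_group_fpkm <- function(truth, design) {
  truth <- truth_table(truth)
  groups <- distinct(as_tibble(design), .data$species, .data$sex, .data$tissue)
  groups$group <- group_id(groups$species, groups$sex, groups$tissue)
  ng <- nrow(truth)
  m <- matrix(truth$mu, nrow = ng, ncol = nrow(groups),
              dimnames = list(truth$gene_id, groups$group))

  spec_factor <- truth$specific_fpkm / pmax(truth$mu, .Machine$double.eps)
  bias_factor <- 1 / truth$fold_change

  low_side <- function(cls_specific, cls_biased) {
    ifelse(truth$class == cls_specific, spec_factor,
           ifelse(truth$class == cls_biased, bias_factor, 1))
  }

  for (j in seq_len(nrow(groups))) {
    g <- groups[j, ]
    if (g$sex == "intersex") next
    f <- rep(1, ng)
    # sex effect (applies across species, incl. normal backcross samples)
    sex_f <- low_side("sex_specific", "sex_biased")
    off <- truth$class %in% c("sex_specific", "sex_biased") & truth$direction != g$sex
    f[off] <- f[off] * sex_f[off]
    # species effect (pure species only; backcross carries the high side)
    if (g$species %in% c("U", "M")) {
      sp_f <- low_side("species_specific", "species_biased")
      off <- truth$class %in% c("species_specific", "species_biased") &
        truth$direction != g$species
      f[off] <- f[off] * sp_f[off]
    }
    # primary tissue effect
    ti_f <- low_side("tissue_specific", "tissue_biased")
    off <- truth$class %in% c("tissue_specific", "tissue_biased") &
      truth$direction != g$tissue
    f[off] <- f[off] * ti_f[off]
    # secondary tissue axis of sex-class genes
    sec <- !is.na(truth$tissue_class) & truth$tissue_class != "unbiased"
    sec_f <- ifelse(truth$tissue_class %in% "specific", spec_factor, bias_factor)
    off <- sec & truth$tissue_direction != g$tissue
    f[off] <- f[off] * sec_f[off]
    m[, j] <- truth$mu * f
  }

  # 'other' genes: perturb the normal backcross mean of the reference sex so
  # the U-vs-UUM / M-vs-UUM comparisons already deviate from no-change.
  other <- which(truth$intersex_behavior == "other")
  for (i in other) {
    cols <- groups$species == "UUM" & groups$sex == truth$intersex_reference[i]
    m[i, cols] <- m[i, cols] * truth$fold_change[i]
  }

  ix_cols <- which(groups$sex == "intersex")
  for (j in ix_cols) {
    g <- groups[j, ]
    ref_group <- group_id("UUM", truth$intersex_reference, g$tissue)
    missing_ref <- !(ref_group %in% groups$group)
    if (any(missing_ref)) {
      abort(paste0("intersex reference group absent from design for gene(s): ",
                   paste(head(truth$gene_id[missing_ref], 5), collapse = ", ")))
    }
    ref_mean <- m[cbind(seq_len(ng), match(ref_group, groups$group))]
    shift <- ifelse(truth$intersex_behavior == "down", 1 / truth$fold_change,
             ifelse(truth$intersex_behavior == "up", truth$fold_change, 1))
    # 'other' genes keep the (unperturbed) reference level in the intersex
    base <- ifelse(truth$intersex_behavior == "other",
                   ref_mean / truth$fold_change, ref_mean)
    m[, j] <- base * shift
  }
  m
}
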