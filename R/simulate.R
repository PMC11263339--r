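#' Simulate a gene-level count matrix from planted truth
#'
#' Counts are drawn independently per gene and sample from a negative
#' binomial with mean `FPKM * length * library_size / 1e9` and variance
#' `mu + phi * mu^2`; `phi = 0` falls back to Poisson. The same
#' (design, truth, seed) triple always yields the identical matrix.
#'
#' @param design An `ix_design` sample sheet (see [design_spec()]).
#' @param truth An `ix_truth` table (see [truth_table()], [plant_truth()]).
#' @param gene_lengths Optional two-column data frame (`gene_id`,
#'   `length_bp`) or named numeric vector; defaults to 1,000 bp for every
#'   gene so FPKM and counts-per-million coincide up to a constant.
#' @param target_library_size Nominal total fragments per sample used to
#'   scale expected counts (default 1e7).
#' @param seed Integer seed; required, no global RNG state is consumed.
#' @return A tibble (class `ix_counts`): `gene_id` plus one integer column
#'   per sample.
#' @export
simulate_counts <- function(design, truth, gene_lengths = NULL,
                            target_library_size = 1e7, seed) {
  design <- design_spec(design)
  truth <- truth_table(truth)
  if (target_library_size <= 0) abort("target_library_size must be > 0")
  len <- resolve_lengths(gene_lengths, truth$gene_id)

  fpkm <- expected_group_fpkm(truth, design)
  mu <- fpkm[, design$group, drop = FALSE] * len / 1e9 * target_library_size
  phi <- truth$dispersion

  counts <- with_local_seed(seed, {
    out <- matrix(0L, nrow = nrow(mu), ncol = ncol(mu))
    for (j in seq_len(ncol(mu))) {
      m <- mu[, j]
      v <- integer(length(m))
      pois <- phi == 0
      if (any(pois)) v[pois] <- rpois(sum(pois), m[pois])
      if (any(!pois)) {
        v[!pois] <- rnbinom(sum(!pois), mu = m[!pois], size = 1 / phi[!pois])
      }
      out[, j] <- v
    }
    out
  })
  dimnames(counts) <- list(truth$gene_id, design$sample_id)
  counts_matrix_to_tbl(counts)
}

# gene_lengths argument -> named vector over the given gene universe,
# erroring on missing or non-positive lengths.
resolve_lengths <- function(gene_lengths, gene_ids) {
  if (is.null(gene_lengths)) {
    return(setNames(rep(1000, length(gene_ids)), gene_ids))
  }
  if (is.data.frame(gene_lengths)) {
    if (!all(c("gene_id", "length_bp") %in% names(gene_lengths))) {
      abort("gene length table needs columns gene_id, length_bp")
    }
    lv <- setNames(gene_lengths$length_bp, gene_lengths$gene_id)
  } else {
    lv <- gene_lengths
  }
  missing <- setdiff(gene_ids, names(lv))
  if (length(missing) > 0) {
    abort(paste0("no length for gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out <- lv[gene_ids]
  if (any(out <= 0)) abort("gene lengths must be > 0")
  out
}

counts_matrix_to_tbl <- function(m) {
  out <- bind_cols(tibble(gene_id = rownames(m)),
                   as_tibble(m, .name_repair = "minimal"))
  class(out) <- c("ix_counts", class(out))
  out
}

counts_tbl_to_matrix <- function(counts) {
  counts <- as_tibble(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  m
}

#' Specify a backcross phenotype generator
#'
#' Describes, per pupa type, how many individuals to draw and the categorical
#' distributions of their adult traits. The defaults emulate the UUM
#' backcross: pupa-type counts (21, 23, 16) for types I-III, with the
#' probability of an intersex adult (germline classes 3-5) rising from 5/21
#' through 18/23 to 15/16, the probability of retaining both male accessory
#' glands falling from 16/21 to 1/16, and the probability of carrying no
#' spermatheca falling from 16/21 to 1/16. Within the normal (1-2) and
#' intersex (3-5) class blocks, and within the abnormal MAG/spermatheca
#' counts, mass is split evenly.
#'
#' @param pupa_counts Named integer vector over pupa types
#'   (`normal`, `I`, `II`, `III`); missing types mean zero individuals.
#' @param class_probs Matrix (types x 5) of adult germline-class
#'   probabilities, rows summing to 1.
#' @param mag_probs Matrix (types x 3) over MAG counts 0..2.
#' @param spermatheca_probs Matrix (types x 5) over spermatheca counts 0..4.
#' @param rotation24_yes Named numeric: probability genitalia rotation is
#'   complete at 24 h per type.
#' @param eclosion_prob Named numeric: probability the pupa ecloses; adults
#'   that die leave all adult-stage fields missing.
#' @return A list of class `ix_phenogen`.
#' @export
phenotype_generator <- function(pupa_counts = c(I = 21, II = 23, III = 16),
                                class_probs = NULL,
                                mag_probs = NULL,
                                spermatheca_probs = NULL,
                                rotation24_yes = NULL,
                                eclosion_prob = NULL) {
  if (any(pupa_counts < 0)) abort("pupa counts must be >= 0")
  types <- names(pupa_counts)
  if (is.null(types) || any(!types %in% c("normal", "I", "II", "III"))) {
    abort("pupa_counts must be named with types among normal, I, II, III")
  }
  split_block <- function(p_main, main_idx, k) {
    # p_main on the 'main' cells (evenly), remainder evenly on the others
    out <- rep((1 - p_main) / (k - length(main_idx)), k)
    out[main_idx] <- p_main / length(main_idx)
    out
  }
  p_ix_default <- c(normal = 0, I = 5 / 21, II = 18 / 23, III = 15 / 16)
  p_mag2_default <- c(normal = 1, I = 16 / 21, II = 5 / 23, III = 1 / 16)
  p_sp0_default <- c(normal = 1, I = 16 / 21, II = 3 / 23, III = 1 / 16)
  if (is.null(class_probs)) {
    class_probs <- t(vapply(types, function(t)
      split_block(p_ix_default[[t]], 3:5, 5), numeric(5)))
  }
  if (is.null(mag_probs)) {
    mag_probs <- t(vapply(types, function(t)
      split_block(p_mag2_default[[t]], 3, 3), numeric(3)))
  }
  if (is.null(spermatheca_probs)) {
    spermatheca_probs <- t(vapply(types, function(t)
      split_block(p_sp0_default[[t]], 1, 5), numeric(5)))
  }
  if (is.null(rotation24_yes)) {
    rotation24_yes <- setNames(ifelse(types == "normal", 1, 0.5), types)
  }
  if (is.null(eclosion_prob)) {
    eclosion_prob <- setNames(rep(1, length(types)), types)
  }
  for (nm in list(class_probs, mag_probs, spermatheca_probs)) {
    if (any(nm < 0) || any(abs(rowSums(nm) - 1) > 1e-8)) {
      abort("trait probabilities must be non-negative and sum to 1 per pupa type")
    }
  }
  structure(list(pupa_counts = pupa_counts, class_probs = class_probs,
                 mag_probs = mag_probs, spermatheca_probs = spermatheca_probs,
                 rotation24_yes = rotation24_yes,
                 eclosion_prob = eclosion_prob, types = types),
            class = "ix_phenogen")
}

#' Draw per-individual phenotype records
#'
#' @param gen An `ix_phenogen` from [phenotype_generator()].
#' @param seed Integer seed.
#' @return Tibble with one row per individual: `individual_id`, `pupa_type`,
#'   `adult_class` (1-5 or NA if died), `mag_count`, `spermatheca_count`,
#'   `rotation_24h`, `rotation_48h`.
#' @export
simulate_phenotypes <- function(gen, seed) {
  stopifnot(inherits(gen, "ix_phenogen"))
  n_total <- sum(gen$pupa_counts)
  if (n_total == 0) {
    return(tibble(individual_id = character(0), pupa_type = character(0),
                  adult_class = integer(0), mag_count = integer(0),
                  spermatheca_count = integer(0), rotation_24h = character(0),
                  rotation_48h = character(0)))
  }
  with_local_seed(seed, {
    recs <- purrr::map(gen$types, function(t) {
      n <- gen$pupa_counts[[t]]
      if (n == 0) return(NULL)
      eclosed <- stats::runif(n) < gen$eclosion_prob[[t]]
      cls <- sample.int(5, n, replace = TRUE, prob = gen$class_probs[t, ])
      mag <- sample.int(3, n, replace = TRUE, prob = gen$mag_probs[t, ]) - 1L
      sp <- sample.int(5, n, replace = TRUE, prob = gen$spermatheca_probs[t, ]) - 1L
      rot24 <- ifelse(stats::runif(n) < gen$rotation24_yes[[t]], "yes", "no")
      rot48 <- ifelse(rot24 == "yes", "n/a",
                      ifelse(stats::runif(n) < 0.5, "yes", "no"))
      tibble(pupa_type = t,
             adult_class = ifelse(eclosed, cls, NA_integer_),
             mag_count = ifelse(eclosed, mag, NA_integer_),
             spermatheca_count = ifelse(eclosed, sp, NA_integer_),
             rotation_24h = ifelse(eclosed, rot24, NA_character_),
             rotation_48h = ifelse(eclosed, rot48, NA_character_))
    })
    out <- bind_rows(recs)
    out <- mutate(out,
                  individual_id = sprintf("ind%04d", seq_len(nrow(out))),
                  adult_class = as.integer(.data$adult_class),
                  mag_count = as.integer(.data$mag_count),
                  spermatheca_count = as.integer(.data$spermatheca_count))
    select(out, "individual_id", dplyr::everything())
  })
}
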