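#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols distinct pull rename
#'   across n all_of any_of count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats p.adjust pchisq rnbinom rpois setNames sd var
#' @importFrom utils head
NULL

# Factor vocabularies shared by the whole pipeline. "U" = Ae. aegypti Uganda,
# "M" = Ae. mascarensis, "UUM" = first-generation backcross to Uganda females.
.species_levels <- c("U", "M", "UUM")
.sex_levels <- c("male", "female", "intersex")
.tissue_levels <- c("reproductive", "carcass")

#' Build a sample-group identifier
#'
#' Groups are the units of replication: one per (species, sex, tissue)
#' combination. The full two-species + backcross design has 14 of them.
#'
#' @param species Character vector of species codes (`"U"`, `"M"`, `"UUM"`).
#' @param sex Character vector (`"male"`, `"female"`, `"intersex"`).
#' @param tissue Character vector (`"reproductive"`, `"carcass"`).
#' @return Character vector of group ids, `species_sex_tissue`.
#' @export
group_id <- function(species, sex, tissue) {
  paste(species, sex, tissue, sep = "_")
}

#' Validate a sample sheet as a design specification
#'
#' Checks the factor levels, uniqueness of sample ids and the constraint that
#' intersex individuals only occur in the backcross (genetic males carrying
#' the mascarensis M-locus), and attaches a `group` column.
#'
#' @param samples Data frame with columns `sample_id`, `species`, `sex`,
#'   `tissue`, `replicate`.
#' @return A tibble of class `ix_design` with an added `group` column.
#' @export
design_spec <- function(samples) {
  samples <- as_tibble(samples)
  required <- c("sample_id", "species", "sex", "tissue", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(samples) == 0) {
    abort("sample sheet is empty: a design needs at least one sample")
  }
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_species <- setdiff(unique(samples$species), .species_levels)
  if (length(bad_species) > 0) {
    abort(paste0("unknown species level(s): ", paste(bad_species, collapse = ", "),
                 " (expected ", paste(.species_levels, collapse = ", "), ")"))
  }
  bad_sex <- setdiff(unique(samples$sex), .sex_levels)
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex level(s): ", paste(bad_sex, collapse = ", ")))
  }
  bad_tissue <- setdiff(unique(samples$tissue), .tissue_levels)
  if (length(bad_tissue) > 0) {
    abort(paste0("unknown tissue level(s): ", paste(bad_tissue, collapse = ", ")))
  }
  bad_ix <- samples$sample_id[samples$sex == "intersex" & samples$species != "UUM"]
  if (length(bad_ix) > 0) {
    abort(paste0("intersex samples must have species UUM: ",
                 paste(bad_ix, collapse = ", ")))
  }
  if (any(samples$replicate < 1)) {
    abort("replicate indices must be >= 1")
  }
  samples <- mutate(samples,
                    replicate = as.integer(.data$replicate),
                    group = group_id(.data$species, .data$sex, .data$tissue))
  class(samples) <- c("ix_design", class(samples))
  samples
}

#' Default 14-group backcross design
#'
#' Two pure species (U, M) by two sexes by two tissues give 8 groups; the
#' backcross (UUM) contributes normal males, normal females and intersexes in
#' both tissues for 6 more. With 3 replicates each this is the standard
#' 42-sample layout.
#'
#' @param replicates Number of biological replicates per group (default 3).
#' @return An `ix_design` tibble.
#' @export
default_design <- function(replicates = 3) {
  pure <- expand.grid(species = c("U", "M"), sex = c("male", "female"),
                      tissue = .tissue_levels, stringsAsFactors = FALSE)
  bc <- expand.grid(species = "UUM", sex = .sex_levels,
                    tissue = .tissue_levels, stringsAsFactors = FALSE)
  groups <- bind_rows(as_tibble(pure), as_tibble(bc))
  samples <- tidyr::crossing(groups, replicate = seq_len(replicates))
  samples <- mutate(samples,
                    sample_id = paste(group_id(.data$species, .data$sex, .data$tissue),
                                      .data$replicate, sep = "_rep"))
  design_spec(select(samples, "sample_id", "species", "sex", "tissue", "replicate"))
}

# Sample ids belonging to one group; errors if the group is absent.
samples_of_group <- function(design, group) {
  ids <- design$sample_id[design$group == group]
  if (length(ids) == 0) {
    abort(paste0("no samples in group '", group, "'"))
  }
  ids
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
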