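# Age-balanced dataset construction and participant-wise cross-validation.
#
# Cohorts recruited through campus channels are heavily skewed toward
# under-30 participants. To balance the age distribution, the under-30
# group is split into 7 disjoint participant-wise subsets; each subset is
# combined with the full 30s/40s/50s groups to form 7 datasets of
# comparable mean age. Model metrics are averaged across the 7 datasets.

#' Partition the under-30 participants into 7 subsets
#'
#' Random, seeded, disjoint and exhaustive partition with subset sizes
#' `floor(n/7)` or `ceil(n/7)` (sizes differ by at most 1). For the study's
#' n = 125 this yields the 17 + 6x18 split.
#'
#' @param under30_ids character vector of participant ids.
#' @param seed integer seed.
#' @param n_subsets number of subsets (default 7).
#' @return list of `n_subsets` character vectors.
#' @export
partition_under30 <- function(under30_ids, seed, n_subsets = 7L) {
  n <- length(under30_ids)
  if (n < n_subsets) {
    stop("need at least ", n_subsets, " under-30 participants, got ", n)
  }
  with_seed(seed, {
    shuffled <- sample(under30_ids)
    # sizes floor(n/k) with the remainder distributed one-per-subset
    sizes <- rep(n %/% n_subsets, n_subsets)
    rem <- n %% n_subsets
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    split(shuffled, rep(seq_len(n_subsets), times = sizes))
  })
}

#' Build the 7 age-balanced datasets
#'
#' Each dataset is one under-30 subset combined with every participant aged
#' 30 or over. Every older participant appears in all 7 datasets; every
#' under-30 participant in exactly one.
#'
#' @param cohort manifest with `participant_id`, `age`, `sex` (e.g. from
#'   [generate_cohort()] or [read_cohort()]).
#' @param seed seed for the under-30 partition.
#' @param n_datasets number of datasets (default 7).
#' @return `data.table` `dataset_idx, participant_id, age, sex` with one
#'   row per (dataset, participant).
#' @export
build_balanced_datasets <- function(cohort, seed, n_datasets = 7L) {
  cohort <- as.data.table(cohort)
  under30 <- cohort[age < 30, participant_id]
  older <- cohort[age >= 30, participant_id]
  subsets <- partition_under30(under30, seed, n_datasets)
  out <- rbindlist(lapply(seq_len(n_datasets), function(d) {
    data.table(dataset_idx = d, participant_id = c(subsets[[d]], older))
  }))
  out <- cohort[, .(participant_id, age, sex)][out, on = "participant_id"]
  setcolorder(out, c("dataset_idx", "participant_id", "age", "sex"))
  setorder(out, dataset_idx, participant_id)
  out[]
}

#' Assign participant-wise cross-validation folds
#'
#' Random, seeded assignment of participants to `k` folds of near-equal
#' size (differing by at most 1), with no age stratification. All of a
#' participant's weekly samples share the participant's fold, so no
#' individual contributes to both training and test sets.
#'
#' @param participant_ids character vector (one entry per participant).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return named integer vector: fold (1..k) per participant id.
#' @export
make_participant_folds <- function(participant_ids, k = 10L, seed = 1L) {
  ids <- unique(participant_ids)
  if (length(ids) < k) {
    stop("need at least ", k, " participants for ", k, "-fold CV, got ",
         length(ids))
  }
  with_seed(seed, {
    shuffled <- sample(ids)
    fold <- rep(seq_len(k), length.out = length(ids))
    stats::setNames(fold[match(ids, shuffled)], ids)
  })
}

#' Balanced datasets with fold labels
#'
#' Convenience wrapper: [build_balanced_datasets()] plus
#' [make_participant_folds()] per dataset, with per-dataset seeds fanned
#' out from the two master seeds.
#'
#' @param cohort manifest with `participant_id`, `age`, `sex`.
#' @param partition_seed seed for the under-30 partition.
#' @param fold_seed seed for fold assignment.
#' @param k folds per dataset.
#' @param n_datasets number of balanced datasets.
#' @return `data.table` `dataset_idx, participant_id, age, sex, fold`.
#' @export
build_cv_design <- function(cohort, partition_seed = 1L, fold_seed = 2L,
                            k = 10L, n_datasets = 7L) {
  ds <- build_balanced_datasets(cohort, partition_seed, n_datasets)
  ds[, fold := {
    f <- make_participant_folds(participant_id, k,
                                fold_seed + .GRP)
    as.integer(f[participant_id])
  }, by = dataset_idx]
  ds[]
}
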