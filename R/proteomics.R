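#' Filter protein identifications
#'
#' Applies the protein-level identification rule used throughout the
#' metaproteome analysis: a protein is accepted only when supported by at
#' least `min_unique_peptides` exclusively unique peptides. Decoy rows are
#' removed as well (compute the FDR with [estimate_fdr()] beforehand).
#' The removal tally is attached as attribute `"removed"`.
#'
#' @param table Spectral-count tibble with columns `protein_id`,
#'   `exclusive_unique_peptides` and (optionally) `is_decoy`.
#' @param min_unique_peptides Minimum exclusively unique peptides
#'   (default 2).
#' @return The filtered tibble.
#' @export
filter_identifications <- function(table, min_unique_peptides = 2) {
  check_cols(table, c("protein_id", "exclusive_unique_peptides"),
             "spectral count table")
  n0 <- nrow(table)
  out <- filter(table, .data$exclusive_unique_peptides >= min_unique_peptides)
  if ("is_decoy" %in% names(out)) out <- filter(out, !.data$is_decoy)
  attr(out, "removed") <- n0 - nrow(out)
  out
}

#' Target-decoy false discovery rate
#'
#' FDR from a concatenated target-decoy search: every decoy match implies
#' on average one false target match, so
#' \deqn{FDR = 2 D / (T + D)}
#' The simple decoy-to-target ratio `D / T` is available via
#' `method = "ratio"`.
#'
#' @param n_target,n_decoy Accepted target / decoy match counts.
#' @param method `"concatenated"` (default) or `"ratio"`.
#' @return FDR as a fraction.
#' @export
#' @examples
#' estimate_fdr(997, 2)  # ~0.004
estimate_fdr <- function(n_target, n_decoy,
                         method = c("concatenated", "ratio")) {
  method <- match.arg(method)
  check_positive(n_target, "n_target")
  check_positive(n_decoy, "n_decoy", strict = FALSE)
  switch(method,
         concatenated = 2 * n_decoy / (n_target + n_decoy),
         ratio = n_decoy / n_target)
}

#' Normalized spectral abundance factors
#'
#' NSAF per protein and sample: the spectral count divided by protein
#' length, normalized so the values sum to one within each sample,
#' \deqn{NSAF_k = (SpC_k / L_k) / \sum_i (SpC_i / L_i)}
#' Length normalization corrects for the larger number of observable
#' peptides of long proteins; the within-sample normalization makes values
#' comparable across runs of different depth.
#'
#' @param table Tibble with columns `protein_id`, `sample_id`,
#'   `spectral_count` (>= 0) and `length_aa` (> 0).
#' @param sample Optional single sample id; default processes all samples.
#' @return Tibble `protein_id`, `sample_id`, `nsaf`; NSAF sums to 1 within
#'   each sample.
#' @export
nsaf <- function(table, sample = NULL) {
  check_cols(table, c("protein_id", "sample_id", "spectral_count",
                      "length_aa"), "spectral count table")
  check_positive(table$length_aa, "length_aa")
  check_positive(table$spectral_count, "spectral_count", strict = FALSE)
  if (!is.null(sample)) table <- filter(table, .data$sample_id %in% sample)
  if (!nrow(table)) {
    abort("no rows for the requested sample",
          class = "nitrosponge_validation_error")
  }
  out <- table |>
    group_by(.data$sample_id) |>
    mutate(.saf = .data$spectral_count / .data$length_aa,
           .total = sum(.data$.saf)) |>
    ungroup()
  if (any(out$.total == 0)) {
    abort("sample with all-zero spectral counts: NSAF undefined",
          class = "nitrosponge_validation_error")
  }
  out |>
    mutate(nsaf = .data$.saf / .data$.total) |>
    select("protein_id", "sample_id", "nsaf")
}

#' Aggregate NSAF shares by bin or gene-family category
#'
#' Computes NSAF per sample, sums within groups, and averages the group
#' shares across samples (each sample's NSAF already sums to one, so the
#' group sums are shares). Protein-count shares are reported alongside.
#' Proteins without a group label are collected into `unassigned`.
#' Shares are expressed as percentages and sum to 100 across groups.
#'
#' @param table Spectral-count tibble with the [nsaf()] columns plus the
#'   grouping column.
#' @param group_by Name of the grouping column (e.g. `"bin"` or
#'   `"category"`).
#' @param combine Also average the two extreme conventions: `"mean"`
#'   (default) averages per-sample shares; `"summed"` pools counts across
#'   samples before normalizing.
#' @return Tibble `group`, `nsaf_percent`, `protein_percent`, `n_proteins`.
#' @export
aggregate_nsaf <- function(table, group_by = "bin",
                           combine = c("mean", "summed")) {
  combine <- match.arg(combine)
  check_cols(table, c("protein_id", "sample_id", "spectral_count",
                      "length_aa"), "spectral count table")
  if (!group_by %in% names(table)) {
    abort(sprintf("grouping column '%s' not found", group_by),
          class = "nitrosponge_validation_error")
  }
  table <- table |>
    mutate(.group = dplyr::coalesce(as.character(.data[[group_by]]),
                                    "unassigned"))
  if (combine == "summed") {
    table <- table |>
      group_by(.data$protein_id, .data$.group, .data$length_aa) |>
      summarise(spectral_count = sum(.data$spectral_count),
                .groups = "drop") |>
      mutate(sample_id = "pooled")
  }
  per <- nsaf(table) |>
    left_join(distinct(table, .data$protein_id, .data$.group),
              by = "protein_id") |>
    group_by(.data$sample_id, .data$.group) |>
    summarise(share = sum(.data$nsaf), .groups = "drop") |>
    tidyr::complete(.data$sample_id, .data$.group,
                    fill = list(share = 0)) |>
    group_by(.data$.group) |>
    summarise(nsaf_percent = 100 * mean(.data$share), .groups = "drop")
  counts <- table |>
    distinct(.data$protein_id, .data$.group) |>
    dplyr::count(.data$.group, name = "n_proteins") |>
    mutate(protein_percent = 100 * .data$n_proteins / sum(.data$n_proteins))
  per |>
    left_join(counts, by = ".group") |>
    rename(group = ".group")
}
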