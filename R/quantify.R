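# Peptide evidence -> filtered, orientation-corrected protein log-ratios.

#' Aggregate peptide evidence to protein-level log-ratios
#'
#' Per protein, the heavy/light log2 ratio is the median of its peptide log2
#' ratios (even counts: mean of the two central values). Proteins are
#' retained only with at least `min_events` quantitation events and at least
#' `min_unique` unique peptides in the experiment. The oriented log-ratio
#' re-expresses the H/L ratio on the allele1/allele2 scale: it equals the
#' raw log2 H/L in forward experiments and its negative in reverse
#' experiments.
#'
#' @param experiment A `pulldown_experiment` (see [simulate_pair()],
#'   [read_evidence()]).
#' @param min_events Minimum quantitation events per protein (default 2).
#' @param min_unique Minimum unique peptides per protein (default 1).
#' @return Tibble with columns `experiment_id`, `protein_id`, `n_events`,
#'   `n_unique_peptides`, `log2_ratio_hl`, `log2_ratio_oriented`,
#'   `median_intensity`; attribute `n_filtered` counts dropped proteins.
#' @export
aggregate_evidence <- function(experiment, min_events = 2, min_unique = 1) {
  stopifnot(inherits(experiment, "pulldown_experiment"))
  ev <- experiment$evidence
  if (is.null(ev) || nrow(ev) == 0) {
    warning(sprintf("no evidence in experiment %s", experiment$experiment_id),
            call. = FALSE)
    res <- tibble(experiment_id = character(), protein_id = character(),
                  n_events = integer(), n_unique_peptides = integer(),
                  log2_ratio_hl = double(), log2_ratio_oriented = double(),
                  median_intensity = double())
    attr(res, "n_filtered") <- 0L
    return(res)
  }
  sign_or <- if (experiment$orientation == "forward") 1 else -1
  all_q <- ev |>
    group_by(.data$protein_id) |>
    summarise(
      n_events = n(),
      n_unique_peptides = n_distinct(.data$peptide_sequence[.data$is_unique]),
      log2_ratio_hl = median(log2(.data$ratio_hl)),
      median_intensity = median(.data$intensity),
      .groups = "drop"
    )
  keep <- all_q$n_events >= min_events & all_q$n_unique_peptides >= min_unique
  res <- all_q[keep, ] |>
    mutate(
      experiment_id = experiment$experiment_id,
      log2_ratio_oriented = sign_or * .data$log2_ratio_hl
    ) |>
    select("experiment_id", "protein_id", "n_events", "n_unique_peptides",
           "log2_ratio_hl", "log2_ratio_oriented", "median_intensity") |>
    arrange(.data$protein_id)
  attr(res, "n_filtered") <- sum(!keep)
  attr(res, "orientation") <- experiment$orientation
  res
}

#' Median-centre oriented protein log-ratios
#'
#' The extracts are mixed 1:1, so the bulk of (nonspecific) proteins should
#' sit at a log-ratio of 0; any systematic mixing offset is removed by
#' subtracting the experiment-wide median of the oriented log-ratios. The
#' raw `log2_ratio_hl` column is left untouched (the contaminant rule in
#' [call_interactions()] reads pre-normalisation ratios).
#'
#' @param quants Tibble from [aggregate_evidence()].
#' @param min_proteins Minimum proteins required to normalise (default 20);
#'   below this the input is returned unchanged with a warning.
#' @return `quants` with centred `log2_ratio_oriented`; the subtracted
#'   offset is stored in attribute `normalization_offset`.
#' @export
normalize_quants <- function(quants, min_proteins = 20) {
  if (nrow(quants) < min_proteins) {
    warning(sprintf(
      "only %d proteins (< %d); normalization skipped", nrow(quants), min_proteins),
      call. = FALSE)
    attr(quants, "normalization_offset") <- 0
    return(quants)
  }
  offset <- median(quants$log2_ratio_oriented)
  quants$log2_ratio_oriented <- quants$log2_ratio_oriented - offset
  attr(quants, "normalization_offset") <- offset
  quants
}
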