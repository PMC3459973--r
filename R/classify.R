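# Two-dimensional interaction-plot classification (quadrant semantics).

#' Classify proteins on the label-swap interaction plot
#'
#' Proteins quantified in both experiments of a forward/reverse pair are
#' assigned exactly one class, in this precedence order:
#'
#' * `contaminant` -- raw (pre-normalisation) heavy/light ratio below 1 in
#'   *both* orientations: unlabelled proteins ignore the label swap and fall
#'   in the lower-left quadrant. Because roughly a quarter of the background
#'   cloud also sits marginally below 1 in both orientations by chance, the
#'   low ratio must in addition be a significant outlier in both experiments
#'   (low tail in forward, high tail in reverse on the oriented scale, each
#'   at `contaminant_alpha`) -- i.e. the protein is clearly separated from
#'   the bulk, not merely left of it.
#' * `specific_allele1` / `specific_allele2` -- combined p-value below
#'   `threshold` with agreeing oriented directions; the sign of the oriented
#'   log-ratios picks the preferred allele.
#' * `background` -- everything else (the cloud around the origin).
#'
#' Proteins quantified in only one experiment are `not_callable`.
#'
#' Plot convention: `x` is the forward oriented log2(allele1/allele2) ratio
#' and `y` the reverse *raw* log2(H/L) ratio, which reproduces the familiar
#' layout -- allele-1 binders lower-right, allele-2 binders upper-left,
#' contaminants lower-left, background at the origin.
#'
#' @param fwd_quants,rev_quants Quant tibbles of the pair
#'   ([aggregate_evidence()], optionally normalised).
#' @param stats [pair_significance()] result for the same pair.
#' @param threshold Combined p-value cutoff for a specific call
#'   (default 1e-7).
#' @param contaminant_alpha Per-experiment one-sided significance required
#'   for a contaminant call (default 0.01).
#' @param rsid SNP identifier attached to the calls (default taken from the
#'   experiment ids when present).
#' @return Tibble `rsid`, `protein_id`, `x`, `y`, `class`, `p_combined`,
#'   `fold_estimate` (geometric-mean fold change across the pair,
#'   `2^((|fwd| + |rev|)/2)` on oriented log-ratios).
#' @export
call_interactions <- function(fwd_quants, rev_quants, stats, threshold = 1e-7,
                              contaminant_alpha = 0.01, rsid = NULL) {
  if (is.null(rsid)) {
    rsid <- unique(sub("_(forward|reverse)$", "",
                       c(fwd_quants$experiment_id, rev_quants$experiment_id)))
    if (length(rsid) != 1) {
      stop("forward and reverse quants do not form one experiment pair", call. = FALSE)
    }
  }
  fo <- unique(sub(".*_", "", fwd_quants$experiment_id))
  ro <- unique(sub(".*_", "", rev_quants$experiment_id))
  if (length(fo) == 1 && length(ro) == 1 && (fo != "forward" || ro != "reverse")) {
    stop("call_interactions expects a (forward, reverse) experiment pair", call. = FALSE)
  }
  m <- full_join(
    fwd_quants |> select("protein_id", fwd_or = "log2_ratio_oriented",
                         fwd_hl = "log2_ratio_hl"),
    rev_quants |> select("protein_id", rev_or = "log2_ratio_oriented",
                         rev_hl = "log2_ratio_hl"),
    by = "protein_id"
  ) |>
    left_join(stats |> select("protein_id", "p_forward", "p_reverse",
                              "p_combined", "direction_forward", "direction_reverse"),
              by = "protein_id")

  in_both <- !is.na(m$fwd_or) & !is.na(m$rev_or)
  # unlabelled signature: low raw ratio in both orientations, and clearly
  # separated from the bulk (forward low tail, reverse high tail) in both
  contaminant <- in_both & m$fwd_hl < 0 & m$rev_hl < 0 &
    !is.na(m$p_forward) & !is.na(m$p_reverse) &
    (1 - m$p_forward) < contaminant_alpha & m$p_reverse < contaminant_alpha
  agree <- m$direction_forward * m$direction_reverse > 0
  specific <- in_both & !contaminant & !is.na(m$p_combined) &
    m$p_combined < threshold & !is.na(agree) & agree
  cls <- rep("background", nrow(m))
  cls[!in_both] <- "not_callable"
  cls[contaminant] <- "contaminant"
  cls[specific & m$direction_forward > 0] <- "specific_allele1"
  cls[specific & m$direction_forward < 0] <- "specific_allele2"

  tibble(
    rsid = rsid,
    protein_id = m$protein_id,
    x = m$fwd_or,
    y = m$rev_hl,
    class = cls,
    p_combined = m$p_combined,
    fold_estimate = 2^((abs(m$fwd_or) + abs(m$rev_or)) / 2)
  ) |> arrange(.data$protein_id)
}

#' Summarise interaction calls across a screen
#'
#' @param calls A tibble of [call_interactions()] results (rows from one or
#'   more SNPs bound together), or a list of such tibbles.
#' @return List with `per_snp` (per-SNP class counts), `hits` (one row per
#'   specific call: `rsid`, `protein_id`, `allele`, `fold_estimate`,
#'   `p_combined`) and `no_hit_snps` (rsids with zero specific calls).
#' @export
summarize_screen <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- bind_rows(calls)
  if (nrow(calls) == 0) {
    return(list(per_snp = tibble(rsid = character()), hits = tibble(),
                no_hit_snps = character()))
  }
  per_snp <- calls |>
    group_by(.data$rsid) |>
    summarise(
      n_specific_allele1 = sum(.data$class == "specific_allele1"),
      n_specific_allele2 = sum(.data$class == "specific_allele2"),
      n_contaminant = sum(.data$class == "contaminant"),
      n_background = sum(.data$class == "background"),
      n_not_callable = sum(.data$class == "not_callable"),
      .groups = "drop"
    )
  hits <- calls |>
    filter(.data$class %in% c("specific_allele1", "specific_allele2")) |>
    mutate(allele = ifelse(.data$class == "specific_allele1", 1L, 2L)) |>
    select("rsid", "protein_id", "allele", "fold_estimate", "p_combined") |>
    arrange(.data$rsid, .data$p_combined)
  no_hit <- per_snp$rsid[per_snp$n_specific_allele1 + per_snp$n_specific_allele2 == 0]
  list(per_snp = per_snp, hits = hits, no_hit_snps = no_hit)
}
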