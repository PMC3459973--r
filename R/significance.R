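# Ratio-outlier p-values per experiment and label-swap combination.

#' Robust ratio-outlier p-values for one experiment
#'
#' A robust z-score is computed for every protein from the experiment-wide
#' distribution of oriented log2 ratios: the centre is the median, and the
#' scale is asymmetric -- deviations above the median are divided by
#' (84.13th percentile - median), deviations below by
#' (median - 15.87th percentile) -- so that each tail of a skewed pull-down
#' ratio cloud is standardised by its own spread (the outlier test style
#' established for SILAC interaction screens).
#'
#' The reported p-value is the upper-tail normal probability `1 - pnorm(z)`
#' of the signed z, i.e. the one-sided p-value for *allele-1 preference*:
#' small p means a strong allele-1 binder, p near 1 means a strong allele-2
#' binder (whose own one-sided tail is `1 - p`), and the bulk of nonspecific
#' proteins is uniform on (0, 1). `direction` carries the sign of the
#' centred log-ratio; [combine_pvalues()] uses it to pick the
#' direction-consistent tail. P-values are floored at 1e-300.
#'
#' @param quants Tibble from [aggregate_evidence()] (optionally normalised).
#' @param min_proteins Minimum proteins required (default 20).
#' @return Tibble `protein_id`, `log2_ratio_oriented`, `z`, `p`, `direction`.
#' @export
outlier_pvalues <- function(quants, min_proteins = 20) {
  if (nrow(quants) < min_proteins) {
    stop(sprintf("outlier test needs at least %d quantified proteins, got %d",
                 min_proteins, nrow(quants)), call. = FALSE)
  }
  x <- quants$log2_ratio_oriented
  centre <- median(x)
  # pnorm(1) = 0.8413447...: one-sigma percentiles define the two scales
  hi <- quantile(x, pnorm(1), names = FALSE) - centre
  lo <- centre - quantile(x, pnorm(-1), names = FALSE)
  if (hi <= 0 || lo <= 0) {
    stop("degenerate log-ratio distribution (zero spread); check the input evidence",
         call. = FALSE)
  }
  d <- x - centre
  z <- ifelse(d >= 0, d / hi, d / lo)
  p <- pmax(pnorm(z, lower.tail = FALSE), 1e-300)
  tibble(
    protein_id = quants$protein_id,
    log2_ratio_oriented = x,
    z = z,
    p = pmin(p, 1),
    direction = sign(d)
  )
}

#' Combine forward and reverse outlier p-values
#'
#' A protein is only callable as allele-specific when both label
#' orientations prefer the same allele. When the oriented directions agree,
#' the two direction-consistent one-sided tails (`p` for allele-1
#' preference, `1 - p` for allele-2 preference) are combined by Fisher's
#' method (chi-square with 4 degrees of freedom) and the resulting p-value
#' is doubled (capped at 1); when the directions disagree the combined
#' p-value is 1. The doubling is the Bonferroni correction for having
#' tested both directional alternatives (either allele may be preferred):
#' without it the combined value is anti-conservative under the null,
#' because the direction-consistent tails are conditioned to lie below 0.5.
#' With it, null combined p-values are calibrated (their tail probability
#' matches the nominal level). Vectorised; tails are floored at 1e-300.
#'
#' @param p_forward,p_reverse Upper-tail (allele-1 preference) p-values from
#'   [outlier_pvalues()].
#' @param direction_forward,direction_reverse Signs of the centred oriented
#'   log-ratios.
#' @return Combined p-values in (0, 1]; `NA` where either input is `NA`.
#' @export
combine_pvalues <- function(p_forward, direction_forward,
                            p_reverse, direction_reverse) {
  n <- max(length(p_forward), length(p_reverse),
           length(direction_forward), length(direction_reverse))
  p_forward <- rep_len(p_forward, n)
  p_reverse <- rep_len(p_reverse, n)
  direction_forward <- rep_len(direction_forward, n)
  direction_reverse <- rep_len(direction_reverse, n)
  agree <- direction_forward * direction_reverse > 0
  tail_f <- ifelse(direction_forward > 0, p_forward, 1 - p_forward)
  tail_r <- ifelse(direction_reverse > 0, p_reverse, 1 - p_reverse)
  tail_f <- pmin(pmax(tail_f, 1e-300), 1)
  tail_r <- pmin(pmax(tail_r, 1e-300), 1)
  stat <- -2 * (log(tail_f) + log(tail_r))
  p <- pmin(2 * pchisq(stat, df = 4, lower.tail = FALSE), 1)
  out <- ifelse(agree, pmax(p, 1e-300), 1)
  out[is.na(p_forward) | is.na(p_reverse)] <- NA_real_
  out
}

#' Outlier significance across a forward/reverse pair
#'
#' Runs [outlier_pvalues()] on both experiments of a label-swap pair and
#' combines them per protein with [combine_pvalues()]. Proteins quantified
#' in only one experiment get `NA` for the missing side and for
#' `p_combined` (not callable).
#'
#' @param fwd_quants,rev_quants Quant tibbles of the forward and reverse
#'   experiment ([aggregate_evidence()], optionally normalised).
#' @param min_proteins Passed to [outlier_pvalues()].
#' @return Tibble `protein_id`, `p_forward`, `direction_forward`,
#'   `p_reverse`, `direction_reverse`, `p_combined`.
#' @export
pair_significance <- function(fwd_quants, rev_quants, min_proteins = 20) {
  f <- outlier_pvalues(fwd_quants, min_proteins)
  r <- outlier_pvalues(rev_quants, min_proteins)
  res <- full_join(
    f |> select("protein_id", p_forward = "p", direction_forward = "direction"),
    r |> select("protein_id", p_reverse = "p", direction_reverse = "direction"),
    by = "protein_id"
  )
  res$p_combined <- combine_pvalues(res$p_forward, res$direction_forward,
                                    res$p_reverse, res$direction_reverse)
  arrange(res, .data$protein_id)
}
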