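# Downstream validation statistics: ddCt knock-down quantification and
# dual-reporter allele-specific activation.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, delta-Ct is the replicate-mean Ct of the target gene minus
#' the replicate-mean Ct of the reference gene; delta-delta-Ct is the
#' treated sample's delta-Ct minus the control sample's, and relative
#' expression is `2^(-ddct)`. Replicate spread is propagated as the standard
#' deviation of replicate-wise delta-delta-Ct values (treated replicate
#' delta-Ct minus the control-mean delta-Ct). Adding a constant to every Ct
#' (a machine offset) leaves the result unchanged.
#'
#' @param ct Tibble with columns `sample`, `gene`, `replicate`, `ct`
#'   (Ct > 0).
#' @param target_gene Gene whose expression is quantified.
#' @param treated_sample Sample to compare against the control.
#' @param reference_gene Housekeeping reference (default `"GAPDH"`).
#' @param control_sample Control/calibrator sample (default `"mock"`).
#' @return One-row tibble: `target_gene`, `treated_sample`,
#'   `delta_ct_treated`, `delta_ct_control`, `ddct`, `rel_expression`,
#'   `sd_ddct`, `n_replicates`.
#' @export
ddct <- function(ct, target_gene, treated_sample,
                 reference_gene = "GAPDH", control_sample = "mock") {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  pick <- function(sample, gene) ct$ct[ct$sample == sample & ct$gene == gene]
  for (s in c(treated_sample, control_sample)) {
    if (length(pick(s, reference_gene)) == 0) {
      stop(sprintf("reference gene %s missing for sample %s", reference_gene, s),
           call. = FALSE)
    }
    if (length(pick(s, target_gene)) == 0) {
      stop(sprintf("target gene %s missing for sample %s", target_gene, s),
           call. = FALSE)
    }
  }
  dct_treated <- mean(pick(treated_sample, target_gene)) -
    mean(pick(treated_sample, reference_gene))
  dct_control <- mean(pick(control_sample, target_gene)) -
    mean(pick(control_sample, reference_gene))
  ddct_val <- dct_treated - dct_control

  # replicate-wise spread: pair target and reference by replicate id
  tr <- ct[ct$sample == treated_sample & ct$gene == target_gene, ]
  rf <- ct[ct$sample == treated_sample & ct$gene == reference_gene, ]
  paired <- inner_join(tr |> select("replicate", ct_t = "ct"),
                       rf |> select("replicate", ct_r = "ct"),
                       by = "replicate")
  rep_ddct <- (paired$ct_t - paired$ct_r) - dct_control
  n_rep <- nrow(paired)
  sd_ddct <- if (n_rep >= 2) sd(rep_ddct) else {
    warning("single replicate: relative expression reported without spread",
            call. = FALSE)
    NA_real_
  }
  tibble(
    target_gene = target_gene,
    treated_sample = treated_sample,
    delta_ct_treated = dct_treated,
    delta_ct_control = dct_control,
    ddct = ddct_val,
    rel_expression = 2^(-ddct_val),
    sd_ddct = sd_ddct,
    n_replicates = n_rep
  )
}

#' Allele-specific reporter activation with a between-allele test
#'
#' Firefly signals are normalised by the co-transfected renilla signal per
#' replicate. For each allele, the per-replicate percent change of the
#' knock-down condition relative to the mock mean is
#' `100 * (norm_i - mean_mock) / mean_mock`; the allele's activation is the
#' mean of these with their standard deviation. The two alleles are compared
#' by a two-sided Welch (unequal-variance) two-sample t-test on the
#' replicate percent changes. Rescaling all renilla signals by a constant
#' leaves the result unchanged.
#'
#' @param reporter Tibble with columns `condition`, `allele`, `replicate`,
#'   `firefly`, `renilla` (signals > 0); exactly two alleles and a mock
#'   condition must be present.
#' @param knockdown_condition Condition to compare against mock.
#' @param mock_condition Name of the mock condition (default `"mock"`).
#' @return List with `per_allele` (tibble `allele`, `percent_change`,
#'   `sd_percent`, `n`), `p_value` (Welch t, or `NA` with a warning when a
#'   cell has fewer than 2 replicates) and `test`.
#' @export
allele_activation <- function(reporter, knockdown_condition,
                              mock_condition = "mock") {
  stopifnot(all(c("condition", "allele", "replicate", "firefly", "renilla") %in%
                  names(reporter)))
  if (any(reporter$firefly <= 0) || any(reporter$renilla <= 0)) {
    stop("reporter signals must be positive", call. = FALSE)
  }
  alleles <- sort(unique(reporter$allele))
  if (length(alleles) != 2) stop("reporter table must contain exactly two alleles", call. = FALSE)
  for (cond in c(mock_condition, knockdown_condition)) {
    if (!any(reporter$condition == cond)) {
      stop(sprintf("condition '%s' missing from reporter table", cond), call. = FALSE)
    }
  }
  norm <- reporter$firefly / reporter$renilla
  pct <- lapply(alleles, function(a) {
    mock <- norm[reporter$allele == a & reporter$condition == mock_condition]
    kd <- norm[reporter$allele == a & reporter$condition == knockdown_condition]
    if (length(mock) == 0 || length(kd) == 0) {
      stop(sprintf("allele %s lacks mock or knock-down measurements", a), call. = FALSE)
    }
    100 * (kd - mean(mock)) / mean(mock)
  })
  per_allele <- tibble(
    allele = alleles,
    percent_change = vapply(pct, mean, double(1)),
    sd_percent = vapply(pct, function(x) if (length(x) >= 2) sd(x) else NA_real_, double(1)),
    n = vapply(pct, length, integer(1))
  )
  if (any(per_allele$n < 2)) {
    warning("fewer than 2 replicates per allele: between-allele test skipped",
            call. = FALSE)
    p_value <- NA_real_
  } else {
    p_value <- tryCatch(
      t.test(pct[[1]], pct[[2]], var.equal = FALSE)$p.value,
      error = function(e) {
        warning(sprintf("between-allele test skipped: %s", conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
  }
  list(per_allele = per_allele, p_value = p_value,
       test = "Welch two-sample t on replicate percent changes")
}

#' Read a Ct table
#'
#' Tab-delimited with header columns `sample`, `gene`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct)))
  as_tibble(ct)
}

#' Read a dual-reporter table
#'
#' Tab-delimited with header columns `condition`, `allele`, `replicate`,
#' `firefly`, `renilla`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_reporter_table <- function(path) {
  rep_tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("condition", "allele", "replicate", "firefly", "renilla") %in%
                  names(rep_tab)))
  as_tibble(rep_tab)
}
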