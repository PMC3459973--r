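# Shared fixtures, all built in code.

shipped_panel_path <- function() {
  system.file("extdata", "snp_panel_t1d.tsv", package = "snppull")
}

shipped_panel <- function() read_snp_panel(shipped_panel_path())

# minimal two-SNP panel constructed in code
tiny_panel <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "rsid\tgroup\ttag\tsequence",
    "rs0001\tgroup 1\tyes\tACGTACGTAC[A/G]TTGCATGCAT",
    "rs0002\tgroup 2\tno\tGGGTTTCCCA[C/T]AAATTTGGGC"
  ), path)
  read_snp_panel(path)
}

# build a pulldown_experiment directly from per-protein ratio vectors;
# `ratios` is a named list protein_id -> vector of heavy/light ratios
manual_experiment <- function(ratios, orientation = "forward", rsid = "rs0001",
                              unique_flags = NULL) {
  rows <- lapply(names(ratios), function(pid) {
    r <- ratios[[pid]]
    uq <- if (is.null(unique_flags[[pid]])) rep(TRUE, length(r)) else unique_flags[[pid]]
    tibble::tibble(
      experiment_id = paste(rsid, orientation, sep = "_"),
      protein_id = pid,
      peptide_sequence = sprintf("%s_pep%03d", pid, seq_along(r)),
      is_unique = uq,
      ratio_hl = r,
      intensity = 1e7
    )
  })
  structure(list(
    rsid = rsid, orientation = orientation,
    heavy_allele = if (orientation == "forward") "A" else "G",
    light_allele = if (orientation == "forward") "G" else "A",
    experiment_id = paste(rsid, orientation, sep = "_"),
    pulldowns = tibble::tibble(bait_allele = c("A", "G"),
                               extract_label = c("heavy", "light")),
    evidence = dplyr::bind_rows(rows)
  ), class = "pulldown_experiment")
}

# quant tibble straight from oriented log2 ratios (bypasses evidence), for
# significance/classification tests on exactly controlled distributions
manual_quants <- function(log2_oriented, orientation = "forward", rsid = "rs0001",
                          protein_id = sprintf("P%04d", seq_along(log2_oriented))) {
  sgn <- if (orientation == "forward") 1 else -1
  tibble::tibble(
    experiment_id = paste(rsid, orientation, sep = "_"),
    protein_id = protein_id,
    n_events = 3L,
    n_unique_peptides = 2L,
    log2_ratio_hl = sgn * log2_oriented,
    log2_ratio_oriented = log2_oriented,
    median_intensity = 1e7
  )
}

# brute-force IUPAC consensus scan: independent oracle for scan_motif
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

revcomp_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

brute_force_scan <- function(sequence, consensus, max_mismatches = 0) {
  s <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    code <- if (strand == "+") consensus else revcomp_oracle(consensus)
    cc <- strsplit(code, "")[[1]]
    L <- length(cc)
    if (L > length(s)) next
    for (off in 0:(length(s) - L)) {
      mm <- 0
      for (j in seq_len(L)) {
        if (!(s[off + j] %in% iupac_sets_oracle[[cc[j]]])) mm <- mm + 1
      }
      if (mm <= max_mismatches) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          strand = strand, offset = off, mismatches = mm)
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(strand = character(), offset = integer(),
                          mismatches = integer())
  }
  dplyr::arrange(out, offset, strand)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_iupac <- function(n) paste(sample(names(iupac_sets_oracle), n, replace = TRUE),
                                  collapse = "")

# swap allele labels of an analysed pair: the old reverse experiment becomes
# the new forward one (its heavy extract now meets the new allele 1)
mirror_pair <- function(fwd, rev) {
  new_fwd <- rev
  new_fwd$experiment_id <- sub("_reverse$", "_forward", rev$experiment_id)
  new_fwd$log2_ratio_oriented <- -rev$log2_ratio_oriented
  new_rev <- fwd
  new_rev$experiment_id <- sub("_forward$", "_reverse", fwd$experiment_id)
  new_rev$log2_ratio_oriented <- -fwd$log2_ratio_oriented
  list(forward = new_fwd, reverse = new_rev)
}

# knock-down / mock Ct table for the ddct tests
make_ct <- function(treated_target, treated_ref, control_target, control_ref) {
  n <- length(treated_target)
  tibble::tibble(
    sample = rep(c("kd", "kd", "mock", "mock"), each = n),
    gene = rep(c("RUNX1", "GAPDH", "RUNX1", "GAPDH"), each = n),
    replicate = rep(seq_len(n), 4),
    ct = c(treated_target, treated_ref, control_target, control_ref)
  )
}

# dual-reporter table with unit renilla signals
make_reporter <- function(mock_a, kd_a, mock_b, kd_b, renilla = 1) {
  n <- length(mock_a)
  tibble::tibble(
    condition = rep(c("mock", "kd"), each = 2 * n),
    allele = rep(c(rep("A", n), rep("T", n)), 2),
    replicate = rep(seq_len(n), 4),
    firefly = c(mock_a, mock_b, kd_a, kd_b) * renilla,
    renilla = renilla
  )
}
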