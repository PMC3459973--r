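# IUPAC consensus motif scanning on allele baits, both strands.

#' Built-in consensus motifs
#'
#' The two consensus motifs used in the worked examples: CREB1 `TGACG` and
#' the (murine) RUNX1 consensus `TGTGGBH`. Further motifs can be supplied
#' with [read_motifs()].
#'
#' @return Tibble `motif_id`, `consensus`.
#' @export
builtin_motifs <- function() {
  tibble(motif_id = c("CREB1", "RUNX1"), consensus = c("TGACG", "TGTGGBH"))
}

#' Read a motif file
#'
#' Tab-delimited with header columns `motif_id` and `consensus`
#' (IUPAC alphabet).
#'
#' @param path Motif TSV path.
#' @return Tibble `motif_id`, `consensus`.
#' @export
read_motifs <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("motif_id", "consensus") %in% names(m))) {
    stop("motif file must have columns motif_id and consensus", call. = FALSE)
  }
  m$consensus <- toupper(m$consensus)
  check_iupac(m$consensus, "motif consensus")
  as_tibble(m[, c("motif_id", "consensus")])
}

# logical: does each sequence base match the IUPAC code at the same position?
.iupac_position_match <- function(seq_chars, code_chars) {
  vapply(seq_along(code_chars),
         function(j) seq_chars[j] %in% IUPAC_SETS[[code_chars[j]]],
         logical(1))
}

# mismatch counts of `code` against every window of `seq_chars`, vectorised
# across offsets position by position
.window_mismatches <- function(seq_chars, code) {
  code_chars <- strsplit(code, "", fixed = TRUE)[[1]]
  L <- length(code_chars)
  n_win <- length(seq_chars) - L + 1
  mm <- integer(n_win)
  for (j in seq_len(L)) {
    ok <- seq_chars[j:(j + n_win - 1)] %in% IUPAC_SETS[[code_chars[j]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a bait sequence for an IUPAC consensus motif
#'
#' Reports every position on both strands where the consensus matches with
#' at most `max_mismatches` mismatches under IUPAC degeneracy (a consensus
#' code matches any base in its degeneracy set, e.g. B = C/G/T). Minus-strand
#' hits are found by scanning the reverse complement of the consensus and
#' are reported with plus-strand 0-based offsets, so both strands share one
#' coordinate frame.
#'
#' @param sequence Bait sequence (A/C/G/T string), or a one-row tibble from
#'   [allele_baits()] (its `sequence` and `snp_offset` are used).
#' @param consensus IUPAC consensus string, or a one-row tibble from
#'   [builtin_motifs()]/[read_motifs()].
#' @param max_mismatches Allowed mismatch count (default 0).
#' @param snp_offset Optional 0-based SNP position used to set
#'   `overlaps_snp` (TRUE when the SNP lies within `[offset, offset + len)`).
#' @param motif_id Optional motif label for the output.
#' @return Tibble `motif_id`, `strand`, `offset`, `mismatches`,
#'   `overlaps_snp`, ordered by offset then strand.
#' @export
scan_motif <- function(sequence, consensus, max_mismatches = 0,
                       snp_offset = NULL, motif_id = NULL) {
  if (is.data.frame(sequence)) {
    if (is.null(snp_offset) && "snp_offset" %in% names(sequence)) {
      snp_offset <- sequence$snp_offset
    }
    sequence <- sequence$sequence
  }
  if (is.data.frame(consensus)) {
    if (is.null(motif_id)) motif_id <- consensus$motif_id
    consensus <- consensus$consensus
  }
  if (is.null(motif_id)) motif_id <- consensus
  sequence <- toupper(sequence)
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", sequence)) stop("bait sequence must be A/C/G/T", call. = FALSE)
  check_iupac(consensus, "motif consensus")
  empty <- tibble(motif_id = character(), strand = character(), offset = integer(),
                  mismatches = integer(), overlaps_snp = logical())
  L <- nchar(consensus)
  if (L > nchar(sequence)) {
    warning("motif longer than bait; no hits possible", call. = FALSE)
    return(empty)
  }
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hits <- lapply(c("+", "-"), function(strand) {
    code <- if (strand == "+") consensus else reverse_complement(consensus)
    mm <- .window_mismatches(seq_chars, code)
    keep <- which(mm <= max_mismatches)
    tibble(motif_id = motif_id, strand = strand, offset = keep - 1L,
           mismatches = mm[keep])
  })
  out <- bind_rows(hits)
  out$overlaps_snp <- if (is.null(snp_offset)) NA else {
    snp_offset >= out$offset & snp_offset < out$offset + L
  }
  arrange(out, .data$offset, .data$strand)
}

#' Allele-differential motif report for one SNP
#'
#' Scans both allele baits of a panel record for each motif and counts
#' SNP-overlapping hits at 0 and at 1 mismatches. A motif is flagged
#' `differential` when the presence of a perfect (0-mismatch)
#' SNP-overlapping hit differs between the two alleles -- i.e. the SNP
#' creates or destroys the consensus site.
#'
#' @param record One-row panel tibble ([read_snp_panel()]).
#' @param motifs Tibble `motif_id`, `consensus` ([builtin_motifs()] by
#'   default).
#' @return Tibble with one row per motif: `rsid`, `motif_id`, `consensus`,
#'   `allele1`, `allele2`, `n_perfect_allele1`, `n_perfect_allele2`,
#'   `n_1mm_allele1`, `n_1mm_allele2`, `differential`.
#' @export
differential_report <- function(record, motifs = builtin_motifs()) {
  stopifnot(nrow(record) == 1)
  b1 <- allele_sequence(record, 1)
  b2 <- allele_sequence(record, 2)
  count_hits <- function(bait, consensus, mm) {
    h <- scan_motif(bait$sequence, consensus, max_mismatches = mm,
                    snp_offset = bait$snp_offset)
    sum(h$overlaps_snp & h$mismatches <= mm)
  }
  bind_rows(lapply(seq_len(nrow(motifs)), function(i) {
    cons <- motifs$consensus[i]
    n0_1 <- count_hits(b1, cons, 0)
    n0_2 <- count_hits(b2, cons, 0)
    tibble(
      rsid = record$rsid,
      motif_id = motifs$motif_id[i],
      consensus = cons,
      allele1 = record$allele1,
      allele2 = record$allele2,
      n_perfect_allele1 = n0_1,
      n_perfect_allele2 = n0_2,
      n_1mm_allele1 = count_hits(b1, cons, 1),
      n_1mm_allele2 = count_hits(b2, cons, 1),
      differential = (n0_1 > 0) != (n0_2 > 0)
    )
  }))
}
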