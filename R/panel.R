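# SNP panel parsing and allele bait construction.
#
# Panel file dialect: tab-delimited with header, columns `rsid`, `group`,
# `sequence` (flanks around a bracketed allele token, e.g.
# "CCTT...CCAA[A/G]TCGC...ACCA"); an optional `tag` column marks
# haplotype-tagging SNPs. Sequences are uppercased on parse.

PANEL_SEQ_RE <- "^([ACGT]+)\\[([ACGT])/([ACGT])\\]([ACGT]+)$"

#' Read a SNP panel file
#'
#' Parses a tab-delimited SNP panel into one record per row. Each `sequence`
#' must contain exactly one bracketed allele token `[X/Y]` flanked by
#' nonempty A/C/G/T strings; the two alleles must be distinct single bases
#' and rsIDs must be unique.
#'
#' The screened type 1 diabetes panel at the IL2RA locus ships with the
#' package: `system.file("extdata", "snp_panel_t1d.tsv", package = "snppull")`.
#'
#' @param path Path to the panel TSV.
#' @return Tibble with columns `rsid`, `group`, `tag` (logical),
#'   `left_flank`, `allele1`, `allele2`, `right_flank`, `snp_offset`
#'   (0-based offset of the SNP within a bait, i.e. `nchar(left_flank)`).
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    warning("panel file is empty; returning an empty panel", call. = FALSE)
    return(empty_panel())
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("rsid", "group", "sequence")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("panel file lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("panel file has no records; returning an empty panel", call. = FALSE)
    return(empty_panel())
  }
  seqs <- toupper(raw$sequence)
  bad <- !grepl(PANEL_SEQ_RE, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "panel row %d (%s): sequence must be ACGT flanks around exactly one [X/Y] allele token",
      i, raw$rsid[i]), call. = FALSE)
  }
  left <- sub(PANEL_SEQ_RE, "\\1", seqs)
  a1 <- sub(PANEL_SEQ_RE, "\\2", seqs)
  a2 <- sub(PANEL_SEQ_RE, "\\3", seqs)
  right <- sub(PANEL_SEQ_RE, "\\4", seqs)
  same <- a1 == a2
  if (any(same)) {
    i <- which(same)[1]
    stop(sprintf("panel row %d (%s): the two alleles must differ", i, raw$rsid[i]),
         call. = FALSE)
  }
  dup <- duplicated(raw$rsid)
  if (any(dup)) {
    stop(sprintf("duplicate rsid in panel: %s",
                 paste(unique(raw$rsid[dup]), collapse = ", ")), call. = FALSE)
  }
  tag <- if ("tag" %in% names(raw)) {
    tolower(raw$tag) %in% c("yes", "true", "1")
  } else {
    rep(FALSE, nrow(raw))
  }
  tibble(
    rsid = raw$rsid,
    group = raw$group,
    tag = tag,
    left_flank = left,
    allele1 = a1,
    allele2 = a2,
    right_flank = right,
    snp_offset = nchar(left)
  )
}

empty_panel <- function() {
  tibble(rsid = character(), group = character(), tag = logical(),
         left_flank = character(), allele1 = character(), allele2 = character(),
         right_flank = character(), snp_offset = integer())
}

#' Write a SNP panel back to the panel TSV dialect
#'
#' Inverse of [read_snp_panel()]: reassembles the bracketed `[X/Y]` sequence
#' notation. `read_snp_panel(write_snp_panel(p, f))` reproduces `p`.
#'
#' @param panel Panel tibble as returned by [read_snp_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  out <- tibble(
    rsid = panel$rsid,
    group = panel$group,
    tag = ifelse(panel$tag, "yes", "no"),
    sequence = paste0(panel$left_flank, "[", panel$allele1, "/", panel$allele2, "]",
                      panel$right_flank)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Bait sequence for one allele of a panel record
#'
#' The bait is the concatenation left flank + allele base + right flank, so
#' the two allele baits of a record differ at exactly the 0-based offset
#' `nchar(left_flank)`.
#'
#' @param record One-row panel tibble (a single record of [read_snp_panel()]).
#' @param which Allele index, 1 or 2.
#' @return One-row tibble with `rsid`, `which`, `allele`, `sequence`,
#'   `snp_offset`, `length`.
#' @export
allele_sequence <- function(record, which) {
  stopifnot(nrow(record) == 1)
  if (!which %in% c(1, 2)) stop("`which` must be 1 or 2", call. = FALSE)
  allele <- if (which == 1) record$allele1 else record$allele2
  seq <- paste0(record$left_flank, allele, record$right_flank)
  tibble(
    rsid = record$rsid,
    which = as.integer(which),
    allele = allele,
    sequence = seq,
    snp_offset = record$snp_offset,
    length = nchar(seq)
  )
}

#' All allele baits of a panel
#'
#' @param panel Panel tibble from [read_snp_panel()].
#' @return Tibble with two rows per SNP (columns as [allele_sequence()]).
#' @export
allele_baits <- function(panel) {
  if (nrow(panel) == 0) {
    return(allele_sequence(
      tibble(rsid = "x", allele1 = "A", allele2 = "G",
             left_flank = "A", right_flank = "A", snp_offset = 1L), 1)[0, ])
  }
  bind_rows(lapply(seq_len(nrow(panel)), function(i) {
    bind_rows(allele_sequence(panel[i, ], 1), allele_sequence(panel[i, ], 2))
  }))
}
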