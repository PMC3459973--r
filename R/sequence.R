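# DNA string utilities shared by bait construction and motif scanning.
# Coordinates are 0-based, half-open throughout the package.

IUPAC_CODES <- "ACGTRYSWKMBDHVN"
IUPAC_COMPLEMENT <- "TGCAYRSWMKVHDBN"

# degeneracy sets; plain bases map to themselves
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

check_iupac <- function(seq, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", IUPAC_CODES), seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters: %s",
                 what, paste(unique(seq[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Complements every IUPAC code (including ambiguity codes, e.g. B <-> V,
#' H <-> D) and reverses the string. Vectorised over `seq`. The empty string
#' maps to itself and the operation is an involution.
#'
#' @param seq Character vector of uppercase IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CGTCA")   # "TGACG"
#' reverse_complement("ACCCACA") # "TGTGGGT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  seq <- toupper(seq)
  check_iupac(seq)
  comp <- chartr(IUPAC_CODES, IUPAC_COMPLEMENT, seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Build a head-to-tail concatemer of a bait unit
#'
#' Bait density on the streptavidin beads is increased by ligating the
#' double-stranded bait unit head-to-tail via short 5' overhangs; the junction
#' overhang is filled in once per junction, so the top-strand length is
#' `copies * nchar(unit) + (copies - 1) * nchar(overhang)`.
#'
#' The overhang must support *directional* polymerisation and strand-specific
#' fill-in labelling with a modified dATP, which imposes two rules:
#' it may contain only A/T bases, and it must not equal its own reverse
#' complement (a palindromic overhang would also ligate head-to-head).
#' The default `"TT"` (pairing an AA overhang on the opposite strand)
#' satisfies both; `"GG"` or `"AT"` are rejected.
#'
#' @param unit Top-strand sequence of the bait unit (A/C/G/T string), e.g.
#'   the `sequence` of one row of [allele_baits()].
#' @param copies Number of unit copies (>= 1).
#' @param overhang 5' overhang used at each junction; default `"TT"`.
#' @return Top-strand sequence of the concatemer.
#' @export
build_concatemer <- function(unit, copies, overhang = "TT") {
  stopifnot(is.character(unit), length(unit) == 1)
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) stop("concatemer unit must be an A/C/G/T string", call. = FALSE)
  if (!is.numeric(copies) || length(copies) != 1 || copies < 1 || copies != floor(copies)) {
    stop("`copies` must be a positive integer", call. = FALSE)
  }
  overhang <- toupper(overhang)
  if (nchar(overhang) < 1 || grepl("[^AT]", overhang)) {
    stop(sprintf(
      "overhang '%s' is not ligation-compatible: junction fill-in labelling requires A/T-only overhangs",
      overhang), call. = FALSE)
  }
  if (identical(overhang, reverse_complement(overhang))) {
    stop(sprintf(
      "overhang '%s' is palindromic and would anneal to itself head-to-head; use a non-palindromic overhang such as 'TT'",
      overhang), call. = FALSE)
  }
  paste0(unit, strrep(paste0(overhang, unit), copies - 1))
}

#' Write allele baits to a FASTA file
#'
#' Headers are `>rsid_allele`; sequences are wrapped at 60 columns.
#'
#' @param baits Tibble from [allele_baits()] (columns `rsid`, `allele`,
#'   `sequence`), or any tibble with those columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bait_fasta <- function(baits, path) {
  stopifnot(all(c("rsid", "allele", "sequence") %in% names(baits)))
  if (nrow(baits) == 0) stop("no baits to write", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(baits$sequence)
  names(seqs) <- paste(baits$rsid, baits$allele, sep = "_")
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60)
  invisible(path)
}

#' Read a bait FASTA file back into a tibble
#'
#' Inverse of [write_bait_fasta()]: headers `rsid_allele` are split back into
#' their two fields.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `rsid`, `allele`, `sequence`.
#' @export
read_bait_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  allele <- sub(".*_", "", ids)
  rsid <- sub("_[^_]*$", "", ids)
  tibble(rsid = rsid, allele = allele, sequence = unname(as.character(seqs)))
}
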