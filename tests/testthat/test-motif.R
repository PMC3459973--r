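test_that("the CREB1 site is created by the C allele of rs12722522 on the minus strand", {
  panel <- shipped_panel()
  rec <- panel[panel$rsid == "rs12722522", ]
  creb <- builtin_motifs()[builtin_motifs()$motif_id == "CREB1", ]

  hits_c <- scan_motif(allele_sequence(rec, 1), creb)
  snp_hit <- hits_c[hits_c$overlaps_snp, ]
  expect_equal(nrow(snp_hit), 1)
  expect_equal(snp_hit$strand, "-")
  expect_equal(snp_hit$mismatches, 0)
  expect_equal(snp_hit$offset, 26)  # site CGTCA starts at the SNP base

  # the T allele reads TGACA on the minus strand: no perfect SNP-overlapping hit
  hits_t <- scan_motif(allele_sequence(rec, 2), creb)
  expect_equal(sum(hits_t$overlaps_snp), 0)
  # but a single mismatch recovers it
  hits_t1 <- scan_motif(allele_sequence(rec, 2), creb, max_mismatches = 1)
  expect_true(any(hits_t1$overlaps_snp & hits_t1$mismatches == 1))
})

test_that("the degenerate RUNX1 consensus matches the rs12722508 A allele site TGTGGGT", {
  panel <- shipped_panel()
  rec <- panel[panel$rsid == "rs12722508", ]
  runx <- builtin_motifs()[builtin_motifs()$motif_id == "RUNX1", ]

  hits_a <- scan_motif(allele_sequence(rec, 1), runx)
  snp_hit <- hits_a[hits_a$overlaps_snp, ]
  expect_equal(nrow(snp_hit), 1)
  expect_equal(snp_hit$strand, "-")
  # plus-strand site ACCCACA ends at the SNP offset 26
  expect_equal(snp_hit$offset, 20)
  expect_equal(reverse_complement(substr(allele_sequence(rec, 1)$sequence, 21, 27)),
               "TGTGGGT")

  hits_t <- scan_motif(allele_sequence(rec, 2), runx)
  expect_equal(sum(hits_t$overlaps_snp), 0)
})

test_that("differential report flags allele-created sites and ignores fully degenerate motifs", {
  panel <- shipped_panel()
  rep522 <- differential_report(panel[panel$rsid == "rs12722522", ])
  creb_row <- rep522[rep522$motif_id == "CREB1", ]
  expect_true(creb_row$differential)
  expect_equal(creb_row$n_perfect_allele1, 1)
  expect_equal(creb_row$n_perfect_allele2, 0)

  rep508 <- differential_report(panel[panel$rsid == "rs12722508", ])
  runx_row <- rep508[rep508$motif_id == "RUNX1", ]
  expect_true(runx_row$differential)

  # N matches everywhere on both alleles: never differential
  any_n <- differential_report(panel[1, ], tibble::tibble(motif_id = "ANY", consensus = "N"))
  expect_false(any_n$differential)
  expect_gt(any_n$n_perfect_allele1, 0)
})

test_that("the scanner agrees with the brute-force oracle on random motif/bait pairs", {
  set.seed(123)
  for (i in 1:100) {
    bait <- random_dna(sample(20:60, 1))
    motif <- random_iupac(sample(3:8, 1))
    mm <- sample(0:2, 1)
    got <- scan_motif(bait, motif, max_mismatches = mm)[, c("strand", "offset", "mismatches")]
    want <- brute_force_scan(bait, motif, mm)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("scanner invariants: strand symmetry, allele agreement off the SNP, mismatch nesting", {
  set.seed(321)
  panel <- shipped_panel()
  for (i in 1:20) {
    bait <- random_dna(40)
    motif <- random_iupac(sample(4:7, 1))
    L <- nchar(motif)

    # scanning the reverse complement swaps strands and mirrors offsets
    h <- scan_motif(bait, motif, max_mismatches = 1)
    h_rc <- scan_motif(reverse_complement(bait), motif, max_mismatches = 1)
    mirrored <- tibble::tibble(
      strand = ifelse(h_rc$strand == "+", "-", "+"),
      offset = nchar(bait) - h_rc$offset - L,
      mismatches = h_rc$mismatches
    )
    mirrored <- dplyr::arrange(mirrored, offset, strand)
    expect_equal(as.data.frame(h[, c("strand", "offset", "mismatches")]),
                 as.data.frame(mirrored))

    # hit sets are nested in the mismatch budget
    h0 <- scan_motif(bait, motif, max_mismatches = 0)
    expect_true(nrow(dplyr::anti_join(h0, h, by = c("strand", "offset"))) == 0)
  }

  # hits not overlapping the SNP are identical across the two alleles
  for (id in panel$rsid[1:4]) {
    rec <- panel[panel$rsid == id, ]
    for (m in builtin_motifs()$consensus) {
      h1 <- scan_motif(allele_sequence(rec, 1), m, max_mismatches = 1)
      h2 <- scan_motif(allele_sequence(rec, 2), m, max_mismatches = 1)
      expect_equal(as.data.frame(h1[!h1$overlaps_snp, ]),
                   as.data.frame(h2[!h2$overlaps_snp, ]))
    }
  }
})

test_that("motif files read and edge cases behave", {
  m <- read_motifs(system.file("extdata", "motifs_consensus.tsv", package = "snppull"))
  expect_equal(m, builtin_motifs())
  expect_warning(h <- scan_motif("ACGT", "ACGTACGT"), "longer")
  expect_equal(nrow(h), 0)
  expect_error(scan_motif("ACGT", "AXG"), "non-IUPAC")
})
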