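test_that("quadrant calls: tenfold binder, far-low contaminant, origin background", {
  set.seed(2)
  n <- 300
  ids <- c(sprintf("P%04d", 1:n), "HIT", "KERATIN")
  l10 <- log2(10)
  # bulk at the origin; HIT inverts between orientations; KERATIN low in both
  fwd <- manual_quants(c(rnorm(n, sd = 0.2), l10, log2(0.2)), "forward", protein_id = ids)
  rev <- manual_quants(c(rnorm(n, sd = 0.2), l10, -log2(0.2)), "reverse", protein_id = ids)
  st <- pair_significance(fwd, rev)
  calls <- call_interactions(fwd, rev, st, rsid = "rs0001")

  hit <- calls[calls$protein_id == "HIT", ]
  expect_equal(hit$class, "specific_allele1")
  expect_lt(hit$p_combined, 1e-7)
  expect_equal(hit$fold_estimate, 10, tolerance = 1e-6)
  # plot convention: allele-1 binders sit lower-right (x > 0, y = raw reverse < 0)
  expect_gt(hit$x, 0)
  expect_lt(hit$y, 0)

  ker <- calls[calls$protein_id == "KERATIN", ]
  expect_equal(ker$class, "contaminant")
  expect_lt(ker$x, 0)
  expect_lt(ker$y, 0)

  origin <- calls[calls$protein_id == "P0001", ]
  expect_equal(origin$class, "background")
})

test_that("every protein gets exactly one class and singletons are not callable", {
  cfg <- simulation_config(seed = 77, n_background = 300, n_contaminants = 20)
  panel <- tiny_panel()
  binders <- dplyr::bind_rows(binder_spec("B1", 1, 8, 8), binder_spec("B2", 2, 6, 8))
  pair <- simulate_pair(panel[1, ], binders, cfg)
  fq <- normalize_quants(aggregate_evidence(pair$forward))
  rq <- normalize_quants(aggregate_evidence(pair$reverse))
  st <- pair_significance(fq, rq)
  calls <- call_interactions(fq, rq, st, rsid = panel$rsid[1])

  expect_setequal(calls$protein_id, union(fq$protein_id, rq$protein_id))
  expect_true(all(calls$class %in% c("specific_allele1", "specific_allele2",
                                     "contaminant", "background", "not_callable")))
  in_both <- intersect(fq$protein_id, rq$protein_id)
  expect_true(all(calls$class[calls$protein_id %in% in_both] != "not_callable"))
  expect_true(all(calls$class[!calls$protein_id %in% in_both] == "not_callable"))
  expect_equal(calls$class[calls$protein_id == "B1"], "specific_allele1")
  expect_equal(calls$class[calls$protein_id == "B2"], "specific_allele2")
})

test_that("relabelling the alleles swaps the specific classes and nothing else", {
  cfg <- simulation_config(seed = 13, n_background = 300, n_contaminants = 20)
  panel <- tiny_panel()
  binders <- dplyr::bind_rows(binder_spec("B1", 1, 10, 8), binder_spec("B2", 2, 5, 8))
  pair <- simulate_pair(panel[1, ], binders, cfg)
  fq <- aggregate_evidence(pair$forward)
  rq <- aggregate_evidence(pair$reverse)
  calls <- call_interactions(fq, rq, pair_significance(fq, rq), rsid = "rs0001")

  mir <- mirror_pair(fq, rq)
  calls_m <- call_interactions(mir$forward, mir$reverse,
                               pair_significance(mir$forward, mir$reverse),
                               rsid = "rs0001")
  m <- dplyr::inner_join(calls, calls_m, by = "protein_id", suffix = c("", "_m"))
  swap <- c(specific_allele1 = "specific_allele2",
            specific_allele2 = "specific_allele1",
            contaminant = "contaminant", background = "background",
            not_callable = "not_callable")
  expect_equal(m$class_m, unname(swap[m$class]))
  expect_equal(m$fold_estimate_m, m$fold_estimate)
})

test_that("screen summary reports hits with recovered folds and flags silent SNPs", {
  cfg <- simulation_config(seed = 55, n_background = 300, n_contaminants = 10)
  panel <- tiny_panel()
  design <- list(rs0001 = binder_spec("B8", 1, 8, 8))  # rs0002 left empty
  study <- simulate_study(panel, design, cfg)
  calls <- lapply(names(study), function(id) {
    fq <- normalize_quants(aggregate_evidence(study[[id]]$forward))
    rq <- normalize_quants(aggregate_evidence(study[[id]]$reverse))
    call_interactions(fq, rq, pair_significance(fq, rq), rsid = id)
  })
  summ <- summarize_screen(calls)
  expect_equal(nrow(summ$hits), 1)
  expect_equal(summ$hits$protein_id, "B8")
  expect_equal(summ$hits$allele, 1L)
  expect_equal(summ$hits$fold_estimate, 8, tolerance = 0.25)
  expect_equal(summ$no_hit_snps, "rs0002")

  empty <- summarize_screen(list())
  expect_equal(nrow(empty$per_snp), 0)
})

test_that("mismatched experiment pairs are rejected", {
  q1 <- manual_quants(rnorm(30), "forward", rsid = "rs0001")
  q2 <- manual_quants(rnorm(30), "forward", rsid = "rs0001")
  st <- pair_significance(q1, manual_quants(rnorm(30), "reverse", rsid = "rs0001"))
  expect_error(call_interactions(q1, q2, st), "pair")
  q3 <- manual_quants(rnorm(30), "reverse", rsid = "rs0002")
  expect_error(call_interactions(q1, q3, st), "pair")
})
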