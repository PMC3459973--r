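test_that("noise-free simulation reproduces the exact ratio model", {
  panel <- tiny_panel()
  cfg <- simulation_config(seed = 11, n_background = 30, n_contaminants = 5,
                           peptide_noise_sd = 0)

  # null model: every protein at fold 1 -> every ratio 1 in both orientations
  null_pair <- simulate_pair(panel[1, ], binder_spec("B1", 1, 1, 4), cfg)
  non_cont <- function(ev) ev$ratio_hl[!grepl("^CONT", ev$protein_id)]
  expect_true(all(non_cont(null_pair$forward$evidence) == 1))
  expect_true(all(non_cont(null_pair$reverse$evidence) == 1))

  # a fold-10 allele-1 binder: ratio 10 forward, 0.1 reverse
  pair <- simulate_pair(panel[1, ], binder_spec("B1", 1, 10, 6), cfg)
  b_fwd <- pair$forward$evidence$ratio_hl[pair$forward$evidence$protein_id == "B1"]
  b_rev <- pair$reverse$evidence$ratio_hl[pair$reverse$evidence$protein_id == "B1"]
  expect_equal(length(b_fwd), 6)
  expect_equal(b_fwd, rep(10, 6))
  expect_equal(b_rev, rep(0.1, 6))

  # contaminants keep the same sub-unity ratio in both orientations
  cont_f <- pair$forward$evidence$ratio_hl[grepl("^CONT", pair$forward$evidence$protein_id)]
  cont_r <- pair$reverse$evidence$ratio_hl[grepl("^CONT", pair$reverse$evidence$protein_id)]
  expect_true(all(cont_f == 0.2) && all(cont_r == 0.2))

  # orientation bookkeeping
  expect_equal(pair$forward$heavy_allele, panel$allele1[1])
  expect_equal(pair$reverse$heavy_allele, panel$allele2[1])
})

test_that("orientation symmetry holds at zero noise for non-contaminants", {
  panel <- tiny_panel()
  cfg <- simulation_config(seed = 3, n_background = 50, n_contaminants = 5,
                           peptide_noise_sd = 0)
  binders <- dplyr::bind_rows(binder_spec("B1", 1, 4, 5), binder_spec("B2", 2, 7, 5))
  pair <- simulate_pair(panel[1, ], binders, cfg)
  fwd <- dplyr::distinct(pair$forward$evidence, protein_id, ratio_hl)
  rev <- dplyr::distinct(pair$reverse$evidence, protein_id, ratio_hl)
  m <- dplyr::inner_join(fwd, rev, by = "protein_id", suffix = c("_f", "_r"))
  cont <- grepl("^CONT", m$protein_id)
  expect_equal(log2(m$ratio_hl_f[!cont]), -log2(m$ratio_hl_r[!cont]))
  # contaminants violate the symmetry: below 1 in both
  expect_true(all(m$ratio_hl_f[cont] < 1 & m$ratio_hl_r[cont] < 1))
})

test_that("the generator is byte-deterministic in the seed and config guards hold", {
  panel <- tiny_panel()
  cfg <- simulation_config(seed = 99, n_background = 40, n_contaminants = 4)
  p1 <- simulate_pair(panel[1, ], binder_spec("B1", 1, 5, 5), cfg)
  p2 <- simulate_pair(panel[1, ], binder_spec("B1", 1, 5, 5), cfg)
  expect_identical(p1$forward$evidence, p2$forward$evidence)
  expect_identical(p1$reverse$evidence, p2$reverse$evidence)
  # different seed changes the draw
  cfg2 <- simulation_config(seed = 100, n_background = 40, n_contaminants = 4)
  p3 <- simulate_pair(panel[1, ], binder_spec("B1", 1, 5, 5), cfg2)
  expect_false(identical(p1$forward$evidence$ratio_hl, p3$forward$evidence$ratio_hl))

  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, contaminant_hl_ratio = 1.2))
  expect_error(simulate_pair(panel[1, ],
                             dplyr::bind_rows(binder_spec("B1", 1, 5, 5),
                                              binder_spec("B1", 2, 3, 5)), cfg),
               "unique")
})

test_that("the study planner enumerates 4 pull-downs per SNP", {
  panel12 <- shipped_panel()
  expect_equal(nrow(pulldown_plan(panel12)), 48)
  expect_equal(nrow(pulldown_plan(panel12[1, ])), 4)
  expect_equal(nrow(pulldown_plan(panel12[0, ])), 0)

  cfg <- simulation_config(seed = 5, n_background = 20, n_contaminants = 2)
  study <- simulate_study(tiny_panel(), config = cfg)
  expect_equal(length(study), 2)
  expect_equal(sum(vapply(study, function(p) nrow(p$forward$pulldowns) +
                            nrow(p$reverse$pulldowns), 0)), 8)
  expect_error(simulate_study(tiny_panel(), list(rs9999 = binder_spec("B", 1, 2, 3)), cfg),
               "rs9999")
})

test_that("evidence tables round-trip through TSV for ingest mode", {
  panel <- tiny_panel()
  cfg <- simulation_config(seed = 21, n_background = 30, n_contaminants = 3)
  pair <- simulate_pair(panel[1, ], binder_spec("B1", 1, 5, 5), cfg)
  dir <- withr::local_tempdir()
  paths <- write_evidence(pair, dir)
  back <- read_evidence(paths[1], pair$forward$rsid, "forward",
                        pair$forward$heavy_allele, pair$forward$light_allele)
  expect_equal(back$evidence$ratio_hl, pair$forward$evidence$ratio_hl)
  expect_equal(back$experiment_id, pair$forward$experiment_id)
  gt <- readr::read_tsv(paths[3], col_types = readr::cols(), progress = FALSE)
  expect_equal(sum(gt$class == "binder"), 1)
  expect_equal(sum(gt$class == "background"), 30)
})
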