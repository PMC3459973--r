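# End-to-end orchestration: panel -> evidence -> quantify -> significance ->
# classify -> motif -> report, with a machine-readable run log.

#' Run the full screen pipeline
#'
#' Orchestrates the whole analysis for a SNP panel and writes an output
#' directory of tab-delimited results. In `simulate` mode, evidence is
#' generated with [simulate_study()] (ground truth written alongside); in
#' `ingest` mode, evidence TSVs are read per the manifest. The run is
#' deterministic given the configuration and seed.
#'
#' Outputs written to `out_dir`: per-experiment protein quant TSVs
#' (`<rsid>_<orientation>_quant.tsv`), per-SNP significance and call TSVs,
#' `plot_coordinates.tsv` (all calls with plot coordinates and class),
#' `screen_hits.tsv`, `screen_per_snp.tsv`, `motif_differential.tsv` and
#' `run_log.json` (versions, seed, filter counts, normalisation offsets).
#'
#' @param panel Panel tibble from [read_snp_panel()], or a path to a panel
#'   TSV.
#' @param out_dir Output directory (created if needed).
#' @param mode `"simulate"` or `"ingest"`.
#' @param seed Integer seed; mandatory in simulate mode.
#' @param design Named list of binder tibbles for [simulate_study()];
#'   default [example_design()].
#' @param config A [simulation_config()]; built from `seed` with defaults
#'   when omitted.
#' @param evidence_manifest For ingest mode: tibble (or TSV path) with
#'   columns `rsid`, `orientation`, `heavy_allele`, `light_allele`, `path`,
#'   one forward and one reverse row per rsid.
#' @param threshold Combined p-value cutoff for specific calls
#'   (default 1e-7).
#' @param motifs Motif tibble or motif TSV path; default [builtin_motifs()].
#' @param normalize Median-centre oriented log-ratios before testing
#'   (default TRUE).
#' @param min_proteins Minimum quantified proteins for normalisation and the
#'   outlier test (default 20).
#' @return Invisibly, a list with `calls` (all SNPs bound), `summary`
#'   ([summarize_screen()]), `motif_report`, `run_log` and `out_dir`.
#' @export
run_screen <- function(panel, out_dir,
                       mode = c("simulate", "ingest"),
                       seed = NULL, design = NULL, config = NULL,
                       evidence_manifest = NULL,
                       threshold = 1e-7, motifs = builtin_motifs(),
                       normalize = TRUE, min_proteins = 20) {
  mode <- match.arg(mode)
  if (is.character(panel)) panel <- read_snp_panel(panel)
  if (nrow(panel) == 0) stop("panel is empty; nothing to screen", call. = FALSE)
  if (is.character(motifs)) motifs <- read_motifs(motifs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (mode == "simulate") {
    if (is.null(config)) {
      if (is.null(seed)) stop("simulate mode requires a seed", call. = FALSE)
      config <- simulation_config(seed = seed)
    }
    if (is.null(design)) design <- example_design(panel)
    pairs <- simulate_study(panel, design, config)
    for (rsid in names(pairs)) {
      readr::write_tsv(pairs[[rsid]]$ground_truth,
                       file.path(out_dir, paste0(rsid, "_ground_truth.tsv")),
                       progress = FALSE)
    }
  } else {
    if (is.null(evidence_manifest)) {
      stop("ingest mode requires an evidence manifest", call. = FALSE)
    }
    if (is.character(evidence_manifest)) {
      evidence_manifest <- readr::read_tsv(evidence_manifest,
                                           col_types = readr::cols(), progress = FALSE)
    }
    pairs <- lapply(panel$rsid, function(id) {
      rows <- evidence_manifest[evidence_manifest$rsid == id, ]
      if (nrow(rows) != 2 || !setequal(rows$orientation, c("forward", "reverse"))) {
        stop(sprintf("manifest must list one forward and one reverse evidence file for %s", id),
             call. = FALSE)
      }
      get_exp <- function(o) {
        r <- rows[rows$orientation == o, ]
        read_evidence(r$path, id, o, r$heavy_allele, r$light_allele)
      }
      list(forward = get_exp("forward"), reverse = get_exp("reverse"))
    })
    names(pairs) <- panel$rsid
  }

  all_calls <- list()
  filter_log <- list()
  for (id in names(pairs)) {
    pair <- pairs[[id]]
    fq <- aggregate_evidence(pair$forward)
    rq <- aggregate_evidence(pair$reverse)
    offsets <- c(forward = 0, reverse = 0)
    if (normalize) {
      fq <- normalize_quants(fq, min_proteins)
      rq <- normalize_quants(rq, min_proteins)
      offsets <- c(forward = attr(fq, "normalization_offset"),
                   reverse = attr(rq, "normalization_offset"))
    }
    stats <- pair_significance(fq, rq, min_proteins)
    calls <- call_interactions(fq, rq, stats, threshold = threshold, rsid = id)
    readr::write_tsv(fq, file.path(out_dir, paste0(id, "_forward_quant.tsv")), progress = FALSE)
    readr::write_tsv(rq, file.path(out_dir, paste0(id, "_reverse_quant.tsv")), progress = FALSE)
    readr::write_tsv(stats, file.path(out_dir, paste0(id, "_significance.tsv")), progress = FALSE)
    readr::write_tsv(calls, file.path(out_dir, paste0(id, "_calls.tsv")), progress = FALSE)
    all_calls[[id]] <- calls
    filter_log[[id]] <- list(
      n_filtered_forward = attr(fq, "n_filtered"),
      n_filtered_reverse = attr(rq, "n_filtered"),
      normalization_offset_forward = unname(offsets["forward"]),
      normalization_offset_reverse = unname(offsets["reverse"])
    )
  }
  calls <- bind_rows(all_calls)
  summary <- summarize_screen(calls)
  readr::write_tsv(calls, file.path(out_dir, "plot_coordinates.tsv"), progress = FALSE)
  readr::write_tsv(summary$hits, file.path(out_dir, "screen_hits.tsv"), progress = FALSE)
  readr::write_tsv(summary$per_snp, file.path(out_dir, "screen_per_snp.tsv"), progress = FALSE)

  motif_report <- bind_rows(lapply(seq_len(nrow(panel)), function(i) {
    differential_report(panel[i, ], motifs)
  }))
  readr::write_tsv(motif_report, file.path(out_dir, "motif_differential.tsv"), progress = FALSE)

  run_log <- list(
    package = "snppull",
    version = as.character(packageVersion("snppull")),
    r_version = as.character(getRversion()),
    mode = mode,
    seed = if (mode == "simulate") config$seed else NULL,
    threshold = threshold,
    normalize = normalize,
    min_proteins = min_proteins,
    n_snps = nrow(panel),
    n_pulldowns = nrow(pulldown_plan(panel)),
    filters = filter_log
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(calls = calls, summary = summary, motif_report = motif_report,
                 run_log = run_log, out_dir = out_dir))
}
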