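# Synthetic peptide-level SILAC evidence with known ground truth.
#
# The generator emulates a label-swap pull-down pair: a dominant nonspecific
# background (log-ratio ~ 0 in both orientations), unlabelled contaminants
# (heavy/light ratio < 1 in both orientations), and spiked allele-specific
# binders whose ratio inverts between the forward and reverse experiment.

#' Simulation configuration
#'
#' @param seed Integer RNG seed; mandatory (no silent default).
#' @param n_background Number of nonspecific background proteins (true
#'   allele1/allele2 ratio 1).
#' @param n_contaminants Number of unlabelled contaminant proteins.
#' @param contaminant_hl_ratio True heavy/light ratio of contaminants in both
#'   label orientations; must be in (0, 1).
#' @param peptide_noise_sd Standard deviation of peptide-level log2-ratio
#'   noise (multiplicative, lognormal around the protein's true ratio).
#' @param peptides_mean Mean of the truncated-geometric (minimum 1)
#'   peptides-per-protein distribution for background and contaminants.
#' @param unique_frac Fraction of synthetic peptides flagged as unique to
#'   their protein, so the unique-peptide filter is exercised.
#' @param intensity_log10_range Range of log10 peptide intensities
#'   (log-uniform).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_background = 1000,
                              n_contaminants = 50,
                              contaminant_hl_ratio = 0.2,
                              peptide_noise_sd = 0.3,
                              peptides_mean = 3,
                              unique_frac = 0.9,
                              intensity_log10_range = c(6, 9)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  }
  stopifnot(
    n_background >= 0, n_contaminants >= 0,
    contaminant_hl_ratio > 0, contaminant_hl_ratio < 1,
    peptide_noise_sd >= 0, peptides_mean >= 1,
    unique_frac >= 0, unique_frac <= 1,
    length(intensity_log10_range) == 2,
    intensity_log10_range[1] <= intensity_log10_range[2]
  )
  structure(list(
    seed = as.integer(seed),
    n_background = as.integer(n_background),
    n_contaminants = as.integer(n_contaminants),
    contaminant_hl_ratio = contaminant_hl_ratio,
    peptide_noise_sd = peptide_noise_sd,
    peptides_mean = peptides_mean,
    unique_frac = unique_frac,
    intensity_log10_range = intensity_log10_range
  ), class = "sim_config")
}

#' Specification of one spiked binder
#'
#' @param protein_id Protein identifier (unique within a design).
#' @param target_allele Which allele the binder prefers: 1 or 2.
#' @param fold_change True abundance ratio in favour of the target allele
#'   (> 0; e.g. 5 means five-fold enriched on the target allele).
#' @param n_peptides Quantitation events the binder contributes per
#'   pull-down experiment (>= 1).
#' @return One-row tibble.
#' @export
binder_spec <- function(protein_id, target_allele, fold_change, n_peptides) {
  stopifnot(fold_change > 0, n_peptides >= 1, target_allele %in% c(1, 2))
  tibble(protein_id = protein_id, target_allele = as.integer(target_allele),
         fold_change = fold_change, n_peptides = as.integer(n_peptides))
}

# stable small hash so each SNP/orientation gets its own substream
.string_seed <- function(base, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  (as.double(base) * 7919 + h) %% 2147483587 + 1
}

# truncated geometric with minimum 1 and the given mean
.rpeptides <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  rgeom(n, 1 / mean) + 1L
}

.simulate_one <- function(snp, binders, config, orientation) {
  heavy <- if (orientation == "forward") snp$allele1 else snp$allele2
  light <- if (orientation == "forward") snp$allele2 else snp$allele1
  experiment_id <- paste(snp$rsid, orientation, sep = "_")

  n_binders <- if (is.null(binders)) 0L else nrow(binders)
  ids <- c(
    if (n_binders > 0) binders$protein_id,
    sprintf("BG%05d", seq_len(config$n_background)),
    sprintf("CONT%03d", seq_len(config$n_contaminants))
  )
  # true allele1/allele2 ratio, then express as H/L for this orientation
  r12 <- c(
    if (n_binders > 0) ifelse(binders$target_allele == 1L,
                              binders$fold_change, 1 / binders$fold_change),
    rep(1, config$n_background),
    rep(NA_real_, config$n_contaminants)  # contaminants ignore the labels
  )
  true_l2 <- ifelse(is.na(r12),
                    log2(config$contaminant_hl_ratio),
                    if (orientation == "forward") log2(r12) else -log2(r12))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(.string_seed(config$seed, experiment_id))

  k <- c(
    if (n_binders > 0) binders$n_peptides,
    .rpeptides(config$n_background + config$n_contaminants, config$peptides_mean)
  )
  n_events <- sum(k)
  pid <- rep(ids, times = k)
  pep_idx <- sequence(k)
  l2 <- rep(true_l2, times = k) + rnorm(n_events, 0, config$peptide_noise_sd)
  lo <- config$intensity_log10_range[1]
  hi <- config$intensity_log10_range[2]
  evidence <- tibble(
    experiment_id = experiment_id,
    protein_id = pid,
    peptide_sequence = sprintf("%s_pep%03d", pid, pep_idx),
    is_unique = runif(n_events) < config$unique_frac,
    ratio_hl = 2^l2,
    intensity = 10^runif(n_events, lo, hi)
  )
  structure(list(
    rsid = snp$rsid,
    orientation = orientation,
    heavy_allele = heavy,
    light_allele = light,
    experiment_id = experiment_id,
    pulldowns = tibble(
      bait_allele = c(snp$allele1, snp$allele2),
      extract_label = if (orientation == "forward") c("heavy", "light") else c("light", "heavy")
    ),
    evidence = evidence
  ), class = "pulldown_experiment")
}

#' Simulate a forward/reverse pull-down pair for one SNP
#'
#' In the forward experiment the allele-1 bait meets the heavy extract and
#' the allele-2 bait the light extract; in the reverse experiment the labels
#' are switched. A binder preferring allele X with fold change f therefore
#' has expected heavy/light ratio f in the orientation where X is heavy and
#' 1/f in the other, background proteins sit at 1 in both, and contaminants
#' at `contaminant_hl_ratio` in both. Peptide log2 ratios receive
#' Normal(0, `peptide_noise_sd`) noise. Fully reproducible from the seed.
#'
#' @param snp One-row panel tibble (see [read_snp_panel()]).
#' @param binders Tibble of [binder_spec()] rows (may be empty/NULL).
#' @param config A [simulation_config()].
#' @return List with elements `forward` and `reverse` (each a
#'   `pulldown_experiment` with fields `rsid`, `orientation`, `heavy_allele`,
#'   `light_allele`, `experiment_id`, `pulldowns`, `evidence`) and
#'   `ground_truth` (tibble `protein_id`, `class`, `target_allele`,
#'   `fold_change`).
#' @export
simulate_pair <- function(snp, binders = NULL, config) {
  stopifnot(inherits(config, "sim_config"), nrow(snp) == 1)
  if (!is.null(binders) && nrow(binders) > 0) {
    if (anyDuplicated(binders$protein_id)) {
      stop("binder protein_ids must be unique", call. = FALSE)
    }
    stopifnot(all(binders$fold_change > 0), all(binders$n_peptides >= 1))
  }
  list(
    forward = .simulate_one(snp, binders, config, "forward"),
    reverse = .simulate_one(snp, binders, config, "reverse"),
    ground_truth = ground_truth(binders, config)
  )
}

#' Ground-truth protein classes for a simulated pair
#'
#' @param binders Binder tibble as in [simulate_pair()].
#' @param config A [simulation_config()].
#' @return Tibble `protein_id`, `class` (binder/background/contaminant),
#'   `target_allele`, `fold_change`.
#' @export
ground_truth <- function(binders, config) {
  n_binders <- if (is.null(binders)) 0L else nrow(binders)
  bind_rows(
    if (n_binders > 0) tibble(protein_id = binders$protein_id, class = "binder",
                              target_allele = binders$target_allele,
                              fold_change = binders$fold_change),
    tibble(protein_id = sprintf("BG%05d", seq_len(config$n_background)),
           class = "background", target_allele = NA_integer_, fold_change = 1),
    tibble(protein_id = sprintf("CONT%03d", seq_len(config$n_contaminants)),
           class = "contaminant", target_allele = NA_integer_, fold_change = NA_real_)
  )
}

#' Enumerate the physical pull-downs of a screen
#'
#' Each SNP is screened in two label orientations, and each orientation
#' comprises two physical pull-downs (one allele bait per extract), so a
#' panel of n SNPs yields 4n pull-downs (48 for the 12-SNP panel).
#'
#' @param panel Panel tibble from [read_snp_panel()].
#' @return Tibble with one row per pull-down: `rsid`, `orientation`,
#'   `bait_allele`, `extract_label`.
#' @export
pulldown_plan <- function(panel) {
  if (nrow(panel) == 0) {
    return(tibble(rsid = character(), orientation = character(),
                  bait_allele = character(), extract_label = character()))
  }
  bind_rows(lapply(seq_len(nrow(panel)), function(i) {
    snp <- panel[i, ]
    tibble(
      rsid = snp$rsid,
      orientation = rep(c("forward", "reverse"), each = 2),
      bait_allele = rep(c(snp$allele1, snp$allele2), 2),
      extract_label = c("heavy", "light", "light", "heavy")
    )
  }))
}

#' Simulate a whole screen
#'
#' @param panel Panel tibble.
#' @param design Named list mapping rsid to a binder tibble
#'   ([binder_spec()] rows); SNPs absent from `design` get no spiked binder.
#' @param config A [simulation_config()].
#' @return Named list (by rsid) of [simulate_pair()] results.
#' @export
simulate_study <- function(panel, design = list(), config) {
  unknown <- setdiff(names(design), panel$rsid)
  if (length(unknown) > 0) {
    stop(sprintf("design refers to rsid(s) not in the panel: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(panel)), function(i) {
    snp <- panel[i, ]
    simulate_pair(snp, design[[snp$rsid]], config)
  })
  names(out) <- panel$rsid
  out
}

#' Example binder design emulating the type 1 diabetes screen
#'
#' A simulated design for the shipped IL2RA panel: allele-specific binders
#' are spiked at the SNPs where the screen detected differential binding
#' (e.g. a five-fold RUNX1-like binder on rs12722508 allele 1 and an
#' eight-fold LEF1-like binder on rs41295061 allele 1), generic four- to
#' six-fold binders at the remaining detected SNPs, and no binder at the
#' three SNPs without differential binding (rs7909519, rs41295063,
#' rs35285258). Binder protein identifiers carry a `SIM_` prefix to make
#' their synthetic origin explicit.
#'
#' @param panel Panel tibble; SNPs named below are used when present.
#' @return Named list suitable as `design` for [simulate_study()].
#' @export
example_design <- function(panel) {
  design <- list(
    rs12722508 = bind_rows(
      binder_spec("SIM_RUNX1", 1, 5, 10),
      binder_spec("SIM_CBFB", 1, 5, 6),
      binder_spec("SIM_SAFB1", 1, 4, 8)
    ),
    rs41295061 = binder_spec("SIM_LEF1", 1, 8, 10),
    rs12722522 = bind_rows(
      binder_spec("SIM_CREB1", 1, 4, 8),
      binder_spec("SIM_TFAP4", 1, 4, 8)
    ),
    rs11597367 = bind_rows(
      binder_spec("SIM_ZNF148", 2, 4, 8),
      binder_spec("SIM_CGGBP1", 2, 4, 6)
    ),
    rs2104286 = binder_spec("SIM_TF_A", 1, 4, 8),
    rs12722495 = binder_spec("SIM_TF_B", 1, 6, 8),
    rs41295049 = binder_spec("SIM_TF_C", 2, 5, 8),
    rs41295065 = binder_spec("SIM_TF_D", 1, 4, 10),
    rs11594656 = binder_spec("SIM_TF_E", 2, 6, 8)
  )
  design[intersect(names(design), panel$rsid)]
}

#' Write evidence tables and ground truth to TSV
#'
#' @param pair A [simulate_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_evidence <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    file.path(dir, paste0(pair$forward$experiment_id, "_evidence.tsv")),
    file.path(dir, paste0(pair$reverse$experiment_id, "_evidence.tsv")),
    file.path(dir, paste0(pair$forward$rsid, "_ground_truth.tsv"))
  )
  readr::write_tsv(pair$forward$evidence, paths[1], progress = FALSE)
  readr::write_tsv(pair$reverse$evidence, paths[2], progress = FALSE)
  readr::write_tsv(pair$ground_truth, paths[3], progress = FALSE)
  invisible(paths)
}

#' Read an evidence TSV as a pull-down experiment
#'
#' For ingesting externally produced (e.g. MaxQuant-style) peptide evidence.
#' The file must have columns `protein_id`, `peptide_sequence`, `is_unique`,
#' `ratio_hl`, `intensity` (an `experiment_id` column is optional and
#' overridden by the metadata given here).
#'
#' @param path Evidence TSV path.
#' @param rsid SNP identifier of the experiment.
#' @param orientation `"forward"` or `"reverse"`.
#' @param heavy_allele,light_allele Allele bases assigned to the heavy and
#'   light extract in this experiment.
#' @return A `pulldown_experiment`.
#' @export
read_evidence <- function(path, rsid, orientation, heavy_allele, light_allele) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  ev <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("protein_id", "peptide_sequence", "is_unique", "ratio_hl", "intensity")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0) {
    stop(sprintf("evidence file %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(ev$ratio_hl <= 0) || any(ev$intensity <= 0)) {
    stop("ratio_hl and intensity must be positive", call. = FALSE)
  }
  experiment_id <- paste(rsid, orientation, sep = "_")
  ev$experiment_id <- experiment_id
  structure(list(
    rsid = rsid, orientation = orientation,
    heavy_allele = heavy_allele, light_allele = light_allele,
    experiment_id = experiment_id,
    pulldowns = tibble(
      bait_allele = c(heavy_allele, light_allele),
      extract_label = c("heavy", "light")
    ),
    evidence = as_tibble(ev[, c("experiment_id", needed)])
  ), class = "pulldown_experiment")
}
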