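#' Simulate TMT plasma-proteome plates
#'
#' Assigns the proteome-flagged animals to 11-plex runs (10 experimental
#' samples plus a pooled reference labelled with the last tag) split over two
#' measurement groups, then generates log2 protein abundances as
#'
#' `intercept + batch + tag + entry_age_slope * age + run + ref_slope * ref
#'  + breeding value + litter + residual`
#'
#' where the breeding values come from a joint `G^{1/2}`-correlated draw
#' shared with [simulate_phenotypes()] (variance scaled to each protein's
#' target heritability), litter and residual variances follow the config, and
#' the reference channel of each run is the pooled mean of its group's
#' samples plus measurement noise. The raw layer is `2^log2`.
#'
#' @param genotypes,metadata Output of [simulate_population()].
#' @param config The same [sim_config()].
#' @return List with `abundance` (raw-layer [abundance_matrix()], complete --
#'   apply [inject_missingness_by_run()] for run-confounded missingness),
#'   `plate_map` (data.frame: `sample_id`, `animal_id`, `run`, `group`,
#'   `tag`, `batch`), `reference` (runs x proteins matrix of log2
#'   reference-channel values), and `truth` (ground-truth sidecar: breeding
#'   values, per-protein h2 and variance components, fixed effects).
#' @export
simulate_proteome <- function(genotypes, metadata, config) {
  validate_sim_config(config)
  n_runs <- config$n_runs_group1 + config$n_runs_group2
  prot_idx <- which(metadata$has_proteome)
  if (length(prot_idx) > config$samples_per_run * n_runs)
    stop("simulate_proteome: more proteome animals (", length(prot_idx),
         ") than run slots (", config$samples_per_run * n_runs, ")")

  bvd <- simulate_breeding_values(genotypes, config)
  P <- config$n_proteins
  h2p <- bvd$protein_h2

  set.seed(derive_seed(config$seed, 202L))

  # plate layout: proteome animals in batch order fill runs sequentially,
  # so runs are (mostly) nested in batch as in a cycle-wise measurement plan
  ord <- prot_idx[order(metadata$batch[prot_idx], prot_idx)]
  ns <- length(ord)
  run <- ((seq_len(ns) - 1L) %/% config$samples_per_run) + 1L
  group <- ifelse(run <= config$n_runs_group1, 1L, 2L)
  tag <- ((seq_len(ns) - 1L) %% config$samples_per_run) + 1L
  plate_map <- data.frame(sample_id = paste0("S", metadata$animal_id[ord]),
                          animal_id = metadata$animal_id[ord],
                          run = factor(sprintf("R%02d", run)),
                          group = group,
                          tag = factor(sprintf("T%02d", tag)),
                          batch = metadata$batch[ord],
                          stringsAsFactors = FALSE)

  # fixed and random effect draws
  batch_lev <- levels(metadata$batch)
  tag_lev <- sort(unique(plate_map$tag))
  batch_eff <- matrix(stats::rnorm(length(batch_lev) * P, 0,
                                   config$batch_effect_sd),
                      length(batch_lev), P, dimnames = list(batch_lev, NULL))
  tag_eff <- matrix(stats::rnorm(length(tag_lev) * P, 0,
                                 config$tag_effect_sd),
                    length(tag_lev), P, dimnames = list(tag_lev, NULL))
  run_eff <- matrix(stats::rnorm(n_runs * P, 0, sqrt(config$run_var)),
                    n_runs, P)
  litter_lev <- levels(metadata$litter)
  lit_eff <- matrix(stats::rnorm(length(litter_lev) * P),
                    length(litter_lev), P, dimnames = list(litter_lev, NULL))
  lit_eff <- sweep(lit_eff, 2L, sqrt(config$litter_var_proportion), `*`)

  intercept <- stats::rnorm(P, mean = 10, sd = 2)
  e_sd <- sqrt(pmax(1 - h2p - config$litter_var_proportion, 0))

  an <- plate_map$animal_id
  base <- matrix(rep(intercept, each = ns), ns, P)
  base <- base + batch_eff[as.character(plate_map$batch), , drop = FALSE]
  base <- base + tag_eff[as.character(plate_map$tag), , drop = FALSE]
  base <- base + config$entry_age_slope *
    matrix(metadata$entry_age[match(an, metadata$animal_id)], ns, P)
  base <- base + run_eff[run, , drop = FALSE]
  base <- base + bvd$bv[an, seq_len(P), drop = FALSE]
  base <- base + lit_eff[as.character(
    metadata$litter[match(an, metadata$animal_id)]), , drop = FALSE]
  base <- base + matrix(stats::rnorm(ns * P), ns, P) %*% diag(e_sd, P)

  # reference channel: pooled mean of the group's samples + per-run noise
  ref <- matrix(NA_real_, n_runs, P,
                dimnames = list(sprintf("R%02d", seq_len(n_runs)), NULL))
  for (g in 1:2) {
    rows <- which(group == g)
    if (!length(rows)) next
    pool <- colMeans(base[rows, , drop = FALSE])
    for (r in unique(run[rows]))
      ref[r, ] <- pool + stats::rnorm(P, 0, config$ref_noise_sd)
  }
  refc <- scale(ref, center = TRUE, scale = FALSE)  # centred before slope
  log2v <- base + config$ref_slope * refc[run, , drop = FALSE]

  prot_ids <- sprintf("PROT%03d", seq_len(P))
  dimnames(log2v) <- list(plate_map$sample_id, prot_ids)
  colnames(ref) <- prot_ids

  truth <- list(bv = bvd$bv, protein_h2 = h2p,
                litter_var_proportion = config$litter_var_proportion,
                run_var = config$run_var,
                batch_effects = batch_eff, tag_effects = tag_eff,
                intercept = intercept, residual_sd = e_sd,
                grm_true = bvd$grm_true)

  list(abundance = abundance_matrix(2^log2v, "raw"),
       plate_map = plate_map, reference = ref, truth = truth)
}

#' Blank whole runs per protein (run-confounded missingness)
#'
#' In multi-plex TMT data a protein is either quantified for every sample of
#' a run or for none of them. For each (protein, run) pair, with probability
#' `missing_protein_fraction_per_run` all experimental samples of that run
#' are set missing for that protein, independently of abundance level.
#'
#' @param abundance An [abundance_matrix()] (any layer).
#' @param plate_map Plate map with `sample_id` and `run` columns.
#' @param config A [sim_config()] (only the missingness fraction and seed are
#'   used).
#' @return The abundance matrix with `NA` blocks inserted.
#' @export
inject_missingness_by_run <- function(abundance, plate_map, config) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  if (!all(rownames(v) %in% plate_map$sample_id))
    stop("inject_missingness_by_run: abundance rows missing from plate map")
  frac <- config$missing_protein_fraction_per_run
  if (frac == 0) return(abundance)
  set.seed(derive_seed(config$seed, 303L))
  runs <- plate_map$run[match(rownames(v), plate_map$sample_id)]
  for (r in levels(droplevels(runs))) {
    rows <- which(runs == r)
    drop <- stats::runif(ncol(v)) < frac
    v[rows, drop] <- NA_real_
  }
  abundance_matrix(v, abundance$layer)
}
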