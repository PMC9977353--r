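#' Trait specification for the synthetic phenotype generator
#'
#' Describes one performance or resilience trait: its measurement type, the
#' production phase in which it is recorded, its genetic architecture, and the
#' favourability convention used downstream when signing enrichment results.
#'
#' @param name Trait name (e.g. `"FCR"`).
#' @param type One of `"continuous"`, `"binary"` or `"score"`. Binary traits
#'   (e.g. mortality) are thresholded from a latent liability; score traits
#'   are health scores on a 1-5 scale cut from the same liability.
#' @param phase One of `"quarantine_nursery"`, `"challenge_nursery"`,
#'   `"finisher"`, `"carcass"`. Finisher-phase records of animals that die are
#'   masked in the "survivor" dataset variant.
#' @param h2 Narrow-sense heritability of the trait (liability for
#'   binary/score traits), in `[0, 1]`.
#' @param litter_prop Proportion of variance due to common-litter effects.
#' @param prevalence For binary traits, the population frequency of the `1`
#'   class (e.g. death), in `(0, 1)`.
#' @param rg_with_proteins Numeric vector of target genetic correlations of
#'   this trait with each simulated protein (recycled / zero-padded to the
#'   number of proteins). Mostly zero in realistic settings.
#' @param lower_is_better Logical; `TRUE` for traits where smaller values are
#'   favourable (treatments, mortality, feed conversion, residual feed
#'   intake, carcass back fat). Drives the sign-reversal in enrichment
#'   summaries.
#'
#' @return An object of class `"trait_spec"` (a validated list).
#' @export
trait_spec <- function(name, type = c("continuous", "binary", "score"),
                       phase = c("finisher", "quarantine_nursery",
                                 "challenge_nursery", "carcass"),
                       h2 = 0.3, litter_prop = 0.1, prevalence = NULL,
                       rg_with_proteins = numeric(0),
                       lower_is_better = FALSE) {
  type <- match.arg(type)
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(h2) || h2 < 0 || h2 > 1)
    stop("trait_spec '", name, "': h2 must be in [0, 1]")
  if (!is.numeric(litter_prop) || litter_prop < 0)
    stop("trait_spec '", name, "': litter_prop must be >= 0")
  if (h2 + litter_prop > 1)
    stop("trait_spec '", name, "': h2 + litter_prop must be <= 1")
  if (type == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("trait_spec '", name, "': binary trait needs prevalence in (0, 1)")
  }
  if (length(rg_with_proteins) && any(abs(rg_with_proteins) > 1))
    stop("trait_spec '", name, "': |rg_with_proteins| must be <= 1")
  structure(list(name = name, type = type, phase = phase, h2 = h2,
                 litter_prop = litter_prop, prevalence = prevalence,
                 rg_with_proteins = as.numeric(rg_with_proteins),
                 lower_is_better = isTRUE(lower_is_better)),
            class = "trait_spec")
}

#' Default trait panel for the scaled-down fixture
#'
#' Six traits mirroring a disease-challenge panel: average daily gain in the
#' quarantine nursery and finisher, feed conversion ratio, number of
#' antibiotic treatments, overall mortality, and a nursery health score. Two
#' traits carry planted genetic correlations with the first proteins so that
#' recovery tests have known truth: FCR has r_g = -0.6 with protein 1 and
#' FinADG has r_g = +0.5 with protein 2.
#'
#' @return List of [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  list(
    trait_spec("qNurADG", "continuous", "quarantine_nursery", h2 = 0.25,
               litter_prop = 0.15),
    trait_spec("FinADG", "continuous", "finisher", h2 = 0.30,
               litter_prop = 0.10, rg_with_proteins = c(0, 0.5)),
    trait_spec("FCR", "continuous", "finisher", h2 = 0.30,
               litter_prop = 0.10, rg_with_proteins = c(-0.6),
               lower_is_better = TRUE),
    trait_spec("AllTRT", "continuous", "challenge_nursery", h2 = 0.20,
               litter_prop = 0.10, lower_is_better = TRUE),
    trait_spec("AllMOR", "binary", "finisher", h2 = 0.10,
               litter_prop = 0.10, prevalence = 0.15,
               lower_is_better = TRUE),
    trait_spec("cNurHS", "score", "challenge_nursery", h2 = 0.15,
               litter_prop = 0.10)
  )
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator: population and genotype
#' design, TMT plate layout, variance structure of log2 protein abundances,
#' run-level missingness, and the trait panel. Defaults give the scaled-down
#' fixture used throughout the test suite: 300 animals (150 with proteome
#' data) in 7 companies and 6 batches, 1,500 SNPs, 60 proteins measured in 15
#' eleven-plex runs (10 samples + 1 pooled reference each, split 7/8 between
#' two measurement groups), and 6 traits.
#'
#' The full study this emulates had ~3,205 phenotyped animals of which 912
#' had proteome data measured in 41 + 51 runs; those sizes are reachable by
#' overriding `n_animals_total`, `n_proteome`, `n_runs_group1/2` etc.
#'
#' @param n_animals_total Number of phenotyped animals.
#' @param n_proteome Number of animals with proteome data (a flagged subset).
#' @param n_companies Number of breeding companies (genetic subpopulations).
#' @param n_batches Number of contemporary batches (fixed effect in models).
#' @param litter_size_mean Mean litter size (litters nest in company/batch).
#' @param n_snps Number of biallelic SNPs.
#' @param allele_freq_range Range from which per-SNP allele frequencies are
#'   drawn uniformly.
#' @param n_proteins Number of proteins quantified.
#' @param n_runs_group1,n_runs_group2 Number of TMT runs in measurement
#'   groups 1 and 2.
#' @param samples_per_run Experimental samples per run (the pooled reference
#'   channel is extra and carried in the plate map).
#' @param protein_h2_distribution Distribution of per-protein heritabilities:
#'   a list with `name` (`"beta"`, `"uniform"` or `"fixed"`) and its
#'   parameters (`shape1`/`shape2`, `min`/`max`, or `value`).
#' @param litter_var_proportion Proportion of (non-run) variance of log2
#'   abundance due to litter, applied to every protein.
#' @param run_var Variance of the random run (plex) effect on log2 scale.
#' @param tag_effect_sd SD of fixed TMT-tag effects.
#' @param batch_effect_sd SD of fixed batch effects.
#' @param entry_age_slope Slope of log2 abundance on entry age (days).
#' @param ref_slope Regression of each sample's log2 abundance on the
#'   reference-channel value of its run (gives the normalization model signal
#'   to absorb).
#' @param ref_noise_sd Run-to-run measurement noise SD of the reference
#'   channel.
#' @param missing_protein_fraction_per_run Probability that a protein is
#'   missing for an entire run (independently per protein x run).
#' @param trait_specs List of [trait_spec()] objects.
#' @param seed Integer seed; the same config + seed reproduce byte-identical
#'   output.
#'
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_animals_total = 300L,
                       n_proteome = 150L,
                       n_companies = 7L,
                       n_batches = 6L,
                       litter_size_mean = 8,
                       n_snps = 1500L,
                       allele_freq_range = c(0.05, 0.95),
                       n_proteins = 60L,
                       n_runs_group1 = 7L,
                       n_runs_group2 = 8L,
                       samples_per_run = 10L,
                       protein_h2_distribution = list(name = "beta",
                                                      shape1 = 1,
                                                      shape2 = 2.5),
                       litter_var_proportion = 0.05,
                       run_var = 0.2,
                       tag_effect_sd = 0.1,
                       batch_effect_sd = 0.2,
                       entry_age_slope = 0.02,
                       ref_slope = 0.3,
                       ref_noise_sd = 0.1,
                       missing_protein_fraction_per_run = 0.15,
                       trait_specs = default_trait_specs(),
                       seed = 20260911L) {
  cfg <- list(n_animals_total = as.integer(n_animals_total),
              n_proteome = as.integer(n_proteome),
              n_companies = as.integer(n_companies),
              n_batches = as.integer(n_batches),
              litter_size_mean = litter_size_mean,
              n_snps = as.integer(n_snps),
              allele_freq_range = allele_freq_range,
              n_proteins = as.integer(n_proteins),
              n_runs_group1 = as.integer(n_runs_group1),
              n_runs_group2 = as.integer(n_runs_group2),
              samples_per_run = as.integer(samples_per_run),
              protein_h2_distribution = protein_h2_distribution,
              litter_var_proportion = litter_var_proportion,
              run_var = run_var,
              tag_effect_sd = tag_effect_sd,
              batch_effect_sd = batch_effect_sd,
              entry_age_slope = entry_age_slope,
              ref_slope = ref_slope,
              ref_noise_sd = ref_noise_sd,
              missing_protein_fraction_per_run =
                missing_protein_fraction_per_run,
              trait_specs = trait_specs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min)
      stop("sim_config: invalid '", field, "' (need a count >= ", min, ")")
  }
  for (f in c("n_animals_total", "n_proteome", "n_companies", "n_batches",
              "n_snps", "n_proteins", "n_runs_group1", "samples_per_run"))
    chk_count(f)
  chk_count("n_runs_group2", min = 0L)
  if (cfg$n_proteome > cfg$n_animals_total)
    stop("sim_config: invalid 'n_proteome' (must be <= n_animals_total)")
  n_runs <- cfg$n_runs_group1 + cfg$n_runs_group2
  if (cfg$samples_per_run * n_runs < cfg$n_proteome)
    stop("sim_config: invalid 'n_proteome' (more proteome animals than ",
         "run slots: ", cfg$samples_per_run, " x ", n_runs, " < ",
         cfg$n_proteome, ")")
  afr <- cfg$allele_freq_range
  if (length(afr) != 2L || any(afr <= 0) || any(afr >= 1) || afr[1] > afr[2])
    stop("sim_config: invalid 'allele_freq_range' (need 0 < lo <= hi < 1)")
  for (f in c("litter_var_proportion", "run_var", "tag_effect_sd",
              "batch_effect_sd", "ref_noise_sd"))
    if (cfg[[f]] < 0) stop("sim_config: invalid '", f, "' (must be >= 0)")
  m <- cfg$missing_protein_fraction_per_run
  if (m < 0 || m >= 1)
    stop("sim_config: invalid 'missing_protein_fraction_per_run' ",
         "(must be in [0, 1))")
  if (!length(cfg$trait_specs) ||
      !all(vapply(cfg$trait_specs, inherits, logical(1), "trait_spec")))
    stop("sim_config: invalid 'trait_specs' (need a list of trait_spec)")
  nms <- vapply(cfg$trait_specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("sim_config: invalid 'trait_specs' (duplicate trait names)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_animals_total, "animals (",
      x$n_proteome, "with proteome),", x$n_snps, "SNPs,",
      x$n_proteins, "proteins,", x$n_runs_group1 + x$n_runs_group2,
      "runs,", length(x$trait_specs), "traits; seed", x$seed, "\n")
  invisible(x)
}

# draw per-protein heritabilities from the configured distribution
draw_protein_h2 <- function(cfg) {
  d <- cfg$protein_h2_distribution
  n <- cfg$n_proteins
  switch(d$name,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         uniform = stats::runif(n, d$min, d$max),
         fixed = rep(d$value, n),
         stop("sim_config: invalid 'protein_h2_distribution' (unknown name '",
              d$name, "')"))
}
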