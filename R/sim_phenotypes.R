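#' Simulate performance and resilience phenotypes
#'
#' Continuous traits are generated as `pen + litter + breeding value +
#' residual` with the heritability and litter proportion of each
#' [trait_spec()] (phenotypic variance 1). Trait breeding values come from
#' the same joint draw as the protein breeding values, so true protein-trait
#' genetic correlations equal `rg_with_proteins`. Binary traits are
#' thresholded from the latent liability at the quantile matching the
#' configured prevalence; score traits are cut from the liability into a 1-5
#' health-score scale with most animals healthy (the downstream pipeline
#' collapses scores <= 4, see [collapse_health_scores()]). Two dataset
#' variants are produced: "survivor", in which finisher-phase records of
#' animals that died are masked, and "expanded", which retains them (the
#' stand-in for imputed records).
#'
#' @param genotypes,metadata Output of [simulate_population()].
#' @param config The same [sim_config()].
#' @return List with `phenotypes` (survivor variant data.frame, one row per
#'   animal: `animal_id` then one column per trait), `phenotypes_expanded`,
#'   `trait_info` (name, type, phase, lower_is_better), and `truth` (trait
#'   breeding values, liabilities, planted rg matrix).
#' @export
simulate_phenotypes <- function(genotypes, metadata, config) {
  validate_sim_config(config)
  bvd <- simulate_breeding_values(genotypes, config)
  n <- nrow(metadata)
  P <- config$n_proteins
  specs <- config$trait_specs
  tn <- vapply(specs, `[[`, character(1), "name")

  set.seed(derive_seed(config$seed, 404L))

  pen_lev <- levels(metadata$pen)
  lit_lev <- levels(metadata$litter)
  pen_var <- 0.05  # small common-pen share, iid within batch

  liab <- matrix(NA_real_, n, length(specs), dimnames = list(
    metadata$animal_id, tn))
  values <- data.frame(animal_id = metadata$animal_id,
                       stringsAsFactors = FALSE)
  for (t in seq_along(specs)) {
    sp <- specs[[t]]
    e_var <- max(1 - sp$h2 - sp$litter_prop - pen_var, 0.01)
    pen_eff <- stats::rnorm(length(pen_lev), 0, sqrt(pen_var))
    lit_eff <- stats::rnorm(length(lit_lev), 0, sqrt(sp$litter_prop))
    y <- pen_eff[as.integer(metadata$pen)] +
      lit_eff[as.integer(metadata$litter)] +
      bvd$bv[metadata$animal_id, P + t] +
      stats::rnorm(n, 0, sqrt(e_var))
    liab[, t] <- y
    values[[sp$name]] <- switch(
      sp$type,
      continuous = y,
      binary = as.integer(y < stats::qnorm(sp$prevalence,
                                           sd = stats::sd(y))),
      # low liability = poor health; cumulative mass 2/4/8/21% under score 5
      score = {
        cuts <- stats::quantile(y, c(0.02, 0.06, 0.14, 0.35))
        as.integer(findInterval(y, cuts) + 1L)
      })
  }

  # deaths: animals with a binary finisher/overall mortality trait = 1; if
  # no such trait, an independent 10% draw
  mor <- which(vapply(specs, function(s)
    s$type == "binary" && s$phase %in% c("finisher", "challenge_nursery"),
    logical(1)))
  died <- if (length(mor)) values[[tn[mor[1]]]] == 1L else
    stats::runif(n) < 0.10

  phen_exp <- values
  phen_sur <- values
  fin <- which(vapply(specs, function(s) s$phase %in% c("finisher", "carcass"),
                      logical(1)))
  for (t in fin) if (specs[[t]]$type != "binary")
    phen_sur[[tn[t]]][died] <- NA

  trait_info <- data.frame(
    name = tn,
    type = vapply(specs, `[[`, character(1), "type"),
    phase = vapply(specs, `[[`, character(1), "phase"),
    lower_is_better = vapply(specs, `[[`, logical(1), "lower_is_better"),
    h2 = vapply(specs, `[[`, numeric(1), "h2"),
    stringsAsFactors = FALSE)

  rg_true <- matrix(0, P, length(specs),
                    dimnames = list(sprintf("PROT%03d", seq_len(P)), tn))
  for (t in seq_along(specs)) {
    rg <- specs[[t]]$rg_with_proteins
    if (length(rg)) rg_true[seq_len(min(length(rg), P)), t] <-
        rg[seq_len(min(length(rg), P))]
  }

  list(phenotypes = phen_sur, phenotypes_expanded = phen_exp,
       trait_info = trait_info,
       truth = list(bv_traits = bvd$bv[, P + seq_along(specs), drop = FALSE],
                    liability = liab, died = died, rg_true = rg_true,
                    protein_h2 = bvd$protein_h2))
}
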