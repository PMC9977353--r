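#' Generate a full synthetic dataset and write it to disk
#'
#' Runs [simulate_population()], [simulate_proteome()] (with run-confounded
#' missingness) and [simulate_phenotypes()] and writes every table as TSV
#' plus a ground-truth sidecar as JSON. An empty cell in the abundance TSV
#' means missing.
#'
#' Files written: `genotypes.tsv` (dosage matrix, SNP header),
#' `metadata.tsv`, `plate_map.tsv`, `abundance_raw.tsv`, `reference.tsv`,
#' `phenotypes_survivor.tsv`, `phenotypes_expanded.tsv`, `trait_info.tsv`,
#' `truth.json`, `schema.json` (column documentation).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips writing.
#' @return Invisibly, the full simulation bundle (list with `genotypes`,
#'   `metadata`, `abundance`, `plate_map`, `reference`, `phenotypes`,
#'   `phenotypes_expanded`, `trait_info`, `truth`).
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL) {
  pop <- simulate_population(config)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, config)
  abundance <- inject_missingness_by_run(prot$abundance, prot$plate_map,
                                         config)
  phen <- simulate_phenotypes(pop$genotypes, pop$metadata, config)

  truth <- c(prot$truth[c("protein_h2", "litter_var_proportion", "run_var",
                          "intercept", "residual_sd")],
             phen$truth[c("died", "rg_true")],
             list(bv = prot$truth$bv,
                  trait_h2 = phen$trait_info$h2))

  bundle <- list(config = config,
                 genotypes = pop$genotypes, metadata = pop$metadata,
                 abundance = abundance, plate_map = prot$plate_map,
                 reference = prot$reference,
                 phenotypes = phen$phenotypes,
                 phenotypes_expanded = phen$phenotypes_expanded,
                 trait_info = phen$trait_info, truth = truth,
                 truth_full = list(proteome = prot$truth,
                                   phenotypes = phen$truth))
  if (!is.null(out_dir)) write_dataset(bundle, out_dir)
  invisible(bundle)
}

write_dataset <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, file, rn = FALSE) {
    data.table::fwrite(as.data.frame(x), file.path(out_dir, file),
                       sep = "\t", row.names = rn, na = "")
  }
  w(bundle$genotypes, "genotypes.tsv", rn = TRUE)
  w(bundle$metadata, "metadata.tsv")
  w(bundle$plate_map, "plate_map.tsv")
  w(bundle$abundance$values, "abundance_raw.tsv", rn = TRUE)
  w(bundle$reference, "reference.tsv", rn = TRUE)
  w(bundle$phenotypes, "phenotypes_survivor.tsv")
  w(bundle$phenotypes_expanded, "phenotypes_expanded.tsv")
  w(bundle$trait_info, "trait_info.tsv")
  tr <- bundle$truth
  tr$bv <- as.data.frame(tr$bv)
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(dataset_schema(), file.path(out_dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

dataset_schema <- function() {
  list(
    genotypes.tsv = "first column animal_id, then one column per SNP with dosages 0/1/2",
    metadata.tsv = list(animal_id = "animal identifier",
                        company = "breeding company label",
                        batch = "contemporary batch (fixed effect)",
                        litter = "litter id, nested in company x batch",
                        pen = "pen id, nested in batch",
                        entry_age = "age (days) at entry into quarantine nursery",
                        has_proteome = "TRUE if the animal has proteome data"),
    plate_map.tsv = list(sample_id = "proteome sample id",
                         animal_id = "animal identifier",
                         run = "TMT 11-plex run id",
                         group = "measurement group (1 or 2)",
                         tag = "TMT labelling tag within run",
                         batch = "batch of the sampled animal"),
    abundance_raw.tsv = "first column sample_id, then one column per protein; raw (linear) scale; empty cell = missing (whole runs)",
    reference.tsv = "first column run id, then one column per protein; log2 reference-channel value of the run",
    phenotypes_survivor.tsv = "animal_id then one column per trait; finisher records of dead animals are empty",
    phenotypes_expanded.tsv = "animal_id then one column per trait; finisher records of dead animals retained",
    trait_info.tsv = list(name = "trait name", type = "continuous/binary/score",
                          phase = "recording phase",
                          lower_is_better = "TRUE if smaller values are favourable",
                          h2 = "simulated heritability"),
    truth.json = "ground-truth sidecar: breeding values, per-protein h2, variance shares, planted genetic correlations, deaths"
  )
}
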