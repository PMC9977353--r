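#' Synthetic gene-set library over simulated proteins
#'
#' Random sets drawn from the protein universe, for exercising the
#' enrichment stage without external GO/REACTOME libraries. Labelled
#' synthetic; real GMT files can be supplied instead wherever a library is
#' accepted.
#'
#' @param protein_ids Universe of protein ids.
#' @param n_sets Number of sets.
#' @param size_range Set-size range (uniform).
#' @param seed Integer seed.
#' @return A `"gene_set_library"`.
#' @export
synthetic_gene_sets <- function(protein_ids, n_sets = 30L,
                                size_range = c(5L, 15L), seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sort(sample(protein_ids, s)))
  names(sets) <- sprintf("SYNTH_SET_%03d", seq_len(n_sets))
  structure(sets,
            description = stats::setNames(rep("synthetic random set",
                                              n_sets), names(sets)),
            source = "synthetic", class = "gene_set_library")
}

#' Pipeline configuration
#'
#' Collects every stage toggle, threshold and seed of the end-to-end
#' pipeline. Threshold defaults are the study's values: proteins kept when
#' identified in more than `min_runs = 20` runs, heritability significance
#' at FDR < 0.10, the heritability gate `min_h2 = 0.05` for bivariate
#' models, genetic-correlation and association significance at FDR < 0.35,
#' and enrichment-term retention at FDR < 0.2. Note the scaled-down demo
#' fixture has only 15 runs, so [scaled_demo_config()] pairs it with
#' `min_runs = 5`.
#'
#' @param out_dir Output directory.
#' @param sim Simulation config ([sim_config()]), used when `stages`
#'   includes `"generate"`.
#' @param stages Character vector of stages to run, in order, from
#'   `c("generate", "preprocess", "h2", "rg", "assoc", "enrich")`.
#' @param min_runs Protein run-count filter (strictly more than).
#' @param min_h2 Heritability gate for genetic correlations.
#' @param fdr_h2,fdr_assoc,fdr_enrich FDR thresholds (0.10 / 0.35 / 0.2).
#' @param fdr_scope `"across"` or `"per_trait"` pooling for BH.
#' @param variants Dataset variants to scan (`"survivor"`, `"expanded"`).
#' @param rg_max_proteins Cap on proteins entering the bivariate scan
#'   (largest heritability first); keeps the demo within minutes.
#' @param gmt Optional path to a GMT library; `NULL` uses
#'   [synthetic_gene_sets()].
#' @param n_perm GSEA permutations.
#' @param seed Master seed for stage-level randomness (enrichment nulls,
#'   synthetic sets); the simulation uses `sim$seed`.
#' @return Object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(out_dir = tempfile("resilprot_run_"),
                            sim = sim_config(),
                            stages = c("generate", "preprocess", "h2", "rg",
                                       "assoc", "enrich"),
                            min_runs = 20L, min_h2 = 0.05,
                            fdr_h2 = 0.10, fdr_assoc = 0.35,
                            fdr_enrich = 0.2,
                            fdr_scope = "across",
                            variants = c("survivor", "expanded"),
                            rg_max_proteins = 10L,
                            gmt = NULL, n_perm = 1000L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (v in list(min_h2 = min_h2, fdr_h2 = fdr_h2, fdr_assoc = fdr_assoc,
                 fdr_enrich = fdr_enrich))
    if (v < 0 || v > 1) stop("pipeline_config: thresholds must be in [0, 1]")
  if (min_runs < 0) stop("pipeline_config: min_runs must be >= 0")
  structure(list(out_dir = out_dir, sim = sim, stages = stages,
                 min_runs = as.integer(min_runs), min_h2 = min_h2,
                 fdr_h2 = fdr_h2, fdr_assoc = fdr_assoc,
                 fdr_enrich = fdr_enrich, fdr_scope = fdr_scope,
                 variants = variants,
                 rg_max_proteins = rg_max_proteins, gmt = gmt,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Scaled-down demo configuration
#'
#' The default [sim_config()] fixture (300 animals, 15 runs, 60 proteins)
#' paired with thresholds scaled to its size: `min_runs = 5` (the study's
#' ">20 of 92 runs" rule maps to roughly a third of the runs) and 200 GSEA
#' permutations. Everything else keeps the study defaults.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (also reseeds the simulation).
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
scaled_demo_config <- function(out_dir = tempfile("resilprot_demo_"),
                               seed = 1L, ...) {
  pipeline_config(out_dir = out_dir,
                  sim = sim_config(seed = derive_seed(seed, 1L)),
                  min_runs = 5L, n_perm = 200L, rg_max_proteins = 6L,
                  seed = seed, ...)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order -- generate, preprocess (filter,
#' normalization model, outlier removal, missingness report), heritability
#' scan, genetic-correlation scan, phenotypic association scan (per dataset
#' variant), and signed preranked enrichment with ward.D clustering -- and
#' writes every table as TSV under `config$out_dir` plus a JSON manifest
#' with seeds, thresholds, row counts and md5 hashes of all outputs.
#' Re-running with the same config reproduces identical outputs and an
#' identical manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and all in-memory stage
#'   outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package = "resilprot",
                   version = as.character(utils::packageVersion("resilprot")),
                   seed = config$seed, sim_seed = config$sim$seed,
                   thresholds = config[c("min_runs", "min_h2", "fdr_h2",
                                         "fdr_assoc", "fdr_enrich")],
                   stages = stages, rows = list(), files = character(0))
  state <- list()
  emit <- function(x, file, rn = FALSE) {
    path <- file.path(config$out_dir, file)
    data.table::fwrite(as.data.frame(x), path, sep = "\t", row.names = rn,
                       na = "")
    manifest$files[[file]] <<- unname(tools::md5sum(path))
    manifest$rows[[file]] <<- nrow(as.data.frame(x))
    path
  }
  need <- function(what, from_stage) {
    if (is.null(state[[what]]))
      stop("run_pipeline: stage requires '", what, "' but stage '",
           from_stage, "' was not run (enable it in config$stages)")
    state[[what]]
  }

  if ("generate" %in% stages) {
    state$data <- generate_dataset(config$sim,
                                   out_dir = file.path(config$out_dir,
                                                       "data"))
    for (f in list.files(file.path(config$out_dir, "data"),
                         full.names = TRUE))
      manifest$files[[file.path("data", basename(f))]] <-
        unname(tools::md5sum(f))
  }

  if ("preprocess" %in% stages) {
    d <- need("data", "generate")
    filtered <- filter_proteins_by_run_count(log2_transform(d$abundance),
                                             d$plate_map, config$min_runs)
    norm <- fit_normalization_model(filtered, d$metadata, d$plate_map,
                                    d$reference)
    iqr <- iqr_outlier_filter(norm$residuals)
    state$filtered <- filtered
    state$residuals <- iqr$residuals
    # marginal residuals feed the genetic analyses: run BLUPs would absorb
    # genetic signal because litters cluster within runs
    state$residuals_genetic <-
      iqr_outlier_filter(norm$residuals_marginal)$residuals
    state$norm_fit <- norm$fit
    emit(norm$fit, "normalization_fit.tsv")
    emit(iqr$report, "outlier_report.tsv")
    emit(iqr$residuals$values, "residuals.tsv", rn = TRUE)
    emit(missingness_report(filtered, d$plate_map), "missingness_report.tsv")
  }

  if ("h2" %in% stages) {
    d <- need("data", "generate")
    filtered <- need("filtered", "preprocess")
    state$grm <- build_grm(d$genotypes, d$metadata$company, blockwise = TRUE)
    state$h2 <- heritability_scan(filtered, d$metadata, d$plate_map,
                                  d$reference, state$grm)
    emit(state$h2, "heritability.tsv")
  }

  if ("rg" %in% stages) {
    d <- need("data", "generate")
    rg <- genetic_correlation_scan(need("residuals_genetic", "preprocess"),
                                   need("h2", "h2"),
                                   d$phenotypes, d$trait_info, d$metadata,
                                   d$plate_map, need("grm", "h2"),
                                   min_h2 = config$min_h2,
                                   max_proteins = config$rg_max_proteins,
                                   fdr_scope = config$fdr_scope)
    state$rg <- rg
    emit(rg$results, "genetic_correlations.tsv")
    emit(rg$signed_log10p, "rg_signed_log10p.tsv", rn = TRUE)
  }

  if ("assoc" %in% stages) {
    d <- need("data", "generate")
    res <- need("residuals", "preprocess")
    state$assoc <- list()
    for (variant in config$variants) {
      ph <- if (variant == "expanded") d$phenotypes_expanded else
        d$phenotypes
      sc <- association_scan(res, ph, d$trait_info, d$metadata, d$plate_map,
                             variant = variant,
                             fdr_scope = config$fdr_scope)
      state$assoc[[variant]] <- sc
      emit(sc$results, paste0("associations_", variant, ".tsv"))
      emit(sc$signed_log10p, paste0("assoc_signed_log10p_", variant,
                                    ".tsv"), rn = TRUE)
    }
  }

  if ("enrich" %in% stages) {
    d <- need("data", "generate")
    sc <- need("assoc", "assoc")[[config$variants[1]]]
    lib <- if (!is.null(config$gmt)) read_gmt(config$gmt) else
      synthetic_gene_sets(rownames(sc$signed_log10p),
                          seed = derive_seed(config$seed, 7L))
    rankings <- list()
    results <- list()
    for (tr in colnames(sc$signed_log10p)) {
      rows <- sc$results$trait == tr & !is.na(sc$results$scaled_coef)
      scores <- stats::setNames(sc$results$scaled_coef[rows],
                                sc$results$protein[rows])
      if (length(scores) < 2) next
      rankings[[tr]] <- ranked_list(scores, trait = tr,
                                    variant = config$variants[1])
      results[[tr]] <- gsea_preranked(rankings[[tr]], lib,
                                      n_perm = config$n_perm,
                                      seed = derive_seed(config$seed, 11L))
      emit(results[[tr]], paste0("enrichment_", tr, ".tsv"))
    }
    sm <- build_signed_fdr_matrix(results, rankings, d$trait_info,
                                  fdr_threshold = config$fdr_enrich)
    state$enrich <- list(results = results, signed_matrix = sm)
    emit(sm, "enrichment_signed_matrix.tsv", rn = TRUE)
    if (nrow(sm) >= 2) {
      cl <- ward_cluster(sm, k = min(4L, nrow(sm)))
      state$enrich$clusters <- cl
      emit(data.frame(term = names(cl$labels), cluster = cl$labels),
           "enrichment_clusters.tsv")
    }
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(list(manifest = manifest, manifest_path = manifest_path),
              state))
}
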