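#' Heritability scan over proteins
#'
#' For each protein, fits the normalization model's fixed effects (batch,
#' tag, entry age, group-specific reference-channel covariates) with random
#' run, litter and genomic animal effects by AI-REML on the log2
#' abundances, and reports heritability and the litter-variance proportion
#' as fractions of `sigma_a2 + sigma_l2 + sigma_e2` (run variance excluded),
#' with boundary-mixture LRT p-values and Benjamini-Hochberg FDR across
#' proteins (significance rule: FDR < 0.10).
#'
#' @param log2_abundance An [abundance_matrix()], layer `"log2"` (missing
#'   entries allowed).
#' @param metadata,plate_map,reference As in [fit_normalization_model()].
#' @param grm Relationship matrix covering the proteome animals.
#' @param min_n Minimum records per protein (default 50).
#' @param lrt Compute the LRT p-values (two extra fits per protein).
#' @return Data.frame, one row per protein: `protein`, `n`, `sigma_a2`,
#'   `sigma_l2`, `sigma_e2`, `sigma_run2`, `h2`, `litter_prop`, `se_h2`,
#'   `p_h2`, `p_litter`, `q_h2`, `q_litter`, `converged`.
#' @export
heritability_scan <- function(log2_abundance, metadata, plate_map,
                              reference = NULL, grm, min_n = 50L,
                              lrt = TRUE) {
  stopifnot(inherits(log2_abundance, "abundance_matrix"))
  v <- log2_abundance$values
  pm <- plate_map[match(rownames(v), plate_map$sample_id), ]
  md <- metadata[match(pm$animal_id, metadata$animal_id), ]
  run <- factor(pm$run)

  rows <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    prot <- colnames(v)[j]
    obs <- which(!is.na(v[, j]))
    empty <- data.frame(protein = prot, n = length(obs),
                        sigma_a2 = NA_real_, sigma_l2 = NA_real_,
                        sigma_e2 = NA_real_, sigma_run2 = NA_real_,
                        h2 = NA_real_, litter_prop = NA_real_,
                        se_h2 = NA_real_, p_h2 = NA_real_,
                        p_litter = NA_real_, converged = FALSE)
    if (length(obs) < min_n) {
      rows[[j]] <- empty
      next
    }
    df <- droplevels(data.frame(batch = factor(md$batch[obs]),
                                tag = factor(pm$tag[obs]),
                                entry_age = md$entry_age[obs]))
    X <- norm_design(df)
    if (!is.null(reference)) {
      refv <- reference[as.character(run[obs]), prot]
      g <- pm$group[obs]
      extra <- cbind(ref_g1 = ifelse(g == 1, refv, 0),
                     ref_g2 = ifelse(g == 2, refv, 0))
      X <- cbind(X, extra[, apply(extra, 2L, function(z) any(z != 0)),
                          drop = FALSE])
    }
    y <- v[obs, j]
    names(y) <- pm$animal_id[obs]
    fit <- tryCatch(
      reml_univariate(y, grm, X = X, litter = droplevels(md$litter[obs]),
                      run = droplevels(run[obs]), lrt = lrt),
      error = function(e) NULL)
    rows[[j]] <- if (is.null(fit)) empty else
      data.frame(protein = prot, n = fit$n, sigma_a2 = fit$sigma_a2,
                 sigma_l2 = fit$sigma_l2, sigma_e2 = fit$sigma_e2,
                 sigma_run2 = fit$sigma_run2, h2 = fit$h2,
                 litter_prop = fit$litter_prop, se_h2 = fit$se_h2,
                 p_h2 = fit$p_h2, p_litter = fit$p_litter,
                 converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged
  tab$q_h2 <- tab$q_litter <- NA_real_
  tab$q_h2[ok] <- bh_fdr(tab$p_h2[ok])
  tab$q_litter[ok] <- bh_fdr(tab$p_litter[ok])
  rownames(tab) <- NULL
  tab
}

#' Genetic-correlation scan of proteins against traits
#'
#' Bivariate AI-REML for each (protein, trait) pair, restricted to proteins
#' whose heritability estimate exceeds `min_h2` (low-heritability proteins
#' make bivariate fits unstable). Trait 1 is the protein residual
#' (intercept + litter); trait 2 the phenotype with the association-model
#' fixed effects (batch, pen, entry age, carcass extras) and litter, on the
#' full phenotyped population (partial overlap with the proteome subset is
#' handled through the relationship matrix). Binary and collapsed score
#' traits are treated as continuous. The genetic correlation is tested by
#' an ordinary chi-square(1) LRT against the r_g = 0 model and FDR is
#' computed across all traits (rule: FDR < 0.35); proteins are ranked per
#' trait by signed -log10(p), sign = sign(r_g).
#'
#' @param residuals An [abundance_matrix()], layer `"residual"`.
#' @param h2_table Output of [heritability_scan()] (needs `protein`, `h2`).
#' @param phenotypes,trait_info,metadata,plate_map As in
#'   [association_scan()].
#' @param grm Relationship matrix covering all animals.
#' @param min_h2 Heritability gate (default 0.05).
#' @param max_proteins Optional cap on the number of gated proteins
#'   (largest h2 first); `Inf` scans all.
#' @param fdr_scope `"across"` traits (default) or `"per_trait"`.
#' @return List with `results` (long data.frame: protein, trait, r_g, p, q,
#'   h2_protein, converged) and `signed_log10p` (gated proteins x traits).
#' @export
genetic_correlation_scan <- function(residuals, h2_table, phenotypes,
                                     trait_info, metadata, plate_map, grm,
                                     min_h2 = 0.05, max_proteins = Inf,
                                     fdr_scope = c("across", "per_trait")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(residuals, "abundance_matrix"))
  v <- residuals$values
  gated <- h2_table$protein[!is.na(h2_table$h2) & h2_table$h2 > min_h2]
  gated <- gated[order(-h2_table$h2[match(gated, h2_table$protein)])]
  if (is.finite(max_proteins) && length(gated) > max_proteins)
    gated <- gated[seq_len(max_proteins)]
  gated <- intersect(gated, colnames(v))

  pm <- plate_map[match(rownames(v), plate_map$sample_id), ]
  lit1_all <- metadata$litter[match(pm$animal_id, metadata$animal_id)]

  md2 <- metadata
  out <- list()
  k <- 0L
  for (t in seq_len(nrow(trait_info))) {
    tname <- trait_info$name[t]
    y2all <- phenotypes[[tname]]
    if (is.null(y2all)) next
    if (trait_info$type[t] == "score")
      y2all <- collapse_health_scores(y2all)
    ok2 <- !is.na(y2all)
    X2 <- assoc_design(md2, carcass = trait_info$phase[t] == "carcass")
    for (prot in gated) {
      k <- k + 1L
      obs1 <- which(!is.na(v[, prot]))
      y1 <- v[obs1, prot]
      ids1 <- pm$animal_id[obs1]
      fit <- tryCatch(
        reml_bivariate(y1, as.numeric(y2all[ok2]), grm,
                       ids1 = ids1,
                       ids2 = phenotypes$animal_id[ok2],
                       X2 = X2[ok2, drop_aliased(X2[ok2, , drop = FALSE]),
                               drop = FALSE],
                       litter1 = droplevels(factor(lit1_all[obs1])),
                       litter2 = droplevels(factor(md2$litter[ok2]))),
        error = function(e) NULL)
      out[[k]] <- data.frame(
        protein = prot, trait = tname,
        r_g = if (is.null(fit)) NA_real_ else fit$r_g,
        p = if (is.null(fit)) NA_real_ else fit$p_value,
        h2_protein = h2_table$h2[match(prot, h2_table$protein)],
        converged = if (is.null(fit)) FALSE else fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(list(results = data.frame(), signed_log10p = matrix(0, 0, 0)))
  res$q <- bh_fdr(res$p, grouping = if (fdr_scope == "per_trait")
    res$trait else NULL)

  traits <- unique(res$trait)
  mat <- matrix(NA_real_, length(gated), length(traits),
                dimnames = list(gated, traits))
  for (i in seq_len(nrow(res)))
    mat[res$protein[i], res$trait[i]] <-
      sign(res$r_g[i]) * -log10(pmax(res$p[i], 1e-300))
  list(results = res, signed_log10p = mat)
}
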