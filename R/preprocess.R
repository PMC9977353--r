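#' Filter proteins by the number of runs in which they were identified
#'
#' Retains proteins observed (non-missing) in strictly more than `min_runs`
#' runs; proteins seen in exactly `min_runs` runs are dropped.
#'
#' @param abundance An [abundance_matrix()].
#' @param plate_map Plate map with `sample_id` and `run`.
#' @param min_runs Run-count threshold (default 20, the study's rule).
#' @return The filtered [abundance_matrix()]; zero columns if nothing passes.
#' @export
filter_proteins_by_run_count <- function(abundance, plate_map,
                                         min_runs = 20L) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  if (!all(rownames(v) %in% plate_map$sample_id))
    stop("filter_proteins_by_run_count: plate map does not cover all samples")
  runs <- plate_map$run[match(rownames(v), plate_map$sample_id)]
  n_runs_obs <- apply(!is.na(v), 2L, function(obs)
    length(unique(runs[obs])))
  abundance_matrix(v[, n_runs_obs > min_runs, drop = FALSE], abundance$layer)
}

# fixed part of the normalization model; factors with a single observed
# level and constant covariates drop out (absorbed by the intercept)
norm_design <- function(df) {
  terms <- character(0)
  if (nlevels(df$batch) > 1) terms <- c(terms, "batch")
  if (nlevels(df$tag) > 1) terms <- c(terms, "tag")
  if (stats::sd(df$entry_age) > 0) terms <- c(terms, "entry_age")
  X <- if (!length(terms))
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(stats::reformulate(terms), df)
  X
}

#' Fit the per-protein normalization mixed model and extract residuals
#'
#' For each protein, fits (on that protein's non-missing samples) the model
#'
#' `log2 abundance = batch + tag + entry_age + ref(group1) + ref(group2)
#'   + run (random) + e`
#'
#' where the two reference-channel covariates carry the log2 reference value
#' of the sample's run and are set to 0 for runs of the other group. The
#' random run intercept is estimated by REML (profiled likelihood over the
#' variance ratio). Residuals are conditional by default (fixed effects and
#' the predicted run effect subtracted); `marginal = TRUE` subtracts fixed
#' effects only.
#'
#' @param log2_abundance An [abundance_matrix()], layer `"log2"`.
#' @param metadata Sample metadata (needs `animal_id`, `batch`, `entry_age`).
#' @param plate_map Plate map (`sample_id`, `animal_id`, `run`, `group`,
#'   `tag`).
#' @param reference Runs x proteins matrix of log2 reference-channel values
#'   (rownames = run ids). `NULL` drops the reference covariates.
#' @param marginal Logical; put marginal instead of conditional residuals
#'   in the `residuals` element.
#' @param min_runs_fit Minimum number of observed runs to attempt a fit
#'   (default 2).
#' @return List with `fit`: a data.frame (one row per protein: `protein`,
#'   `n`, `sigma2_run`, `sigma2_e`, `entry_age_slope`, `ref_slope_g1`,
#'   `ref_slope_g2`, `converged`) plus attribute `"effects"` holding the full
#'   coefficient tables; `residuals`: an [abundance_matrix()] (layer
#'   `"residual"`, conditional unless `marginal = TRUE`) with missing entries
#'   preserved; and `residuals_marginal`: the marginal residuals (fixed
#'   effects only subtracted), the preferred input for genetic analyses when
#'   litters cluster within runs (a subtracted run BLUP would absorb part of
#'   the genetic signal).
#' @export
fit_normalization_model <- function(log2_abundance, metadata, plate_map,
                                    reference = NULL, marginal = FALSE,
                                    min_runs_fit = 2L) {
  stopifnot(inherits(log2_abundance, "abundance_matrix"))
  if (log2_abundance$layer != "log2")
    stop("fit_normalization_model: expected the log2 layer")
  v <- log2_abundance$values
  m <- match(rownames(v), plate_map$sample_id)
  if (anyNA(m))
    stop("fit_normalization_model: plate map does not cover all samples")
  pm <- plate_map[m, ]
  md <- metadata[match(pm$animal_id, metadata$animal_id), ]

  run <- factor(pm$run)
  base <- data.frame(batch = factor(md$batch), tag = factor(pm$tag),
                     entry_age = md$entry_age, group = pm$group)

  resid_mat <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  resid_marg <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  rows <- vector("list", ncol(v))
  effects <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    prot <- colnames(v)[j]
    obs <- which(!is.na(v[, j]))
    n_runs_obs <- length(unique(run[obs]))
    if (n_runs_obs < min_runs_fit) {
      rows[[j]] <- data.frame(protein = prot, n = length(obs),
                              sigma2_run = NA_real_, sigma2_e = NA_real_,
                              entry_age_slope = NA_real_,
                              ref_slope_g1 = NA_real_,
                              ref_slope_g2 = NA_real_, converged = FALSE)
      next
    }
    df <- droplevels(base[obs, ])
    X <- norm_design(df)
    if (!is.null(reference)) {
      refv <- reference[as.character(run[obs]), prot]
      ref_g1 <- ifelse(df$group == 1, refv, 0)
      ref_g2 <- ifelse(df$group == 2, refv, 0)
      extra <- cbind(ref_g1 = ref_g1, ref_g2 = ref_g2)
      extra <- extra[, apply(extra, 2L, function(z) any(z != 0)),
                     drop = FALSE]
      X <- cbind(X, extra)
    }
    fit <- tryCatch(
      fit_lmm_reml(v[obs, j], X, droplevels(run[obs]), warn_label = prot),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[j]] <- data.frame(protein = prot, n = length(obs),
                              sigma2_run = NA_real_, sigma2_e = NA_real_,
                              entry_age_slope = NA_real_,
                              ref_slope_g1 = NA_real_,
                              ref_slope_g2 = NA_real_, converged = FALSE)
      next
    }
    resid_mat[obs, j] <- if (marginal) fit$resid_marginal else
      fit$resid_conditional
    resid_marg[obs, j] <- fit$resid_marginal
    gb <- function(term) if (term %in% names(fit$beta))
      unname(fit$beta[term]) else NA_real_
    rows[[j]] <- data.frame(protein = prot, n = fit$n,
                            sigma2_run = fit$sigma2_u,
                            sigma2_e = fit$sigma2_e,
                            entry_age_slope = gb("entry_age"),
                            ref_slope_g1 = gb("ref_g1"),
                            ref_slope_g2 = gb("ref_g2"),
                            converged = fit$converged)
    effects[[j]] <- data.frame(protein = prot, term = names(fit$beta),
                               estimate = unname(fit$beta),
                               se = unname(fit$se))
  }
  fit_tab <- do.call(rbind, rows)
  attr(fit_tab, "effects") <- do.call(rbind, effects)
  list(fit = fit_tab,
       residuals = abundance_matrix(resid_mat, "residual"),
       residuals_marginal = abundance_matrix(resid_marg, "residual"))
}

#' Remove residual outliers by the 1.5 x IQR rule
#'
#' Per protein, residuals outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are set
#' missing. Quartiles use linear interpolation (type 7, configurable).
#' Proteins with fewer than 4 observations are skipped with a warning.
#'
#' @param residuals An [abundance_matrix()], layer `"residual"`.
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()].
#' @return List with `residuals` (filtered matrix) and `report` (per
#'   protein: observations, removed count, fraction removed).
#' @export
iqr_outlier_filter <- function(residuals, k = 1.5, type = 7) {
  stopifnot(inherits(residuals, "abundance_matrix"))
  v <- residuals$values
  removed <- integer(ncol(v))
  nobs <- integer(ncol(v))
  skipped <- character(0)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- which(!is.na(x))
    nobs[j] <- length(obs)
    if (length(obs) < 4L) {
      skipped <- c(skipped, colnames(v)[j])
      next
    }
    qs <- stats::quantile(x[obs], c(0.25, 0.75), type = type, names = FALSE)
    iqr <- qs[2] - qs[1]
    out <- obs[x[obs] < qs[1] - k * iqr | x[obs] > qs[2] + k * iqr]
    removed[j] <- length(out)
    v[out, j] <- NA_real_
  }
  if (length(skipped))
    warning("iqr_outlier_filter: skipped protein(s) with < 4 observations: ",
            paste(skipped, collapse = ", "))
  report <- data.frame(protein = colnames(v), n = nobs, removed = removed,
                       fraction_removed = ifelse(nobs > 0, removed / nobs, NA))
  list(residuals = abundance_matrix(v, "residual"), report = report)
}

#' Per-protein missingness summary
#'
#' Reports, per protein, the fraction of runs in which it is missing and its
#' mean observed log2 abundance, together with the across-protein
#' correlation of the two -- the diagnostic used to justify treating
#' run-level missingness as missing at random.
#'
#' @param abundance An [abundance_matrix()] (log2 or raw layer; raw is
#'   log2-transformed for the mean).
#' @param plate_map Plate map with `sample_id` and `run`.
#' @return A data.frame (`protein`, `missing_run_fraction`,
#'   `mean_log2_observed`, `fully_missing`) with attribute
#'   `"cor_missing_abundance"`.
#' @export
missingness_report <- function(abundance, plate_map) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  if (abundance$layer == "raw") v <- log2(v)
  runs <- plate_map$run[match(rownames(v), plate_map$sample_id)]
  all_runs <- unique(runs)
  frac <- apply(is.na(v), 2L, function(miss)
    1 - length(unique(runs[!miss])) / length(all_runs))
  mean_obs <- colMeans(v, na.rm = TRUE)
  mean_obs[!is.finite(mean_obs)] <- NA_real_
  out <- data.frame(protein = colnames(v), missing_run_fraction = frac,
                    mean_log2_observed = mean_obs,
                    fully_missing = frac >= 1)
  ok <- stats::complete.cases(out$missing_run_fraction, out$mean_log2_observed)
  attr(out, "cor_missing_abundance") <-
    if (sum(ok) > 2 && stats::sd(out$missing_run_fraction[ok]) > 0 &&
        stats::sd(out$mean_log2_observed[ok]) > 0)
      stats::cor(out$missing_run_fraction[ok], out$mean_log2_observed[ok])
    else NA_real_
  rownames(out) <- NULL
  out
}
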