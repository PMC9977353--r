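#' Collapse 1-5 health scores
#'
#' Health scores are recorded on a 1 (severe clinical signs) to 5 (perfect
#' health) scale, but low scores are rare and the scale need not be linear,
#' so scores less than or equal to 4 are assigned 4 before analysis.
#'
#' @param scores Integer-ish vector with values in 1..5 (`NA` allowed).
#' @return The collapsed scores (values in \{4, 5\}).
#' @export
collapse_health_scores <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) && (any(obs < 1) || any(obs > 5)))
    stop("collapse_health_scores: scores must be in 1..5")
  ifelse(!is.na(scores) & scores <= 4, 4, scores)
}

#' Convert a reverse-regression coefficient to the forward direction
#'
#' The reverse mixed linear model regresses the protein residual on the
#' binary phenotype; its coefficient is converted by multiplying with the
#' ratio of the residual variances of the binary trait and of protein
#' abundance, which in the fixed-effects-only limit reproduces the ordinary
#' forward (trait-on-protein) slope exactly.
#'
#' @param b_rev Coefficient of the binary trait in the reverse model.
#' @param var_resid_trait Residual variance of the trait (adjusted for the
#'   same systematic effects, protein excluded).
#' @param var_resid_protein Residual variance of the protein residual
#'   (adjusted for the same systematic effects).
#' @return The converted coefficient.
#' @export
convert_reverse_coefficient <- function(b_rev, var_resid_trait,
                                        var_resid_protein) {
  if (!is.finite(var_resid_trait) || var_resid_trait <= 0 ||
      !is.finite(var_resid_protein) || var_resid_protein <= 0)
    stop("convert_reverse_coefficient: residual variances must be positive")
  b_rev * var_resid_trait / var_resid_protein
}

# shared design builder for model (2): fixed batch + entry age + pen
# (+ slaughter-date block for carcass traits), random litter
assoc_design <- function(md, carcass = FALSE) {
  df <- data.frame(batch = factor(md$batch), pen = factor(md$pen),
                   entry_age = md$entry_age)
  form <- ~ batch + pen + entry_age
  if (carcass) {
    if (!is.null(md$slaughter_date)) df$slaughter_date <-
        factor(md$slaughter_date)
    if (!is.null(md$age_slaughter)) df$age_slaughter <- md$age_slaughter
    if (!is.null(md$weight_slaughter)) df$weight_slaughter <-
        md$weight_slaughter
    form <- stats::reformulate(c("batch", "pen", "entry_age",
                                 intersect(c("slaughter_date",
                                             "age_slaughter",
                                             "weight_slaughter"),
                                           names(df))))
  }
  stats::model.matrix(form, df)
}

#' Phenotypic association of one protein with one continuous trait
#'
#' Mixed linear model with fixed batch, pen, entry age (plus slaughter date
#' and age/weight at slaughter for carcass traits), the protein residual as
#' a covariate, and a random litter effect. The protein coefficient is
#' tested by a Wald z test.
#'
#' @param trait Numeric trait records (one per animal; `NA` allowed).
#' @param protein Protein residuals aligned with `trait`.
#' @param metadata Data frame aligned with `trait` (needs `batch`, `pen`,
#'   `entry_age`, `litter`; carcass columns optional).
#' @param carcass Add the carcass-trait fixed effects.
#' @param min_records Minimum joint records (default 30).
#' @return One-row data.frame: `estimate` (trait units per unit log2
#'   residual), `se`, `p`, `std_coef` (= estimate x SD(protein residual)),
#'   `scaled_coef` (= std_coef / SD(trait)), `n`.
#' @export
fit_phenotypic_association <- function(trait, protein, metadata,
                                       carcass = FALSE, min_records = 30L) {
  ok <- !is.na(trait) & !is.na(protein)
  if (sum(ok) < min_records)
    stop("fit_phenotypic_association: fewer than ", min_records,
         " joint records")
  X <- assoc_design(metadata, carcass)
  X <- cbind(X, protein = protein)
  fit <- fit_lmm_reml(trait[ok], X[ok, , drop = FALSE],
                      metadata$litter[ok])
  w <- wald_test(fit, "protein")
  sd_prot <- stats::sd(protein[ok])
  sd_trait <- stats::sd(trait[ok])
  data.frame(estimate = w[["estimate"]], se = w[["se"]], p = w[["p"]],
             std_coef = w[["estimate"]] * sd_prot,
             scaled_coef = w[["estimate"]] * sd_prot / sd_trait,
             n = fit$n)
}

#' Reverse mixed-model association for a binary trait
#'
#' Logistic models for rare binary outcomes often fail to converge, so the
#' protein residual is regressed on the binary phenotype (same fixed and
#' random structure as the forward model) and the coefficient is converted
#' to the forward direction via [convert_reverse_coefficient()], using the
#' REML residual variances of the trait and of the protein from matching
#' auxiliary models without the covariate.
#'
#' @inheritParams fit_phenotypic_association
#' @param trait Binary 0/1 records.
#' @return One-row data.frame as in [fit_phenotypic_association()]; the
#'   `estimate` is the converted (forward-direction) coefficient, and `p` is
#'   the Wald p-value of the reverse coefficient.
#' @export
fit_reverse_association <- function(trait, protein, metadata,
                                    carcass = FALSE, min_records = 30L) {
  ok <- !is.na(trait) & !is.na(protein)
  if (sum(ok) < min_records)
    stop("fit_reverse_association: fewer than ", min_records,
         " joint records")
  if (length(unique(trait[ok])) < 2L)
    stop("fit_reverse_association: single-class binary trait")
  X0 <- assoc_design(metadata, carcass)[ok, , drop = FALSE]
  lit <- metadata$litter[ok]
  rev_fit <- fit_lmm_reml(protein[ok], cbind(X0, trait = trait[ok]), lit)
  b_rev <- wald_test(rev_fit, "trait")
  var_rt <- fit_lmm_reml(trait[ok], X0, lit)$sigma2_e
  var_rp <- fit_lmm_reml(protein[ok], X0, lit)$sigma2_e
  est <- convert_reverse_coefficient(b_rev[["estimate"]], var_rt, var_rp)
  se <- abs(convert_reverse_coefficient(b_rev[["se"]], var_rt, var_rp))
  sd_prot <- stats::sd(protein[ok])
  sd_trait <- stats::sd(trait[ok])
  data.frame(estimate = est, se = se, p = b_rev[["p"]],
             std_coef = est * sd_prot,
             scaled_coef = est * sd_prot / sd_trait,
             n = rev_fit$n)
}

#' Scan all proteins against all traits
#'
#' Runs the forward mixed model for continuous (and collapsed score) traits
#' and the reverse model for binary traits, for every protein x trait pair
#' of a dataset variant, then applies Benjamini-Hochberg FDR over the
#' configured pooling scope and assembles the protein x trait signed
#' -log10(p) matrix (sign = coefficient sign) used by the enrichment module.
#'
#' @param residuals An [abundance_matrix()], layer `"residual"` (samples x
#'   proteins).
#' @param phenotypes Phenotype table (`animal_id` + one column per trait).
#' @param trait_info Data frame with `name`, `type`, `phase`,
#'   `lower_is_better` per trait.
#' @param metadata Animal metadata (`animal_id`, `batch`, `pen`, `litter`,
#'   `entry_age`, optional carcass columns).
#' @param plate_map Plate map linking sample ids to animal ids.
#' @param variant Dataset variant label (`"survivor"` or `"expanded"`).
#' @param fdr_scope `"across"` (all traits pooled, default) or
#'   `"per_trait"`.
#' @return List with `results` (long data.frame: protein, trait, variant,
#'   estimate, se, p, q, std_coef, scaled_coef, direction_favorable, n) and
#'   `signed_log10p` (proteins x traits matrix).
#' @export
association_scan <- function(residuals, phenotypes, trait_info, metadata,
                             plate_map, variant = "survivor",
                             fdr_scope = c("across", "per_trait")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(residuals, "abundance_matrix"))
  v <- residuals$values
  animal <- plate_map$animal_id[match(rownames(v), plate_map$sample_id)]
  md <- metadata[match(animal, metadata$animal_id), ]
  ph <- phenotypes[match(animal, phenotypes$animal_id), ]

  out <- vector("list", nrow(trait_info) * ncol(v))
  k <- 0L
  for (t in seq_len(nrow(trait_info))) {
    tname <- trait_info$name[t]
    ttype <- trait_info$type[t]
    carcass <- trait_info$phase[t] == "carcass"
    y <- ph[[tname]]
    if (is.null(y)) next
    if (ttype == "score") y <- collapse_health_scores(y)
    for (j in seq_len(ncol(v))) {
      k <- k + 1L
      row <- tryCatch({
        if (ttype == "binary")
          fit_reverse_association(y, v[, j], md, carcass = carcass)
        else
          fit_phenotypic_association(y, v[, j], md, carcass = carcass)
      }, error = function(e) NULL)
      if (is.null(row)) {
        row <- data.frame(estimate = NA_real_, se = NA_real_, p = NA_real_,
                          std_coef = NA_real_, scaled_coef = NA_real_,
                          n = NA_integer_)
      }
      out[[k]] <- cbind(data.frame(protein = colnames(v)[j], trait = tname,
                                   variant = variant,
                                   stringsAsFactors = FALSE), row)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res$q <- bh_fdr(res$p, grouping = if (fdr_scope == "per_trait")
    res$trait else NULL)
  lib <- trait_info$lower_is_better[match(res$trait, trait_info$name)]
  res$direction_favorable <- ifelse(is.na(res$estimate), NA,
                                    xor(res$estimate > 0, lib))

  traits <- unique(res$trait)
  mat <- matrix(NA_real_, ncol(v), length(traits),
                dimnames = list(colnames(v), traits))
  for (i in seq_len(nrow(res)))
    mat[res$protein[i], res$trait[i]] <-
      sign(res$estimate[i]) * -log10(pmax(res$p[i], 1e-300))
  list(results = res, signed_log10p = mat)
}
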