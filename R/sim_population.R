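#' Simulate a genotyped population with the study's nesting structure
#'
#' Assigns every animal to a breeding company, contemporary batch, litter
#' and pen, then draws biallelic SNP genotypes with family structure: for
#' each litter a sire and dam are drawn from Hardy-Weinberg equilibrium at
#' per-SNP allele frequencies sampled uniformly from `allele_freq_range`,
#' and litter mates are full sibs obtained by Mendelian sampling (expected
#' genomic relationship 0.5 within litter; column mean dosage stays `2p`).
#' Batches rotate over companies (one batch per company per rotation, as in
#' a continuous-flow challenge barn); litters nest within company x batch;
#' pens nest within batch. A deterministic, evenly spread subset of
#' `n_proteome` animals is flagged as having proteome data.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (animals x SNPs integer matrix of dosages
#'   in 0/1/2, rownames = animal ids) and `metadata` (data.frame with
#'   `animal_id`, `company`, `batch`, `litter`, `pen`, `entry_age`,
#'   `has_proteome`).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_animals_total

  # batches rotate over companies: batch b belongs to company ((b-1) mod C)+1
  batch <- sort(rep_len(seq_len(config$n_batches), n))
  company <- ((batch - 1L) %% config$n_companies) + 1L

  litter <- integer(n)
  pen <- integer(n)
  next_litter <- 1L
  for (b in seq_len(config$n_batches)) {
    idx <- which(batch == b)
    nb <- length(idx)
    # litter sizes ~ 1 + Poisson(mean - 1), truncated to fill the batch
    sizes <- integer(0)
    while (sum(sizes) < nb)
      sizes <- c(sizes, 1L + stats::rpois(1L,
                                          max(config$litter_size_mean - 1, 0)))
    lit <- rep(seq_along(sizes), sizes)[seq_len(nb)]
    litter[idx] <- next_litter + lit - 1L
    next_litter <- next_litter + max(lit)
    # ~15 animals per pen within batch
    pen[idx] <- (b - 1L) * 100L + ((seq_len(nb) - 1L) %/% 15L) + 1L
  }

  p <- stats::runif(config$n_snps, config$allele_freq_range[1],
                    config$allele_freq_range[2])
  nsnp <- config$n_snps
  geno <- matrix(0L, n, nsnp,
                 dimnames = list(sprintf("A%04d", seq_len(n)),
                                 sprintf("SNP%05d", seq_len(nsnp))))
  for (l in unique(litter)) {
    kids <- which(litter == l)
    sire <- stats::rbinom(nsnp, 2L, p)
    dam <- stats::rbinom(nsnp, 2L, p)
    for (i in kids)
      geno[i, ] <- stats::rbinom(nsnp, 1L, sire / 2) +
        stats::rbinom(nsnp, 1L, dam / 2)
  }

  entry_age <- round(stats::rnorm(n, mean = 21, sd = 1.5), 1)
  entry_age <- pmax(entry_age, 16)

  has_proteome <- rep(FALSE, n)
  has_proteome[unique(round(seq(1L, n, length.out = config$n_proteome)))] <-
    TRUE
  # rounding collisions possible only for extreme configs; top up from front
  short <- config$n_proteome - sum(has_proteome)
  if (short > 0)
    has_proteome[which(!has_proteome)[seq_len(short)]] <- TRUE

  metadata <- data.frame(animal_id = rownames(geno),
                         company = factor(paste0("C", company)),
                         batch = factor(paste0("B", batch)),
                         litter = factor(paste0("L", sprintf("%03d", litter))),
                         pen = factor(paste0("P", pen)),
                         entry_age = entry_age,
                         has_proteome = has_proteome,
                         stringsAsFactors = FALSE)
  list(genotypes = geno, metadata = metadata)
}

# Joint draw of additive-genetic values for all proteins and traits.
#
# Breeding values are G^{1/2} z deviates made correlated across columns by
# the Cholesky factor of the target genetic correlation matrix (proteins
# first, traits after), so realized protein-trait genetic correlations match
# the trait_specs' rg_with_proteins exactly in expectation. Deterministic
# given config$seed; called identically by simulate_proteome and
# simulate_phenotypes so either can run alone.
simulate_breeding_values <- function(genotypes, config) {
  n <- nrow(genotypes)
  P <- config$n_proteins
  tn <- vapply(config$trait_specs, `[[`, character(1), "name")
  TT <- length(tn)

  # target genetic correlation matrix (identity + protein-trait entries)
  S <- diag(P + TT)
  for (t in seq_len(TT)) {
    rg <- config$trait_specs[[t]]$rg_with_proteins
    if (length(rg)) {
      rg <- rg[seq_len(min(length(rg), P))]
      S[seq_along(rg), P + t] <- rg
      S[P + t, seq_along(rg)] <- rg
    }
  }
  C <- tryCatch(chol(S), error = function(e) {
    bad <- which(S != 0 & row(S) < col(S) & (row(S) <= P) & (col(S) > P),
                 arr.ind = TRUE)
    pairs <- paste0("(protein ", bad[, 1], ", trait ", tn[bad[, 2] - P], ")",
                    collapse = ", ")
    stop("simulate_breeding_values: target genetic correlation matrix is ",
         "not positive semi-definite; offending nonzero pairs: ", pairs)
  })

  G <- vanraden_grm(genotypes)
  L <- t(chol(G + diag(1e-6, n)))

  set.seed(derive_seed(config$seed, 101L))
  h2p <- draw_protein_h2(config)
  Z <- matrix(stats::rnorm(n * (P + TT)), n, P + TT)
  bv <- (L %*% Z) %*% C               # cov = S_jk * G
  sds <- c(sqrt(h2p), sqrt(vapply(config$trait_specs, `[[`, numeric(1),
                                  "h2")))
  bv <- sweep(bv, 2L, sds, `*`)       # total phenotypic variance 1 per column
  colnames(bv) <- c(sprintf("PROT%03d", seq_len(P)), tn)
  rownames(bv) <- rownames(genotypes)
  list(bv = bv, protein_h2 = h2p, grm_true = G)
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
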