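#' Build a genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = ZZ' / (2 * sum(p_k (1 - p_k)))` where `Z` is the dosage
#' matrix centred by twice the observed allele frequency `p_k`. Frequencies
#' are computed within the animal set used for each block. With
#' `blockwise = TRUE` the matrix is built separately per company and the
#' relationship between animals of different companies is set exactly to 0,
#' focusing the downstream variance components on pooled within-company
#' variation.
#'
#' @param genotypes Animals x SNPs matrix of dosages in \{0, 1, 2\}; missing
#'   values are mean-imputed (per block) with a warning.
#' @param company_labels Optional vector (length = animals) of company
#'   labels; required when `blockwise = TRUE`.
#' @param blockwise Logical; zero cross-company relationships.
#' @return Object of class `"grm"`: the relationship matrix with animal ids
#'   as dimnames and attributes `company` and `blockwise`.
#' @export
build_grm <- function(genotypes, company_labels = NULL, blockwise = FALSE) {
  stopifnot(is.matrix(genotypes))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("A%04d", seq_len(nrow(genotypes)))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("build_grm: dosages must be in {0, 1, 2}")
  if (blockwise && is.null(company_labels))
    stop("build_grm: blockwise = TRUE requires company_labels")

  n <- nrow(genotypes)
  if (!blockwise) {
    G <- vanraden_grm(genotypes)
  } else {
    company_labels <- as.character(company_labels)
    stopifnot(length(company_labels) == n)
    G <- matrix(0, n, n, dimnames = list(rownames(genotypes),
                                         rownames(genotypes)))
    for (cc in unique(company_labels)) {
      idx <- which(company_labels == cc)
      G[idx, idx] <- vanraden_grm(genotypes[idx, , drop = FALSE])
    }
  }
  structure(G, company = company_labels, blockwise = blockwise,
            class = c("grm", "matrix", "array"))
}

# VanRaden method 1 on one block; frequencies from the supplied animals
vanraden_grm <- function(M) {
  if (anyNA(M)) {
    warning("vanraden_grm: missing dosages mean-imputed per SNP")
    for (j in which(colSums(is.na(M)) > 0)) {
      mj <- M[, j]
      mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
      M[, j] <- mj
    }
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("vanraden_grm: all SNPs are monomorphic in this animal set")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2L, 2 * p, `-`)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", nrow(x), "animals",
      if (isTRUE(attr(x, "blockwise"))) "(blockwise by company)" else "",
      "\n  mean diagonal:", round(mean(diag(x)), 3), "\n")
  invisible(x)
}
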