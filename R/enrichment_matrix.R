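#' Signed -log10(FDR) matrix of enrichment across traits
#'
#' Summarizes per-trait preranked GSEA results into a terms x traits matrix
#' of `-log10(FDR)` signed by direction: `+` when increased abundance of the
#' core (leading-edge) proteins is favourable for the trait, `-` when
#' unfavourable. Direction is taken from the mean ranking score of the
#' leading-edge proteins (alternative: the enrichment-score sign), and is
#' flipped for lower-is-better traits (treatments, mortality, feed
#' conversion, residual feed intake, carcass back fat). Terms are retained
#' if their FDR is below `fdr_threshold` for at least one trait; cells with
#' FDR = 0 are clipped to the permutation resolution `1 / n_perm` with a
#' warning.
#'
#' @param results Named list (trait -> [gsea_preranked()] table).
#' @param rankings Named list (trait -> [ranked_list()]), used for the
#'   core-protein direction.
#' @param trait_info Data frame with `name` and `lower_is_better`.
#' @param fdr_threshold Retention threshold (study used 0.2 / 0.35).
#' @param direction `"core"` (mean leading-edge score, default) or
#'   `"aggregate"` (sign of ES).
#' @return Terms x traits numeric matrix (0 where a term was not tested for
#'   a trait).
#' @export
build_signed_fdr_matrix <- function(results, rankings, trait_info,
                                    fdr_threshold = 0.2,
                                    direction = c("core", "aggregate")) {
  direction <- match.arg(direction)
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  traits <- names(results)
  terms <- sort(unique(unlist(lapply(results, `[[`, "set"))))
  mat <- matrix(0, length(terms), length(traits),
                dimnames = list(terms, traits))
  keep <- stats::setNames(rep(FALSE, length(terms)), terms)
  clipped <- FALSE
  for (tr in traits) {
    res <- results[[tr]]
    if (!nrow(res)) next
    n_perm <- attr(res, "n_perm")
    if (is.null(n_perm)) n_perm <- 1000L
    lib <- trait_info$lower_is_better[match(tr, trait_info$name)]
    if (is.na(lib)) lib <- FALSE
    rk <- rankings[[tr]]
    for (i in seq_len(nrow(res))) {
      qv <- res$q[i]
      if (is.na(qv)) next
      if (qv <= 0) {
        qv <- 1 / n_perm
        clipped <- TRUE
      }
      dir_sign <- if (direction == "core" && !is.null(rk)) {
        core <- strsplit(res$leading_edge[i], ",", fixed = TRUE)[[1]]
        s <- mean(rk$score[rk$protein %in% core])
        if (is.na(s) || s == 0) sign(res$es[i]) else sign(s)
      } else sign(res$es[i])
      if (lib) dir_sign <- -dir_sign
      mat[res$set[i], tr] <- dir_sign * -log10(qv)
      if (res$q[i] < fdr_threshold) keep[res$set[i]] <- TRUE
    }
  }
  if (clipped)
    warning("build_signed_fdr_matrix: FDR = 0 clipped to 1/n_perm")
  mat[keep, , drop = FALSE]
}

#' Ward.D hierarchical clustering of enrichment profiles
#'
#' Agglomerative clustering of the rows of a signed -log10(FDR) matrix with
#' the classic Ward update ("ward.D" in [stats::hclust()], i.e. the
#' Lance-Williams Ward coefficients applied directly to the supplied
#' Euclidean distance). Missing entries are set to 0 with a warning.
#'
#' @param matrix Terms x traits numeric matrix (at least 2 rows).
#' @param k Number of clusters for the label cut.
#' @return List with `labels` (named cluster assignment), `order` (leaf
#'   order), `hclust` (the full tree).
#' @export
ward_cluster <- function(matrix, k) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L) stop("ward_cluster: need at least 2 rows")
  if (k > nrow(matrix))
    stop("ward_cluster: k (", k, ") exceeds the number of rows (",
         nrow(matrix), ")")
  if (anyNA(matrix)) {
    warning("ward_cluster: missing entries set to 0")
    matrix[is.na(matrix)] <- 0
  }
  hc <- stats::hclust(stats::dist(matrix), method = "ward.D")
  list(labels = stats::cutree(hc, k = k), order = hc$order, hclust = hc)
}
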