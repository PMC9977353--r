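#' Build a ranked protein list
#'
#' Sorts proteins by a real-valued score, descending, with deterministic
#' tie-breaking by protein id. Scores must be finite.
#'
#' @param scores Named numeric vector (names = protein ids).
#' @param mode Ranking mode label (`"phenotypic_scaled_coefficient"` or
#'   `"genetic_signed_log10p"`).
#' @param trait,variant Bookkeeping labels.
#' @return Object of class `"ranked_list"`: data.frame `protein`, `score`,
#'   sorted, with attributes `mode`, `trait`, `variant`.
#' @export
ranked_list <- function(scores, mode = "phenotypic_scaled_coefficient",
                        trait = NA_character_, variant = NA_character_) {
  scores <- scores[!is.na(scores)]
  if (!length(scores) || is.null(names(scores)))
    stop("ranked_list: need a named, non-empty score vector")
  if (any(!is.finite(scores))) stop("ranked_list: scores must be finite")
  o <- order(-scores, names(scores), method = "radix")
  structure(data.frame(protein = names(scores)[o], score = unname(scores[o]),
                       stringsAsFactors = FALSE),
            mode = mode, trait = trait, variant = variant,
            class = c("ranked_list", "data.frame"))
}

#' Weighted running-sum enrichment score
#'
#' Kolmogorov-Smirnov-like statistic of preranked GSEA: walking down the
#' ranked list, the running sum increases by `|score|^p / sum(|score|^p over
#' hits)` at set members ("hits") and decreases by `1 / (N - N_hits)`
#' otherwise; the enrichment score is the value of maximal absolute
#' deviation from zero. The leading edge is the hits at or before the
#' extremum (at or after it for negative ES). `weight_p = 1` is the tool's
#' "weighted" statistic.
#'
#' @param ranked A [ranked_list()] (or data.frame with `protein`, `score`).
#' @param set Character vector of member ids.
#' @param weight_p Hit-weight exponent (default 1).
#' @return List with `es`, `leading_edge` (member ids), `running` (length-N
#'   running sum).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  hit <- ranked$protein %in% set
  N <- nrow(ranked)
  Nh <- sum(hit)
  if (Nh == 0L) stop("enrichment_score: empty intersection of set and list")
  if (Nh == N)
    warning("enrichment_score: set covers the whole ranked list ",
            "(degenerate, no misses)")
  es_running(ranked$score, hit, weight_p, ranked$protein)
}

# core running-sum computation shared with the permutation null
es_running <- function(scores, hit, weight_p, ids = NULL) {
  N <- length(scores)
  Nh <- sum(hit)
  w <- abs(scores[hit])^weight_p
  sw <- sum(w)
  inc <- numeric(N)
  if (sw > 0) inc[hit] <- w / sw else inc[hit] <- 1 / Nh  # all-zero scores
  if (N > Nh) inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  # extremum of maximal |deviation|; near-ties (within accumulation
  # round-off) resolve to the earliest position so that exact +-tie cases
  # are deterministic across summation orders
  m <- max(abs(running))
  i_max <- which(abs(running) >= m - 1e-12)[1]
  es <- running[i_max]
  le <- NULL
  if (!is.null(ids))
    le <- if (es >= 0) ids[hit & seq_len(N) <= i_max] else
      ids[hit & seq_len(N) >= i_max]
  list(es = es, leading_edge = le, running = running)
}

#' Preranked gene-set enrichment with gene-label permutation FDR
#'
#' For each set with `min_size <= |set intersect list| <= max_size`,
#' computes the weighted enrichment score, a permutation null obtained by
#' drawing random member positions from the ranked scores (`n_perm` draws),
#' the normalized enrichment score NES = ES / mean(|null ES| of the same
#' sign), a same-sign nominal p-value, and the NES-ratio FDR of the original
#' tool: q = (fraction of all pooled null NES at least as extreme, same
#' sign) / (fraction of observed NES at least as extreme, same sign),
#' clipped to [0, 1] and monotone-adjusted along NES order. Deterministic
#' for a fixed seed.
#'
#' @param ranked A [ranked_list()].
#' @param library A `"gene_set_library"` (named list of id vectors).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size,max_size Set-size filter on the intersection with the
#'   list (defaults 1 and 500).
#' @param weight_p Hit-weight exponent (default 1).
#' @param seed Integer seed.
#' @return Data.frame (one row per retained set): `set`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-separated ids), plus attribute
#'   `"n_perm"`.
#' @export
gsea_preranked <- function(ranked, library, n_perm = 1000L, min_size = 1L,
                           max_size = 500L, weight_p = 1, seed = 1L) {
  stopifnot(inherits(ranked, "data.frame"))
  N <- nrow(ranked)
  sizes <- vapply(library, function(s) sum(ranked$protein %in% s), 1L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    warning("gsea_preranked: all sets filtered out")
    return(structure(data.frame(set = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p = numeric(0), q = numeric(0),
                                leading_edge = character(0)),
                     n_perm = n_perm))
  }
  library <- library[keep]
  sizes <- sizes[keep]
  ns <- length(library)
  scores <- ranked$score

  obs <- lapply(library, function(s) enrichment_score(ranked, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(as.integer(seed))
  # one null matrix per distinct set size; rows = permutations
  null_by_size <- list()
  for (sz in sort(unique(sizes))) {
    nul <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      hit <- logical(N)
      hit[sample.int(N, sz)] <- TRUE
      nul[b] <- es_running(scores, hit, weight_p)$es
    }
    null_by_size[[as.character(sz)]] <- nul
  }

  nes <- numeric(ns)
  pval <- numeric(ns)
  null_nes_all <- vector("list", ns)
  for (i in seq_len(ns)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos <- nul[nul >= 0]
    neg <- nul[nul < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes[i] <- if (es[i] >= 0) es[i] / mpos else es[i] / mneg
    pval[i] <- if (es[i] >= 0)
      (sum(pos >= es[i]) + 1) / (length(pos) + 1)
    else (sum(neg <= es[i]) + 1) / (length(neg) + 1)
    nn <- nul
    nn[nul >= 0] <- nul[nul >= 0] / mpos
    nn[nul < 0] <- nul[nul < 0] / mneg
    null_nes_all[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(null_nes_all)

  q <- rep(NA_real_, ns)
  for (sgn in c(1, -1)) {
    side <- if (sgn > 0) which(nes >= 0) else which(nes < 0)
    if (!length(side)) next
    pool_side <- if (sgn > 0) pool[pool >= 0] else pool[pool < 0]
    for (i in side) {
      num <- if (sgn > 0) mean(pool_side >= nes[i]) else
        mean(pool_side <= nes[i])
      den <- if (sgn > 0) mean(nes[side] >= nes[i]) else
        mean(nes[side] <= nes[i])
      q[i] <- min(max(num / den, 0), 1)
    }
    # monotone adjustment (step-up): a more extreme NES cannot have a
    # larger q than any less extreme set on the same side
    o <- side[order(abs(nes[side]), decreasing = TRUE)]
    q[o] <- rev(cummin(rev(q[o])))
  }

  structure(data.frame(set = names(library), size = sizes, es = es,
                       nes = nes, p = pval, q = q,
                       leading_edge = vapply(obs, function(o)
                         paste(o$leading_edge, collapse = ","),
                         character(1)),
                       row.names = NULL, stringsAsFactors = FALSE),
            n_perm = n_perm)
}
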