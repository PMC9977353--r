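# Shared fixtures, built once per session. Everything is generated in code;
# the default scaled-down config takes well under a second.

fx_env <- new.env(parent = emptyenv())

# default fixture: 300 animals, 150 with proteome, 60 proteins, 15 runs
demo_fixture <- function() {
  if (is.null(fx_env$demo))
    fx_env$demo <- generate_dataset(sim_config(seed = 20260911L))
  fx_env$demo
}

# demo fixture taken through preprocessing (filter at >5 of 15 runs)
preprocessed_fixture <- function() {
  if (is.null(fx_env$pre)) {
    d <- demo_fixture()
    filt <- filter_proteins_by_run_count(log2_transform(d$abundance),
                                         d$plate_map, 5L)
    nm <- fit_normalization_model(filt, d$metadata, d$plate_map, d$reference)
    iqr <- iqr_outlier_filter(nm$residuals)
    fx_env$pre <- list(data = d, filtered = filt, norm = nm,
                       residuals = iqr$residuals, iqr_report = iqr$report)
  }
  fx_env$pre
}

# small HWE genotype matrix + GRM for quantgen tests
hwe_grm_fixture <- function(n = 200L, nsnp = 600L, seed = 11L) {
  key <- sprintf("grm_%d_%d_%d", n, nsnp, seed)
  if (is.null(fx_env[[key]])) {
    set.seed(seed)
    p <- runif(nsnp, 0.1, 0.9)
    M <- vapply(p, function(pk) rbinom(n, 2L, pk), integer(n))
    rownames(M) <- sprintf("A%04d", seq_len(n))
    fx_env[[key]] <- list(M = M, G = build_grm(M))
  }
  fx_env[[key]]
}

# brute-force running-sum ES, the independent oracle for the GSEA
# statistic; keeps the earliest extremum under the same near-tie rule as
# the implementation (|improvements| below round-off do not move it)
brute_force_es <- function(scores, hit, p = 1) {
  N <- length(scores)
  Nh <- sum(hit)
  sw <- sum(abs(scores[hit])^p)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(scores[i])^p / sw else -1 / (N - Nh)
    if (abs(run) > abs(best) + 1e-12) best <- run
  }
  best
}

# brute-force BH step-up q-values, the oracle for bh_fdr
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}
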