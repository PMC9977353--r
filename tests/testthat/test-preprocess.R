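# preprocessing: run-count filter, normalization mixed model, IQR outlier
# removal, missingness diagnostics

make_plate <- function(n_runs, per_run) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_runs * per_run)),
             animal_id = sprintf("A%03d", seq_len(n_runs * per_run)),
             run = factor(rep(sprintf("R%02d", seq_len(n_runs)),
                              each = per_run)),
             group = rep(1L, n_runs * per_run),
             tag = factor(rep(sprintf("T%02d", seq_len(per_run)), n_runs)),
             stringsAsFactors = FALSE)
}

test_that("run-count filter uses a strict > boundary and matches a recount", {
  pm <- make_plate(6, 3)
  v <- matrix(1, 18, 4, dimnames = list(pm$sample_id, paste0("P", 1:4)))
  v[pm$run != "R01", 2] <- NA          # P2: exactly 1 run
  v[!(pm$run %in% c("R01", "R02")), 3] <- NA  # P3: exactly 2 runs
  v[7:18, 4] <- NA                     # P4: 2 runs
  ab <- abundance_matrix(v, "log2")
  expect_equal(colnames(filter_proteins_by_run_count(ab, pm, 0)$values),
               paste0("P", 1:4))       # all observed in > 0 runs
  f1 <- filter_proteins_by_run_count(ab, pm, 1)
  expect_equal(colnames(f1$values), c("P1", "P3", "P4"))  # P2 dropped at ==
  f2 <- filter_proteins_by_run_count(ab, pm, 2)
  expect_equal(colnames(f2$values), "P1")
  # brute-force recount oracle on a random missingness pattern
  set.seed(1)
  v2 <- matrix(rnorm(18 * 30), 18, 30,
               dimnames = list(pm$sample_id, sprintf("Q%02d", 1:30)))
  for (j in 1:30) {
    gone <- sample(levels(pm$run), sample(0:5, 1))
    v2[pm$run %in% gone, j] <- NA
  }
  ab2 <- abundance_matrix(v2, "log2")
  runs_obs <- vapply(seq_len(30), function(j)
    length(unique(pm$run[!is.na(v2[, j])])), integer(1))
  for (thr in c(2L, 4L))
    expect_equal(colnames(filter_proteins_by_run_count(ab2, pm, thr)$values),
                 colnames(v2)[runs_obs > thr])
})

test_that("normalization with zero effects reduces to centering", {
  # single batch/tag and constant age alias to the intercept; data are
  # pre-centred within run, so the run variance sits exactly on the
  # boundary and conditional residuals equal plain centring
  pm <- make_plate(4, 5)
  pm$tag <- factor(rep("T01", 20))
  set.seed(2)
  v <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(pm$sample_id, paste0("P", 1:3)))
  for (r in levels(pm$run))
    v[pm$run == r, ] <- scale(v[pm$run == r, , drop = FALSE],
                              scale = FALSE)
  v <- v + 8
  md <- data.frame(animal_id = pm$animal_id, batch = factor("B1"),
                   entry_age = rep(21, 20), litter = factor("L1"),
                   pen = factor("P1"))
  fit <- fit_normalization_model(abundance_matrix(v, "log2"), md, pm,
                                 reference = NULL)
  r <- fit$residuals$values
  expect_lt(max(abs(colMeans(r))), 1e-8)
  expect_lt(max(abs(r - scale(v, scale = FALSE))), 1e-6)
  expect_true(all(fit$fit$sigma2_run <= 1e-10))
})

test_that("normalization recovers simulated batch and tag effects", {
  pre <- preprocessed_fixture()
  d <- pre$data
  eff <- attr(pre$norm$fit, "effects")
  tru_b <- d$truth_full$proteome$batch_effects
  tru_t <- d$truth_full$proteome$tag_effects
  n_checked <- 0L
  bad <- 0L
  for (prot in unique(eff$protein)[1:20]) {
    ej <- eff[eff$protein == prot, ]
    j <- as.integer(sub("PROT", "", prot))
    for (lev in c("batchB2", "batchB3")) {
      row <- ej[ej$term == lev, ]
      if (!nrow(row)) next
      truth <- tru_b[sub("batch", "", lev), j] - tru_b["B1", j]
      n_checked <- n_checked + 1L
      if (abs(row$estimate - truth) > 3 * row$se) bad <- bad + 1L
    }
    row <- ej[ej$term == "tagT02", ]
    if (nrow(row)) {
      truth <- tru_t["T02", j] - tru_t["T01", j]
      n_checked <- n_checked + 1L
      if (abs(row$estimate - truth) > 3 * row$se) bad <- bad + 1L
    }
  }
  expect_gt(n_checked, 30L)
  # ~0.3% expected outside 3 SE; allow a small margin
  expect_lte(bad / n_checked, 0.05)
})

test_that("run variance estimate hits the boundary when simulated zero", {
  # no run effect and no other run-clustered variance (litters share runs,
  # so litter and genetic variance must be off for a clean boundary case)
  cfg <- sim_config(run_var = 0, litter_var_proportion = 0,
                    protein_h2_distribution = list(name = "fixed",
                                                   value = 0),
                    missing_protein_fraction_per_run = 0,
                    n_proteins = 20L, seed = 19L)
  d <- generate_dataset(cfg)
  nm <- fit_normalization_model(log2_transform(d$abundance), d$metadata,
                                d$plate_map, d$reference)
  ratio <- nm$fit$sigma2_run / nm$fit$sigma2_e
  # REML boundary mixture: about half the estimates sit exactly at zero
  expect_gte(mean(ratio <= 1e-6), 0.35)
  expect_lte(median(ratio), 0.02)
})

test_that("IQR filter: hand cases, normal tail rate, monotone shrink", {
  mk <- function(x) abundance_matrix(matrix(x, ncol = 1,
                                            dimnames = list(
                                              sprintf("S%03d",
                                                      seq_along(x)), "P1")),
                                     "residual")
  r1 <- iqr_outlier_filter(mk(c(-1, -0.5, 0, 0.5, 1)))
  expect_equal(r1$report$removed, 0L)
  r2 <- iqr_outlier_filter(mk(c(0, 0, 0, 0, 100)))
  expect_equal(r2$report$removed, 1L)
  expect_true(is.na(r2$residuals$values[5, 1]))
  expect_warning(iqr_outlier_filter(mk(c(1, 2, 3))), "< 4 observations")
  # standard-normal removal fraction: beyond quartile +- 1.5 IQR fences,
  # analytically 2 * pnorm(-2.698) ~ 0.70%
  set.seed(4)
  r3 <- iqr_outlier_filter(mk(rnorm(10000)))
  expect_lt(abs(r3$report$fraction_removed - 0.007), 0.003)
  # second application removes no more than the first (monotone shrink)
  r4 <- iqr_outlier_filter(r3$residuals)
  expect_lte(r4$report$removed, r3$report$removed)
  # quartile convention: type-7 linear interpolation, hand-computed
  x <- c(1, 2, 3, 4, 10)
  expect_equal(unname(quantile(x, 0.25, type = 7)), 2)
  fences <- c(2 - 1.5 * 2, 4 + 1.5 * 2)  # Q1=2, Q3=4
  r5 <- iqr_outlier_filter(mk(x))
  expect_equal(r5$report$removed, sum(x < fences[1] | x > fences[2]))
})

test_that("missingness report covers degenerate cases", {
  pm <- make_plate(4, 3)
  v <- matrix(rnorm(12 * 3, 8), 12, 3,
              dimnames = list(pm$sample_id, paste0("P", 1:3)))
  ab <- abundance_matrix(v, "log2")
  rep0 <- missingness_report(ab, pm)
  expect_equal(rep0$missing_run_fraction, rep(0, 3))
  v[, 2] <- NA
  rep1 <- missingness_report(abundance_matrix(v, "log2"), pm)
  expect_equal(rep1$missing_run_fraction[2], 1)
  expect_true(rep1$fully_missing[2])
  expect_true(is.na(rep1$mean_log2_observed[2]))
})

test_that("normalization model agrees with lme4 on one protein", {
  skip_if_not_installed("lme4")
  pre <- preprocessed_fixture()
  d <- pre$data
  v <- pre$filtered$values
  j <- which.max(colSums(!is.na(v)))
  obs <- which(!is.na(v[, j]))
  pm <- d$plate_map[match(rownames(v), d$plate_map$sample_id), ]
  md <- d$metadata[match(pm$animal_id, d$metadata$animal_id), ]
  df <- droplevels(data.frame(
    y = v[obs, j], batch = factor(md$batch[obs]), tag = factor(pm$tag[obs]),
    age = md$entry_age[obs], run = factor(pm$run[obs]),
    ref = d$reference[as.character(pm$run[obs]), colnames(v)[j]],
    grp = pm$group[obs]))
  df$ref_g1 <- ifelse(df$grp == 1, df$ref, 0)
  df$ref_g2 <- ifelse(df$grp == 2, df$ref, 0)
  lf <- lme4::lmer(y ~ batch + tag + age + ref_g1 + ref_g2 + (1 | run),
                   df, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))
  X <- model.matrix(~ batch + tag + age + ref_g1 + ref_g2, df)
  mine <- resilprot:::fit_lmm_reml(df$y, X, df$run)
  expect_equal(mine$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  expect_equal(unname(mine$beta["age"]), unname(lme4::fixef(lf)["age"]),
               tolerance = 1e-4)
  expect_equal(mine$sigma2_u,
               as.numeric(lme4::VarCorr(lf)$run[1]), tolerance = 1e-3)
})
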