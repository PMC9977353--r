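# GRM construction, AI-REML variance components, boundary LRT, BH FDR

test_that("GRM matches the hand-evaluated VanRaden formula", {
  # one SNP, p = 0.5, dosages (0, 2): Z = (-1, 1), denom = 0.5
  M <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- build_grm(M)
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  # 3 animals, 2 SNPs, hand computation
  M2 <- matrix(c(0L, 1L, 2L,
                 1L, 1L, 0L), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  p <- colMeans(M2) / 2                       # (0.5, 1/3)
  Z <- sweep(M2, 2, 2 * p)
  Ghand <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  expect_equal(unclass(build_grm(M2)), Ghand, ignore_attr = TRUE)
})

test_that("GRM structural properties and error contracts", {
  fx <- hwe_grm_fixture()
  G <- fx$G
  expect_equal(unclass(G), t(unclass(G)), ignore_attr = TRUE)
  expect_lt(abs(mean(diag(G)) - 1), 0.2)
  # two identical individuals: off-diagonal equals both diagonals
  M <- rbind(fx$M[1, ], fx$M[1, ], fx$M[2, ])
  rownames(M) <- c("x", "y", "z")
  Gd <- build_grm(M)
  expect_equal(Gd["x", "y"], Gd["x", "x"])
  expect_equal(Gd["x", "y"], Gd["y", "y"])
  # blockwise: all cross-company entries exactly 0
  comp <- rep(c("c1", "c2"), each = 100)
  Gb <- build_grm(fx$M, comp, blockwise = TRUE)
  expect_true(all(Gb[1:100, 101:200] == 0))
  expect_false(all(Gb[1:100, 1:100] == 0))
  expect_error(build_grm(matrix(2L, 4, 3)), "monomorphic")
  Mna <- fx$M[1:50, 1:50]
  Mna[1, 1] <- NA
  expect_warning(build_grm(Mna), "imputed")
  expect_error(build_grm(matrix(c(0, 3), 2, 2)), "\\{0, 1, 2\\}")
})

test_that("univariate REML recovers variance components and invariances", {
  fx <- hwe_grm_fixture(n = 120L, nsnp = 500L, seed = 21L)
  G <- fx$G
  n <- 120
  set.seed(22)
  L <- t(chol(unclass(G) + diag(1e-6, n)))
  lit <- factor(rep(seq_len(30), each = 4))
  a <- sqrt(0.4) * drop(L %*% rnorm(n))
  le <- rnorm(30, 0, sqrt(0.2))
  y <- setNames(a + le[as.integer(lit)] + rnorm(n, 0, sqrt(0.4)),
                rownames(G))
  fit <- reml_univariate(y, G, litter = lit, lrt = FALSE)
  expect_true(fit$converged)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  expect_equal(fit$h2,
               fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_l2 + fit$sigma_e2))

  # optimality: the returned optimum beats 20 random admissible points
  ll_at <- function(th) {
    K <- list(unclass(G), resilprot:::grouping_structure(lit), diag(n))
    V <- th[1] * K[[1]] + th[2] * K[[2]] + th[3] * K[[3]]
    X <- matrix(1, n, 1)
    cV <- chol(V)
    Viy <- backsolve(cV, forwardsolve(t(cV), y))
    ViX <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, ViX)
    b <- solve(XtViX, crossprod(X, Viy))
    yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * b)
    -0.5 * (2 * sum(log(diag(cV))) + log(XtViX[1, 1]) + yPy +
              (n - 1) * log(2 * pi))
  }
  set.seed(23)
  rand_ll <- replicate(20, ll_at(runif(3, 0.05, 1.2)))
  expect_true(all(fit$loglik >= rand_ll - 1e-6))

  # brute-force 2-D grid over variance ratios (sigma_e profiled by search)
  grid <- expand.grid(h2 = seq(0.02, 0.9, by = 0.04),
                      lp = seq(0.02, 0.5, by = 0.04))
  grid <- grid[grid$h2 + grid$lp < 0.95, ]
  vp <- var(y)
  grid_ll <- apply(grid, 1, function(g)
    ll_at(vp * c(g[1], g[2], 1 - g[1] - g[2])))
  expect_gte(fit$loglik, max(grid_ll) - 1e-4)
  best <- grid[which.max(grid_ll), ]
  expect_lt(abs(fit$h2 - best$h2), 0.1)

  # invariance to record order and to adding a constant
  o <- sample(n)
  fit_o <- reml_univariate(y[o], G, litter = lit[o], lrt = FALSE)
  expect_equal(fit_o$h2, fit$h2, tolerance = 1e-4)
  fit_c <- reml_univariate(y + 100, G, litter = lit, lrt = FALSE)
  expect_equal(fit_c$h2, fit$h2, tolerance = 1e-4)
})

test_that("boundary behaviour under a null animal effect", {
  # under h2 = 0 the REML estimate is a ~50:50 mixture of a point mass at
  # the boundary and a positive half-normal, so roughly half the estimates
  # should be (near) zero
  fx <- hwe_grm_fixture(n = 150L, nsnp = 400L, seed = 31L)
  set.seed(32)
  h2s <- replicate(20, {
    y <- setNames(rnorm(150), rownames(fx$G))
    reml_univariate(y, fx$G, litter = NULL, lrt = FALSE)$h2
  })
  expect_gte(mean(h2s < 0.02), 0.35)
  expect_lt(mean(h2s), 0.15)
})

test_that("lrt_boundary: mixture arithmetic and error contract", {
  expect_equal(lrt_boundary(10, 10), 0.5)
  expect_equal(lrt_boundary(11.9205, 10), 0.025, tolerance = 1e-3)
  # chi2_1 0.95 quantile = 3.841: halved tail = 0.025
  expect_equal(lrt_boundary(10 + 3.841 / 2, 10),
               0.5 * pchisq(3.841, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(lrt_boundary(10 + 3.841 / 2, 10, mixture = FALSE),
               pchisq(3.841, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_error(lrt_boundary(9, 10), "optimizer")
})

test_that("BH q-values match the hand/brute-force oracle", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_force_bh(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))  # cross-check base R
  }
  # grouped pooling equals per-group application
  p <- runif(20)
  g <- rep(c("a", "b"), 10)
  q <- bh_fdr(p, g)
  expect_equal(q[g == "a"], brute_force_bh(p[g == "a"]))
  # NA handling and null calibration
  expect_warning(qna <- bh_fdr(c(0.5, NA)), "NA")
  expect_true(is.na(qna[2]))
  set.seed(42)
  expect_lte(mean(bh_fdr(runif(1000)) < 0.1), 0.01)
})

test_that("bivariate REML: null symmetry, bounds, loglik additivity", {
  fx <- hwe_grm_fixture(n = 160L, nsnp = 500L, seed = 51L)
  G <- fx$G
  n <- 160
  set.seed(52)
  L <- t(chol(unclass(G) + diag(1e-6, n)))
  y1 <- setNames(sqrt(0.4) * drop(L %*% rnorm(n)) + rnorm(n, 0, sqrt(0.6)),
                 rownames(G))
  y2 <- setNames(sqrt(0.3) * drop(L %*% rnorm(n)) + rnorm(n, 0, sqrt(0.7)),
                 rownames(G))
  fb <- reml_bivariate(y1, y2, G)
  expect_true(abs(fb$r_g) <= 1)
  expect_true(fb$p_value > 0 && fb$p_value <= 1)
  # with the genetic covariance fixed at 0 and no shared structure, the
  # bivariate restricted likelihood is the sum of the univariate ones
  f1 <- reml_univariate(y1, G, litter = NULL, lrt = FALSE)
  f2 <- reml_univariate(y2, G, litter = NULL, lrt = FALSE)
  expect_equal(fb$loglik_rg0, f1$loglik + f2$loglik, tolerance = 1e-4)
})

test_that("bivariate REML recovers a planted genetic correlation", {
  fx <- hwe_grm_fixture(n = 300L, nsnp = 700L, seed = 61L)
  G <- fx$G
  n <- 300
  set.seed(62)
  L <- t(chol(unclass(G) + diag(1e-6, n)))
  rgs <- replicate(4, {
    Z <- matrix(rnorm(n * 2), n, 2) %*%
      chol(matrix(c(1, -0.6, -0.6, 1), 2))
    A <- L %*% Z
    y1 <- setNames(sqrt(0.45) * A[, 1] + rnorm(n, 0, sqrt(0.55)),
                   rownames(G))
    y2 <- setNames(sqrt(0.35) * A[, 2] + rnorm(n, 0, sqrt(0.65)),
                   rownames(G))
    reml_bivariate(y1[seq_len(150)], y2, G, lrt = FALSE)$r_g
  })
  expect_lt(abs(mean(rgs) - (-0.6)), 0.25)
  expect_true(all(abs(rgs) <= 1))
})

test_that("heritability scan returns a well-formed table", {
  pre <- preprocessed_fixture()
  d <- pre$data
  G <- build_grm(d$genotypes, d$metadata$company, blockwise = TRUE)
  sub <- abundance_matrix(pre$filtered$values[, 1:6], "log2")
  tab <- heritability_scan(sub, d$metadata, d$plate_map, d$reference, G)
  expect_equal(nrow(tab), 6L)
  ok <- tab$converged
  expect_gte(sum(ok), 4L)
  expect_true(all(tab$h2[ok] >= 0 & tab$h2[ok] <= 1))
  expect_true(all(tab$p_h2[ok] > 0 & tab$p_h2[ok] <= 1))
  expect_true(all(abs(tab$h2[ok] -
                        tab$sigma_a2[ok] / (tab$sigma_a2[ok] +
                                              tab$sigma_l2[ok] +
                                              tab$sigma_e2[ok])) < 1e-8))
})
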