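# Average-information REML for variance-component models V = sum_k theta_k K_k
# with dense symmetric structures K_k (n up to ~1000). EM-stabilized warm-up,
# AI updates with step halving, non-negativity by clamping at a small floor,
# covariance parameters projected inside the PSD bound of their two variances.

aireml_fit <- function(y, X, K, is_var, cov_bound = NULL,
                       init = NULL, max_iter = 100L, tol = 1e-6,
                       n_em = 3L, floor_frac = 1e-8) {
  n <- length(y)
  stopifnot(nrow(X) == n, all(vapply(K, nrow, 1L) == n))
  keep <- drop_aliased(X)
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  m <- length(K)
  vy <- stats::var(y)
  floor_v <- floor_frac * vy

  clamp <- function(th) {
    th[is_var] <- pmax(th[is_var], floor_v)
    if (!is.null(cov_bound)) {
      for (cb in cov_bound) {
        bnd <- 0.999 * sqrt(th[cb$i] * th[cb$j])
        th[cb$k] <- sign(th[cb$k]) * min(abs(th[cb$k]), bnd)
      }
    }
    th
  }

  build_V <- function(th) {
    V <- th[1] * K[[1]]
    for (k in seq_len(m)[-1]) V <- V + th[k] * K[[k]]
    V
  }

  ll_only <- function(th) {
    cV <- tryCatch(chol(build_V(th)), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(-Inf)
    b <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vi_y)))
    yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * b)
    -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + yPy +
              (n - p) * log(2 * pi))
  }

  if (is.null(init)) {
    init <- rep(0, m)
    init[is_var] <- vy / sum(is_var)
  }
  th <- clamp(init)
  ll <- ll_only(th)
  converged <- FALSE
  AIm <- NULL
  grad <- rep(NA_real_, m)

  for (it in seq_len(max_iter)) {
    cV <- tryCatch(chol(build_V(th)), error = function(e) NULL)
    if (is.null(cV)) break
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cX <- chol(XtViX)
    XtViX_inv <- chol2inv(cX)
    P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
    Py <- drop(P %*% y)

    KPy <- matrix(0, n, m)
    trPK <- numeric(m)
    for (k in seq_len(m)) {
      KPy[, k] <- K[[k]] %*% Py
      trPK[k] <- sum(P * K[[k]])
    }
    yPKPy <- drop(crossprod(Py, KPy))
    grad <- -0.5 * (trPK - yPKPy)
    PKPy <- P %*% KPy
    AIm <- 0.5 * crossprod(KPy, PKPy)

    if (it <= n_em) {
      delta <- rep(0, m)
      delta[is_var] <- th[is_var]^2 * (yPKPy[is_var] - trPK[is_var]) / n
    } else {
      delta <- tryCatch(
        solve(AIm + diag(1e-8 * max(diag(AIm)) + 1e-12, m), grad),
        error = function(e) grad / (abs(diag(AIm)) + 1))
    }

    attempt <- function(dl) {
      step <- 1
      for (h in 1:12) {
        th_try <- clamp(th + step * dl)
        ll_try <- ll_only(th_try)
        if (ll_try >= ll - 1e-8)
          return(list(th = th_try, ll = ll_try, ok = TRUE))
        step <- step / 2
      }
      list(ok = FALSE)
    }
    acc <- attempt(delta)
    if (!acc$ok && it > n_em) {
      # active-set retry: freeze variances pinned at the floor whose
      # gradient points outward, re-solve the AI system for the rest
      pinned <- is_var & th <= floor_v * (1 + 1e-6) & grad < 0
      if (any(pinned) && any(!pinned)) {
        free <- which(!pinned)
        d2 <- numeric(m)
        d2[free] <- tryCatch(
          solve(AIm[free, free, drop = FALSE] +
                  diag(1e-8 * max(diag(AIm)) + 1e-12, length(free)),
                grad[free]),
          error = function(e) grad[free] / (abs(diag(AIm))[free] + 1))
        acc <- attempt(d2)
      }
    }
    if (!acc$ok) {  # no uphill step: constrained optimum at line-search
      converged <- TRUE
      break
    }
    th_new <- acc$th
    ll_new <- acc$ll
    rel <- max(abs(th_new - th) / pmax(abs(th), floor_v))
    improved <- ll_new - ll
    th <- th_new
    ll <- ll_new
    if (it > n_em && rel < tol && max(abs(grad)) < 1e-4 * max(1, n * vy)) {
      converged <- TRUE
      break
    }
    if (it > n_em && rel < tol && improved < 1e-10) {
      converged <- TRUE
      break
    }
  }

  se <- rep(NA_real_, m)
  ai_inv <- tryCatch(solve(AIm), error = function(e) NULL)
  if (!is.null(ai_inv)) se <- sqrt(pmax(diag(ai_inv), 0))
  list(theta = th, loglik = ll, converged = converged, se = se,
       ai_inv = ai_inv, grad = grad, n = n, p = p)
}

# litter (or any grouping) similarity structure: 1 if same level
grouping_structure <- function(f) {
  Z <- stats::model.matrix(~ 0 + ff, data.frame(ff = factor(f)))
  tcrossprod(Z)
}

#' Univariate animal-model REML for heritability and litter proportion
#'
#' Fits `y = Xb + a + litter + (run) + e` with `a ~ N(0, G sigma_a2)`,
#' `litter ~ N(0, I sigma_l2)` by average-information REML (EM-stabilized
#' first steps, non-negativity by clamping). Heritability and the litter
#' proportion are expressed as fractions of `sigma_a2 + sigma_l2 + sigma_e2`;
#' the optional run variance is estimated but excluded from that denominator.
#' Boundary likelihood-ratio tests (mixture 0.5 chi2_0 + 0.5 chi2_1) against
#' models without the animal (resp. litter) effect give p-values for h2 and
#' the litter proportion.
#'
#' @param y Numeric response (one record per animal).
#' @param grm Relationship matrix covering all records ([build_grm()] or any
#'   matrix with animal ids as dimnames).
#' @param ids Animal ids aligning `y` with `grm` (default `names(y)`).
#' @param X Fixed-effect design matrix (default intercept only).
#' @param litter Litter factor, or `NULL` to omit the litter component.
#' @param run Optional run factor: adds a nuisance variance component
#'   excluded from the phenotypic-variance denominator.
#' @param lrt Logical; also fit the reduced models for the boundary LRTs.
#' @param max_iter,tol Passed to the AI-REML core.
#' @return Object of class `"varcomp"`: a list with `sigma_a2`, `sigma_l2`,
#'   `sigma_e2` (and `sigma_run2` if requested), `h2`, `litter_prop`,
#'   standard errors (AI-based, delta method for the ratios), `loglik`,
#'   `p_h2`, `p_litter`, `converged`.
#' @export
reml_univariate <- function(y, grm, ids = names(y), X = NULL, litter = NULL,
                            run = NULL, lrt = TRUE, max_iter = 100L,
                            tol = 1e-6) {
  n <- length(y)
  if (n < 50) stop("reml_univariate: need at least 50 records")
  if (is.null(ids)) stop("reml_univariate: need animal ids (names of y)")
  idx <- match(ids, rownames(grm))
  if (anyNA(idx)) stop("reml_univariate: GRM does not cover all records")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  K <- list(a = unclass(grm)[idx, idx, drop = FALSE])
  if (!is.null(litter)) K$l <- grouping_structure(litter)
  if (!is.null(run)) K$run <- grouping_structure(run)
  K$e <- diag(n)
  m <- length(K)
  is_var <- rep(TRUE, m)

  fit <- aireml_fit(y, X, K, is_var, max_iter = max_iter, tol = tol)
  th <- fit$theta
  names(th) <- names(K)
  sa <- th[["a"]]
  sl <- if (!is.null(litter)) th[["l"]] else 0
  se2 <- th[["e"]]
  vtot <- sa + sl + se2
  h2 <- sa / vtot
  litter_prop <- sl / vtot

  p_h2 <- p_litter <- NA_real_
  ll_no_a <- ll_no_l <- NA_real_
  if (lrt) {
    drop_one <- function(comp) {
      keep <- names(K) != comp
      f0 <- aireml_fit(y, X, K[keep], rep(TRUE, sum(keep)),
                       max_iter = max_iter, tol = tol)
      # nesting guard: the full model must reach at least the reduced
      # optimum; warm-start it from the reduced solution if it fell short
      if (f0$loglik > fit$loglik + 1e-8) {
        init <- stats::setNames(numeric(m), names(K))
        init[keep] <- f0$theta
        init[comp] <- 1e-6 * stats::var(y)
        refit <- aireml_fit(y, X, K, is_var, init = unname(init),
                            max_iter = max_iter, tol = tol)
        if (refit$loglik > fit$loglik) fit <<- refit
      }
      f0$loglik
    }
    ll_no_a <- drop_one("a")
    if (!is.null(litter)) ll_no_l <- drop_one("l")
    th <- stats::setNames(fit$theta, names(K))
    sa <- th[["a"]]
    sl <- if (!is.null(litter)) th[["l"]] else 0
    se2 <- th[["e"]]
    vtot <- sa + sl + se2
    h2 <- sa / vtot
    litter_prop <- sl / vtot
    p_h2 <- lrt_boundary(fit$loglik, ll_no_a, tol = 0.05)
    if (!is.null(litter))
      p_litter <- lrt_boundary(fit$loglik, ll_no_l, tol = 0.05)
  }

  # delta-method SEs for the ratios from the AI inverse
  se_h2 <- se_lp <- NA_real_
  if (!is.null(fit$ai_inv)) {
    pos <- match(c("a", "l", "e"), names(K))
    pos <- pos[!is.na(pos)]
    Vth <- fit$ai_inv[pos, pos, drop = FALSE]
    dh <- (vtot * (names(K)[pos] == "a") - sa) / vtot^2
    se_h2 <- sqrt(max(drop(t(dh) %*% Vth %*% dh), 0))
    if (!is.null(litter)) {
      dl <- (vtot * (names(K)[pos] == "l") - sl) / vtot^2
      se_lp <- sqrt(max(drop(t(dl) %*% Vth %*% dl), 0))
    }
  }

  out <- list(sigma_a2 = sa, sigma_l2 = sl, sigma_e2 = se2,
              sigma_run2 = if (!is.null(run)) th[["run"]] else NA_real_,
              h2 = h2, litter_prop = litter_prop,
              se_h2 = se_h2, se_litter_prop = se_lp,
              se_components = stats::setNames(fit$se, names(K)),
              loglik = fit$loglik, loglik_no_animal = ll_no_a,
              loglik_no_litter = ll_no_l,
              p_h2 = p_h2, p_litter = p_litter,
              converged = fit$converged, n = n)
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Animal model (AI-REML): n =", x$n, "\n",
      " sigma_a2 =", signif(x$sigma_a2, 4),
      " sigma_l2 =", signif(x$sigma_l2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4), "\n",
      " h2 =", round(x$h2, 3), "(p =", signif(x$p_h2, 3),
      ") litter =", round(x$litter_prop, 3), "\n")
  invisible(x)
}

#' Bivariate animal-model REML for a genetic correlation
#'
#' Fits a two-trait animal model with an unstructured 2x2 genetic
#' (co)variance, independent litter effects per trait, and
#' heterogeneous residual variances; the residual covariance is fixed at 0
#' by default (appropriate when trait 1 is a model-adjusted protein residual
#' and the two record sets overlap only partially) or, with
#' `resid_cov = TRUE`, estimated through the jointly-measured animals. The
#' genetic correlation is tested against 0 by an ordinary chi-square(1)
#' likelihood-ratio test (the covariance is an interior parameter, so the
#' boundary mixture does not apply).
#'
#' @param y1,y2 Records for trait 1 (e.g. protein residuals) and trait 2.
#' @param ids1,ids2 Animal ids for each record vector (default names).
#' @param grm Relationship matrix covering both record sets.
#' @param X1,X2 Fixed-effect designs (default intercepts).
#' @param litter1,litter2 Litter factors (or `NULL`).
#' @param resid_cov Estimate the residual covariance over jointly-measured
#'   animals (default `FALSE`).
#' @param lrt Fit the constrained (r_g = 0) model for the LRT.
#' @param max_iter,tol Passed to the AI-REML core.
#' @return Object of class `"rg_estimate"`: `r_g`, genetic (co)variances,
#'   per-trait variance components and h2, `loglik`, `loglik_rg0`,
#'   `p_value`, `converged`.
#' @export
reml_bivariate <- function(y1, y2, grm, ids1 = names(y1), ids2 = names(y2),
                           X1 = NULL, X2 = NULL, litter1 = NULL,
                           litter2 = NULL, resid_cov = FALSE, lrt = TRUE,
                           max_iter = 100L, tol = 1e-6) {
  n1 <- length(y1)
  n2 <- length(y2)
  if (is.null(ids1) || is.null(ids2))
    stop("reml_bivariate: need animal ids (names of y1/y2)")
  i1 <- match(ids1, rownames(grm))
  i2 <- match(ids2, rownames(grm))
  if (anyNA(i1) || anyNA(i2))
    stop("reml_bivariate: GRM does not cover all records")
  if (is.null(X1)) X1 <- matrix(1, n1, 1)
  if (is.null(X2)) X2 <- matrix(1, n2, 1)
  colnames(X1) <- paste0("t1_", if (is.null(colnames(X1)))
    seq_len(ncol(X1)) else colnames(X1))
  colnames(X2) <- paste0("t2_", if (is.null(colnames(X2)))
    seq_len(ncol(X2)) else colnames(X2))

  N <- n1 + n2
  b1 <- seq_len(n1)
  b2 <- n1 + seq_len(n2)
  y <- c(as.numeric(y1), as.numeric(y2))
  X <- matrix(0, N, ncol(X1) + ncol(X2),
              dimnames = list(NULL, c(colnames(X1), colnames(X2))))
  X[b1, seq_len(ncol(X1))] <- X1
  X[b2, ncol(X1) + seq_len(ncol(X2))] <- X2

  G <- unclass(grm)
  zero <- matrix(0, N, N)
  Ka11 <- zero; Ka11[b1, b1] <- G[i1, i1]
  Ka22 <- zero; Ka22[b2, b2] <- G[i2, i2]
  Ka12 <- zero
  Ka12[b1, b2] <- G[i1, i2]
  Ka12 <- Ka12 + t(Ka12)
  Ke1 <- zero; diag(Ke1)[b1] <- 1
  Ke2 <- zero; diag(Ke2)[b2] <- 1

  K <- list(a1 = Ka11, a12 = Ka12, a2 = Ka22)
  if (!is.null(litter1)) {
    Kl1 <- zero; Kl1[b1, b1] <- grouping_structure(litter1); K$l1 <- Kl1
  }
  if (!is.null(litter2)) {
    Kl2 <- zero; Kl2[b2, b2] <- grouping_structure(litter2); K$l2 <- Kl2
  }
  K$e1 <- Ke1
  K$e2 <- Ke2
  if (resid_cov) {
    same <- outer(ids1, ids2, `==`)
    if (any(same)) {
      Ke12 <- zero
      Ke12[b1, b2] <- same
      Ke12 <- Ke12 + t(Ke12)
      K$e12 <- Ke12
    }
  }
  nm <- names(K)
  m <- length(K)
  is_var <- !(nm %in% c("a12", "e12"))
  cov_bound <- list(list(k = which(nm == "a12"), i = which(nm == "a1"),
                         j = which(nm == "a2")))
  if ("e12" %in% nm)
    cov_bound <- c(cov_bound, list(list(k = which(nm == "e12"),
                                        i = which(nm == "e1"),
                                        j = which(nm == "e2"))))

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  init <- numeric(m)
  init[nm == "a1"] <- 0.3 * v1; init[nm == "a2"] <- 0.3 * v2
  init[nm == "l1"] <- 0.1 * v1; init[nm == "l2"] <- 0.1 * v2
  init[nm == "e1"] <- 0.6 * v1; init[nm == "e2"] <- 0.6 * v2

  fit <- aireml_fit(y, X, K, is_var, cov_bound = cov_bound, init = init,
                    max_iter = max_iter, tol = tol)
  th <- stats::setNames(fit$theta, nm)
  r_g <- th[["a12"]] / sqrt(th[["a1"]] * th[["a2"]])
  r_g <- max(min(r_g, 1), -1)

  p <- NA_real_
  ll0 <- NA_real_
  if (lrt) {
    keep0 <- nm != "a12"
    cb0 <- if ("e12" %in% nm)
      list(list(k = which(nm[keep0] == "e12"),
                i = which(nm[keep0] == "e1"),
                j = which(nm[keep0] == "e2"))) else NULL
    fit0 <- aireml_fit(y, X, K[keep0], is_var[keep0], cov_bound = cb0,
                       init = init[keep0], max_iter = max_iter, tol = tol)
    ll0 <- fit0$loglik
    if (ll0 > fit$loglik + 1e-8) {
      # nesting guard: warm-start the free model from the constrained one
      init2 <- numeric(m)
      init2[keep0] <- fit0$theta
      refit <- aireml_fit(y, X, K, is_var, cov_bound = cov_bound,
                          init = init2, max_iter = max_iter, tol = tol)
      if (refit$loglik > fit$loglik) {
        fit <- refit
        th <- stats::setNames(fit$theta, nm)
        r_g <- th[["a12"]] / sqrt(th[["a1"]] * th[["a2"]])
        r_g <- max(min(r_g, 1), -1)
      }
    }
    lam <- 2 * (fit$loglik - ll0)
    if (lam < -1e-6)
      warning("reml_bivariate: constrained fit beat the free fit (",
              signif(lam, 3), "); p-value set to 1")
    p <- stats::pchisq(max(lam, 0), df = 1, lower.tail = FALSE)
  }

  vt1 <- th[["a1"]] + (if ("l1" %in% nm) th[["l1"]] else 0) + th[["e1"]]
  vt2 <- th[["a2"]] + (if ("l2" %in% nm) th[["l2"]] else 0) + th[["e2"]]
  out <- list(r_g = r_g, sigma_a12 = th[["a12"]],
              components = th,
              h2_1 = th[["a1"]] / vt1, h2_2 = th[["a2"]] / vt2,
              loglik = fit$loglik, loglik_rg0 = ll0, p_value = p,
              converged = fit$converged, n1 = n1, n2 = n2)
  class(out) <- "rg_estimate"
  out
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat("Bivariate animal model: r_g =", round(x$r_g, 3),
      "(p =", signif(x$p_value, 3), "), n =", x$n1, "+", x$n2, "\n")
  invisible(x)
}

#' Likelihood-ratio test for a variance component on the boundary
#'
#' `Lambda = 2 (ll_full - ll_reduced)` (clipped at 0) compared to the
#' 0.5 chi2_0 + 0.5 chi2_1 mixture: `p = 0.5 P(chi2_1 > Lambda)`. With
#' `mixture = FALSE` the ordinary chi-square(1) tail is returned (interior
#' parameters such as a covariance).
#'
#' @param ll_full,ll_reduced Restricted log-likelihoods of the nested fits.
#' @param mixture Halve the chi-square tail (boundary case, default).
#' @param tol Allowed negative slack before erroring (optimizer-bug signal).
#' @return p-value in (0, 1].
#' @export
lrt_boundary <- function(ll_full, ll_reduced, mixture = TRUE, tol = 1e-6) {
  lambda <- 2 * (ll_full - ll_reduced)
  if (lambda < -tol)
    stop("lrt_boundary: ll_full < ll_reduced beyond tolerance (Lambda = ",
         signif(lambda, 4), "); the optimizer likely failed")
  lambda <- max(lambda, 0)
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  if (mixture) p <- 0.5 * p
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR q-values, optionally within groups (the pooling scope:
#' per-trait vs across all traits and tests). `NA`/NaN p-values are excluded
#' with a warning and returned as `NA`.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param grouping Optional vector defining pooling groups.
#' @return q-values, same length/order as `p_values`.
#' @export
bh_fdr <- function(p_values, grouping = NULL) {
  if (anyNA(p_values))
    warning("bh_fdr: ", sum(is.na(p_values)), " NA p-value(s) excluded")
  if (is.null(grouping)) grouping <- rep(1L, length(p_values))
  q <- rep(NA_real_, length(p_values))
  for (g in unique(grouping)) {
    idx <- which(grouping == g & !is.na(p_values))
    if (!length(idx)) next
    pg <- p_values[idx]
    mg <- length(pg)
    o <- order(pg)
    qs <- pg[o] * mg / seq_len(mg)
    qs <- rev(cummin(rev(qs)))
    qs <- pmin(qs, 1)
    q[idx[o]] <- qs
  }
  q
}
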