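# Linear mixed model with one random intercept, fitted by REML profiled
# over the variance ratio lambda = sigma2_u / sigma2_e. With Z the group
# indicator matrix, V = sigma2_e (I + lambda Z Z') and Woodbury gives
#   (I + lambda Z Z')^{-1} = I - Z diag(lambda / (1 + lambda n_j)) Z'
# so every likelihood evaluation is O(n p + p^3). Brent search on log-lambda
# plus an explicit boundary evaluation at lambda = 0.

# deterministic left-to-right aliasing removal: keep a column iff it adds rank
drop_aliased <- function(X, warn_label = NULL) {
  p <- ncol(X)
  qr_all <- qr(X)
  if (qr_all$rank == p) return(seq_len(p))
  keep <- integer(0)
  r <- 0L
  for (j in seq_len(p)) {
    rj <- qr(X[, c(keep, j), drop = FALSE])$rank
    if (rj > r) {
      keep <- c(keep, j)
      r <- rj
    }
  }
  if (!is.null(warn_label))
    warning(warn_label, ": dropped aliased column(s) ",
            paste(colnames(X)[setdiff(seq_len(p), keep)], collapse = ", "))
  keep
}

# core fitter; group = NULL gives generalized least squares with W = I (OLS)
fit_lmm_reml <- function(y, X, group = NULL, drop_alias = TRUE,
                         warn_label = NULL) {
  ok <- stats::complete.cases(y, X)
  if (!is.null(group)) ok <- ok & !is.na(group)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  keep <- if (drop_alias) drop_aliased(X, warn_label) else seq_len(ncol(X))
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  if (n <= p) stop("fit_lmm_reml: fewer observations than fixed effects")

  if (!is.null(group)) {
    group <- droplevels(factor(group[ok]))
    gi <- as.integer(group)
    nj <- tabulate(gi)
    q <- length(nj)
  }

  # profiled REML criterion at variance ratio lambda >= 0
  eval_lambda <- function(lambda) {
    if (is.null(group) || lambda <= 0) {
      Wy <- y; WX <- X; ldW <- 0
    } else {
      d <- lambda / (1 + lambda * nj)
      sy <- rowsum(y, gi)[, 1]
      SX <- rowsum(X, gi)
      Wy <- y - (d * sy)[gi]
      WX <- X - (d[gi]) * SX[gi, , drop = FALSE]
      ldW <- sum(log1p(lambda * nj))
    }
    XtWX <- crossprod(X, WX)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, Wy)))
    r <- y - X %*% beta
    # r' W^{-1} r computed through Wy-style contraction
    if (is.null(group) || lambda <= 0) {
      rWr <- sum(r * r)
    } else {
      sr <- rowsum(r, gi)[, 1]
      d <- lambda / (1 + lambda * nj)
      rWr <- sum(r * r) - sum(d * sr^2)
    }
    s2e <- rWr / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + ldW +
                    2 * sum(log(diag(ch))))
    list(ll = ll, beta = beta, s2e = s2e, chol_XtWX = ch)
  }

  if (is.null(group)) {
    lambda <- 0
    opt_ll <- eval_lambda(0)$ll
  } else {
    f <- function(t) -eval_lambda(exp(t))$ll
    opt <- stats::optimize(f, interval = c(-20, 15),
                           tol = .Machine$double.eps^0.4)
    ll0 <- eval_lambda(0)$ll
    # boundary preference: snap to lambda = 0 unless the interior optimum
    # is a real improvement
    if (ll0 >= -opt$objective - 1e-8) {
      lambda <- 0
      opt_ll <- ll0
    } else {
      lambda <- exp(opt$minimum)
      opt_ll <- -opt$objective
    }
  }

  fit <- eval_lambda(lambda)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  s2e <- fit$s2e
  vcov_beta <- chol2inv(fit$chol_XtWX) * s2e
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  r_marg <- drop(y - X %*% fit$beta)
  if (!is.null(group) && lambda > 0) {
    d <- lambda / (1 + lambda * nj)
    sr <- rowsum(r_marg, gi)[, 1]
    blup <- lambda * (sr - d * nj * sr)       # lambda * Z' W^{-1} r
    names(blup) <- levels(group)
    r_cond <- r_marg - blup[gi]
  } else {
    blup <- if (is.null(group)) NULL else stats::setNames(rep(0, q),
                                                          levels(group))
    r_cond <- r_marg
  }

  res <- list(beta = beta, vcov = vcov_beta,
              se = sqrt(diag(vcov_beta)),
              sigma2_u = lambda * s2e, sigma2_e = s2e, lambda = lambda,
              loglik = fit$ll, n = n, kept = keep,
              resid_marginal = r_marg, resid_conditional = r_cond,
              blup = blup, obs_used = which(ok), converged = TRUE)
  class(res) <- "lmm_fit"
  res
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("LMM (REML, single random intercept): n =", x$n,
      " sigma2_u =", signif(x$sigma2_u, 4),
      " sigma2_e =", signif(x$sigma2_e, 4),
      " logLik =", round(x$loglik, 3), "\n")
  invisible(x)
}

# Wald z test for one coefficient
wald_test <- function(fit, term) {
  b <- fit$beta[term]
  se <- fit$se[term]
  z <- b / se
  c(estimate = unname(b), se = unname(se),
    p = unname(2 * stats::pnorm(-abs(z))))
}
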