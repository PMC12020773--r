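# Fast closed-form fitter for the one-random-intercept Gaussian mixed model
#
#   y = X beta + Z u + e,  u_g ~ N(0, sigma_u^2),  e ~ N(0, sigma_e^2)
#
# With a single grouping factor, V = sigma_e^2 (I + theta Z Z') with
# theta = sigma_u^2 / sigma_e^2, and (I + theta J_g)^{-1} has the closed
# Sherman-Morrison form per group, so beta and sigma_e^2 profile out and only
# theta needs a 1-D optimisation. This is orders of magnitude faster than a
# general mixed-model fitter and is used inside the multiple-imputation loop;
# unit tests cross-check it against lme4::lmer on the same data.

ri_suffstats <- function(y, X, group) {
  group <- as.factor(group)
  idx <- split(seq_along(y), group)
  ng <- lengths(idx)
  p <- ncol(X)
  # per-group: X'X, X'1, 1'y, X'y, y'y
  Sxx <- crossprod(X)
  Sxy <- crossprod(X, y)
  Syy <- sum(y * y)
  Xg1 <- rowsum(X, group)          # G x p : column sums per group
  yg1 <- rowsum(y, group)[, 1]     # G     : y sums per group
  list(Sxx = Sxx, Sxy = Sxy, Syy = Syy, Xg1 = Xg1, yg1 = yg1,
       ng = as.numeric(ng), n = length(y), p = p,
       levels = levels(group), group = group)
}

# Profiled -2*log-likelihood (REML or ML) at a given theta >= 0.
ri_profile <- function(ss, theta, reml = TRUE) {
  cg <- theta / (1 + theta * ss$ng)                  # per-group shrink weight
  A <- ss$Sxx - crossprod(ss$Xg1 * sqrt(cg))         # X' V*^-1 X
  b <- ss$Sxy - crossprod(ss$Xg1, cg * ss$yg1)       # X' V*^-1 y
  qyy <- ss$Syy - sum(cg * ss$yg1^2)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(obj = Inf))
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  rss <- max(qyy - 2 * sum(beta * b) + sum(beta * (A %*% beta)), 1e-12)
  n <- ss$n; p <- ss$p
  logdetV <- sum(log1p(theta * ss$ng))
  if (reml) {
    logdetA <- 2 * sum(log(diag(R)))
    sigma2 <- rss / (n - p)
    obj <- (n - p) * log(2 * pi * sigma2) + logdetV + logdetA + (n - p)
  } else {
    sigma2 <- rss / n
    obj <- n * log(2 * pi * sigma2) + logdetV + n
  }
  list(obj = obj, beta = beta, sigma2 = sigma2, A = A, R = R, rss = rss)
}

# Fit the random-intercept model. Returns an object of class "ri_fit".
ri_fit <- function(y, X, group, reml = TRUE) {
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; group <- factor(group[keep])
  if (nrow(X) <= ncol(X)) stop("more coefficients than observations")
  ss <- ri_suffstats(y, X, group)
  f <- function(lt) ri_profile(ss, exp(lt), reml)$obj
  opt <- optimize(f, interval = c(-16, 16), tol = 1e-10)
  # compare against the theta = 0 boundary (no group variance)
  at0 <- ri_profile(ss, 0, reml)
  if (at0$obj <= opt$objective) {
    theta <- 0; prof <- at0
  } else {
    theta <- exp(opt$minimum); prof <- ri_profile(ss, theta, reml)
  }
  Ainv <- chol2inv(prof$R)
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  vcov <- prof$sigma2 * Ainv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # per-group residual means for BLUPs / conditional draws
  res <- y - drop(X %*% prof$beta)
  rg <- rowsum(res, ss$group)[, 1] / ss$ng
  structure(list(
    beta = beta, vcov = vcov,
    sigma2_e = prof$sigma2, sigma2_u = theta * prof$sigma2, theta = theta,
    logLik = -prof$obj / 2 - if (reml) 0 else 0,
    m2ll = prof$obj, reml = reml, n = ss$n, p = ss$p,
    group_levels = ss$levels, group_n = setNames(ss$ng, ss$levels),
    group_resid_mean = setNames(rg, ss$levels)
  ), class = "ri_fit")
}

# Shrunken person-effect predictions (BLUPs): shrink * mean residual.
ri_blup <- function(fit, ids = fit$group_levels) {
  ng <- fit$group_n[ids]
  shrink <- fit$theta * ng / (1 + fit$theta * ng)
  unname(shrink * fit$group_resid_mean[ids])
}

# Conditional posterior variance of the person effect given its reports.
ri_cond_var <- function(fit, ids = fit$group_levels) {
  ng <- fit$group_n[ids]
  if (fit$theta == 0) return(rep(0, length(ids)))
  unname(fit$sigma2_e * fit$theta / (1 + ng * fit$theta))
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Random-intercept model (", if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("  n =", x$n, " groups =", length(x$group_levels), "\n")
  cat("  sigma_u^2 =", signif(x$sigma2_u, 4),
      " sigma_e^2 =", signif(x$sigma2_e, 4), "\n")
  print(signif(x$beta, 4))
  invisible(x)
}
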