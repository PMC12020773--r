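# Single-exposure analysis: exhaustive best-subset selection over the five
# usual exposures (covariates always included), then cluster-bootstrap
# percentile confidence intervals for the selected coefficients. Exposures
# enter on natural units so coefficients read as per-hour / per-percent /
# per-occasion effects.

selection_design <- function(data, covariates, exposures) {
  data <- as.data.frame(data)
  for (v in intersect(c("sex", "isced", "country"), covariates)) {
    data[[v]] <- factor(as.character(data[[v]]))
  }
  rhs <- paste(c(covariates, exposures), collapse = " + ")
  model.matrix(as.formula(paste("~", rhs)), data = data)
}

col_var <- function(x) {
  m <- colMeans(x)
  colMeans(x^2) - m^2
}

all_subsets <- function(items) {
  n <- length(items)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    out[[mask]] <- items[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

#' Best-subset selection over the usual meal-timing exposures
#'
#' Evaluates every non-empty subset of the five usual exposures (31 models)
#' with the adjustment covariates held fixed, ranks them by an information
#' criterion on maximum-likelihood mixed-model fits (family random
#' intercept), and refits the winning subset by REML for the reported
#' coefficients. Rank-deficient subsets are skipped with a log entry.
#'
#' @param data one row per participant: outcome z column, the five exposure
#'   columns on natural units, \code{family_id} and the covariates.
#' @param outcome outcome z column name.
#' @param covariates fixed adjustment covariates (default the basic set).
#' @param exposures candidate exposure columns (default [exposure_names()]).
#' @param criterion \code{"bic"} (default), \code{"aic"} or \code{"mallows"}
#'   (Mallows-style penalty 2p relative to the full-model error variance).
#' @return list of class \code{subset_result}: \code{selected} exposure
#'   names, \code{coefficients} (REML data.frame), \code{criterion},
#'   \code{criterion_value}, a \code{table} of all subsets with criterion
#'   values, and \code{skipped}.
#' @export
best_subset <- function(data, outcome,
                        covariates = c("age", "bmi_z", "isced", "sex", "country"),
                        exposures = exposure_names(),
                        criterion = c("bic", "aic", "mallows")) {
  criterion <- match.arg(criterion)
  if (length(exposures) < 1) stop("need at least one candidate exposure")
  data <- as.data.frame(data)
  need <- c(outcome, "family_id", covariates, exposures)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  y <- data[[outcome]]
  group <- data$family_id
  n <- length(y)

  # Mallows-style option needs the full-model error variance as yardstick
  s2_full <- NULL
  if (criterion == "mallows") {
    Xf <- selection_design(data, covariates, exposures)
    s2_full <- ri_fit(y, Xf, group, reml = TRUE)$sigma2_e
  }
  subsets <- all_subsets(exposures)
  rows <- vector("list", length(subsets))
  skipped <- character(0)
  for (i in seq_along(subsets)) {
    X <- selection_design(data, covariates, subsets[[i]])
    if (qr(X)$rank < ncol(X)) {
      skipped <- c(skipped, paste(subsets[[i]], collapse = "+"))
      next
    }
    fit <- tryCatch(ri_fit(y, X, group, reml = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, paste(subsets[[i]], collapse = "+"))
      next
    }
    p_all <- ncol(X) + 2  # fixed effects + two variance components
    crit <- switch(criterion,
      bic = fit$m2ll + p_all * log(n),
      aic = fit$m2ll + 2 * p_all,
      mallows = n * fit$sigma2_e / s2_full - n + 2 * p_all)
    rows[[i]] <- data.frame(subset = paste(subsets[[i]], collapse = "+"),
                            size = length(subsets[[i]]), criterion = crit)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("every subset was rank deficient")
  best_i <- which.min(tab$criterion)
  selected <- strsplit(tab$subset[best_i], "+", fixed = TRUE)[[1]]

  Xb <- selection_design(data, covariates, selected)
  refit <- ri_fit(y, Xb, group, reml = TRUE)
  idx <- match(selected, names(refit$beta))
  coefficients <- data.frame(exposure = selected,
                             estimate = unname(refit$beta[idx]),
                             se = sqrt(diag(refit$vcov)[idx]),
                             row.names = NULL)
  structure(list(selected = selected, coefficients = coefficients,
                 criterion = criterion,
                 criterion_value = tab$criterion[best_i],
                 table = tab[order(tab$criterion), ],
                 skipped = skipped, outcome = outcome,
                 covariates = covariates, n = n),
            class = "subset_result")
}

#' Cluster-bootstrap percentile confidence intervals
#'
#' With the selected exposure set fixed, resamples clusters (families by
#' default, preserving the random-intercept structure; individuals via
#' \code{resample = "individual"}) with replacement, refits the REML model
#' per replicate and returns 2.5/97.5 percentile intervals per coefficient.
#' More than 5\% failed refits aborts.
#'
#' @inheritParams best_subset
#' @param selected exposure names fixed before resampling (e.g.
#'   \code{subset_result$selected}).
#' @param B bootstrap replicates (analysis default 1000).
#' @param seed integer seed.
#' @param resample \code{"family"} or \code{"individual"}.
#' @param conf_level confidence level (default 0.95).
#' @return list of class \code{bootstrap_ci}: \code{ci} data.frame
#'   (exposure, estimate, lower, upper), \code{B}, \code{failures} and the
#'   replicate matrix.
#' @export
bootstrap_ci <- function(data, outcome, selected,
                         covariates = c("age", "bmi_z", "isced", "sex", "country"),
                         B = 1000, seed = 1L, resample = c("family", "individual"),
                         conf_level = 0.95) {
  resample <- match.arg(resample)
  data <- as.data.frame(data)
  need <- c(outcome, "family_id", covariates, selected)
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  y0 <- data[[outcome]]
  X0 <- selection_design(data, covariates, selected)
  refit0 <- ri_fit(y0, X0, data$family_id, reml = TRUE)
  point <- refit0$beta[selected]

  units <- if (resample == "family") split(seq_len(nrow(data)), data$family_id)
           else as.list(seq_len(nrow(data)))
  draws <- matrix(NA_real_, B, length(selected),
                  dimnames = list(NULL, selected))
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      pick <- sample.int(length(units), replace = TRUE)
      idx <- unlist(units[pick], use.names = FALSE)
      # resampled clusters become distinct groups to keep the RE structure
      grp <- rep(seq_along(pick), lengths(units[pick]))
      Xb <- X0[idx, , drop = FALSE]
      # a resample can lose rare factor levels entirely; drop the dead
      # dummy columns instead of failing the replicate
      keep_col <- colnames(Xb) == "(Intercept)" |
        col_var(Xb) > 0
      fit <- tryCatch(
        ri_fit(y0[idx], Xb[, keep_col, drop = FALSE], grp, reml = TRUE),
        error = function(e) NULL)
      if (is.null(fit)) {
        failures <- failures + 1L
        if (failures > max(1, ceiling(0.05 * B))) {
          stop("more than 5% of bootstrap refits failed")
        }
        next
      }
      draws[b, ] <- fit$beta[selected]
    }
  })
  a <- (1 - conf_level) / 2
  ci <- data.frame(
    exposure = selected,
    estimate = unname(point),
    lower = apply(draws, 2, quantile, probs = a, na.rm = TRUE),
    upper = apply(draws, 2, quantile, probs = 1 - a, na.rm = TRUE),
    row.names = NULL)
  structure(list(ci = ci, B = B, failures = failures, draws = draws,
                 seed = seed, resample = resample),
            class = "bootstrap_ci")
}
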