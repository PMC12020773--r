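# Stage 3 and the multiple-imputation loop: linear mixed models of outcome
# z-scores on pattern membership with a family random intercept, repeated
# over conditional usual-exposure draws and pooled by Rubin's rule.

#' Age- and sex-specific outcome standardisation
#'
#' Within each sex, the raw outcome is residualised on a low-order
#' polynomial in age and divided by the residual SD, yielding z-scores with
#' mean 0 / SD 1 conditional on sex and (polynomially) on age. Values
#' already supplied as z-scores should bypass this (passthrough).
#'
#' @param values raw outcome values.
#' @param age,sex covariate vectors of matching length.
#' @param degree polynomial degree for the age trend (default 2).
#' @return numeric vector of z-scores.
#' @export
standardize_outcome <- function(values, age, sex, degree = 2) {
  sex <- normalize_sex(sex)
  z <- rep(NA_real_, length(values))
  for (s in unique(sex)) {
    i <- which(sex == s & !is.na(values))
    if (length(i) < 30) stop("fewer than 30 observations for sex = ", s)
    fit <- lm(values[i] ~ poly(age[i], degree))
    r <- resid(fit)
    z[i] <- r / sd(r)
  }
  z
}

#' Homeostasis model assessment of insulin resistance
#'
#' HOMA-IR = insulin (\eqn{\mu}U/mL) x glucose (mmol/L) / 22.5.
#'
#' @param glucose fasting glucose, mmol/L, > 0.
#' @param insulin fasting insulin, \eqn{\mu}U/mL, > 0.
#' @param constant divisor (default 22.5).
#' @return HOMA-IR values.
#' @export
compute_homa_ir <- function(glucose, insulin, constant = 22.5) {
  if (any(glucose <= 0) || any(insulin <= 0)) {
    stop("glucose and insulin must be positive")
  }
  insulin * glucose / constant
}

#' Model specification for the association stage
#'
#' The nested covariate sets: \code{basic} (age, BMI z, ISCED, sex, country),
#' \code{puberty} adds pubertal status, \code{energy_hfi} adds usual energy
#' and usual healthy-food intake, \code{fully_adjusted} additionally adds
#' sleep duration. Family membership always enters as a random intercept.
#'
#' @param outcome outcome column name (e.g. \code{"homa_ir_z"}).
#' @param model one of the four covariate-set labels.
#' @param reference reference pattern (default "early-often").
#' @param extra_covariates optional extra covariate column names appended to
#'   the fixed effects (generic sensitivity hook).
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(outcome, model = c("basic", "puberty", "energy_hfi",
                                          "fully_adjusted"),
                       reference = "early-often", extra_covariates = NULL) {
  model <- match.arg(model)
  covs <- c("age", "bmi_z", "isced", "sex", "country")
  covs <- switch(model,
    basic = covs,
    puberty = c(covs, "puberty"),
    energy_hfi = c(covs, "usual_energy", "usual_healthy"),
    fully_adjusted = c(covs, "usual_energy", "usual_healthy", "sleep_h"))
  structure(list(outcome = outcome, model = model,
                 covariates = c(covs, extra_covariates),
                 reference = reference),
            class = "model_spec")
}

lmm_design <- function(data, spec, mtp_levels) {
  data <- as.data.frame(data)
  data$mtp <- factor(data$mtp, levels = mtp_levels)
  for (v in intersect(c("sex", "isced", "country"), spec$covariates)) {
    data[[v]] <- factor(as.character(data[[v]]))
  }
  fml <- as.formula(paste("~ mtp +", paste(spec$covariates, collapse = " + ")))
  model.matrix(fml, data = data)
}

#' Linear mixed model of an outcome z-score on pattern membership
#'
#' Fixed effects are the pattern dummies versus the reference pattern plus
#' the covariate set of the [model_spec()]; a family random intercept
#' captures sibling correlation. The default engine is the package's
#' closed-form random-intercept REML fitter (cross-checked against
#' \pkg{lme4} in the test suite); \code{engine = "lmer"} fits the identical
#' model with \code{lme4::lmer}. A singular / failed \code{lmer} fit falls
#' back to the zero-family-variance least-squares fit with a warning.
#'
#' @param data one row per participant with columns \code{outcome} (per
#'   spec), \code{mtp}, \code{family_id} and the spec covariates.
#' @param spec a [model_spec()].
#' @param engine \code{"fast"} or \code{"lmer"}.
#' @return list of class \code{lmm_fit}: \code{contrasts} (data.frame with
#'   \code{term}, \code{estimate}, \code{se}), full coefficient vector,
#'   variance components and bookkeeping.
#' @export
fit_lmm <- function(data, spec, engine = c("fast", "lmer")) {
  engine <- match.arg(engine)
  data <- as.data.frame(data)
  need <- c(spec$outcome, "mtp", "family_id", spec$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!spec$reference %in% data$mtp) {
    stop("reference pattern `", spec$reference, "` absent from labels")
  }
  mtp_levels <- c(spec$reference, sort(setdiff(unique(data$mtp), spec$reference)))
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  y <- data[[spec$outcome]]
  X <- lmm_design(data, spec, mtp_levels)
  group <- data$family_id

  if (engine == "fast") {
    fit <- ri_fit(y, X, group, reml = TRUE)
    beta <- fit$beta; vc <- fit$vcov
    s2u <- fit$sigma2_u; s2e <- fit$sigma2_e
  } else {
    df <- data.frame(y = y, family_id = group)
    df <- cbind(df, as.data.frame(X[, -1, drop = FALSE]))
    xnames <- colnames(X)[-1]
    safe <- paste0("x", seq_along(xnames))
    names(df)[-(1:2)] <- safe
    fml <- as.formula(paste("y ~", paste(safe, collapse = " + "),
                            "+ (1 | family_id)"))
    mod <- tryCatch(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (is.null(mod)) {
      warning("lmer failed; falling back to zero family variance (OLS)")
      ols <- lm(y ~ X - 1)
      beta <- setNames(coef(ols), colnames(X))
      vc <- stats::vcov(ols); dimnames(vc) <- list(colnames(X), colnames(X))
      s2u <- 0; s2e <- summary(ols)$sigma^2
    } else {
      beta <- setNames(lme4::fixef(mod), colnames(X))
      vc <- as.matrix(stats::vcov(mod))
      dimnames(vc) <- list(colnames(X), colnames(X))
      s2u <- as.numeric(lme4::VarCorr(mod)$family_id)
      s2e <- stats::sigma(mod)^2
    }
  }
  idx <- grep("^mtp", names(beta))
  contrasts <- data.frame(
    term = sub("^mtp", "", names(beta)[idx]),
    estimate = unname(beta[idx]),
    se = sqrt(diag(vc)[idx]),
    row.names = NULL)
  structure(list(contrasts = contrasts, beta = beta, vcov = vc,
                 sigma2_family = s2u, sigma2_resid = s2e,
                 n = length(y), engine = engine, spec = spec,
                 mtp_levels = mtp_levels),
            class = "lmm_fit")
}

#' Pool estimates across imputations by Rubin's rule
#'
#' Pooled estimate = mean of the M estimates; within-imputation variance W =
#' mean of the variances; between-imputation variance B = sample variance of
#' the estimates; total variance T = W + (1 + 1/M) B; degrees of freedom
#' (classical large-sample form) \eqn{(M-1)(1 + W / ((1+1/M)B))^2}; the 95\%
#' CI is \eqn{\beta \pm t_{df} \sqrt{T}}. The Barnard-Rubin small-sample df
#' is available via \code{df_method}.
#'
#' @param estimates numeric vector of M point estimates.
#' @param variances numeric vector of M squared standard errors.
#' @param conf_level confidence level (default 0.95).
#' @param df_method \code{"classical"} or \code{"barnard_rubin"}.
#' @param n_obs,n_par complete-data size / parameter count, needed only for
#'   Barnard-Rubin.
#' @return list of class \code{mi_result}: \code{beta}, \code{W}, \code{B},
#'   \code{T}, \code{df}, \code{ci} (length 2), \code{M}.
#' @export
rubins_rule <- function(estimates, variances, conf_level = 0.95,
                        df_method = c("classical", "barnard_rubin"),
                        n_obs = NULL, n_par = NULL) {
  df_method <- match.arg(df_method)
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length")
  }
  M <- length(estimates)
  if (M < 1) stop("need at least one estimate")
  if (M == 1) {
    warning("M = 1: returning the single fit, no between-imputation variance")
    se <- sqrt(variances)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    return(structure(list(beta = estimates, W = variances, B = 0,
                          T = variances, df = Inf,
                          ci = estimates + c(-1, 1) * zq * se, M = 1L),
                     class = "mi_result"))
  }
  beta <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / M) * B
  if (B <= 0) {
    df <- Inf
  } else {
    df <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
    if (df_method == "barnard_rubin") {
      if (is.null(n_obs) || is.null(n_par)) {
        stop("Barnard-Rubin df needs n_obs and n_par")
      }
      df_com <- n_obs - n_par
      gamma <- (1 + 1 / M) * B / Tv
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - gamma)
      df <- 1 / (1 / df + 1 / df_obs)
    }
  }
  tq <- if (is.finite(df)) qt(1 - (1 - conf_level) / 2, df) else
    qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = beta, W = W, B = B, T = Tv, df = df,
                 ci = beta + c(-1, 1) * tq * sqrt(Tv), M = M),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("pooled beta %.4f (95%% CI %.4f, %.4f), M = %d, df = %.1f\n",
              x$beta, x$ci[1], x$ci[2], x$M, x$df))
  invisible(x)
}

participant_misreporter <- function(daily_labelled) {
  dt <- data.table::as.data.table(daily_labelled)
  dt <- dt[plausibility != "excluded_low_energy"]
  dt[, .(misreporter = mean(plausibility == "misreporter") >= 0.5),
     by = participant_id]
}

#' Three-stage association analysis with multiple-imputation correction
#'
#' Runs the full pipeline for one outcome: Stage 1 fits the
#' regression-calibration error models and predicts usual exposures; Stage 2
#' derives the meal-timing patterns by k-means on their z-scores (the
#' classification function is frozen); an outcome-conditioned Stage-1 model
#' set is then fitted, and for each of M imputations a conditional usual-
#' exposure draw is classified with the frozen Stage-2 model and the Stage-3
#' linear mixed model is fitted. The M contrast estimates are pooled with
#' [rubins_rule()]. Failed imputations are skipped and counted; more than
#' 5\% failures aborts.
#'
#' @param daily per-day exposure table (from [derive_daily_exposures()]).
#' @param participants participant covariate table.
#' @param outcomes table with \code{participant_id} and outcome z columns.
#' @param outcome outcome column name.
#' @param M number of imputations (analysis default 500; tests use less).
#' @param seed integer seed for the draws.
#' @param model covariate-set label, see [model_spec()].
#' @param k,n_starts clustering parameters.
#' @param lambda_grid Box-Cox grid for the error models.
#' @param plausible_only restrict to participants classified plausible
#'   (sensitivity analysis); the main analysis keeps misreporters and
#'   adjusts for BMI z instead.
#' @param engine passed to [fit_lmm()].
#' @param energy_threshold kcal threshold for the low-energy day exclusion.
#' @return list of class \code{three_stage_result}: \code{results}
#'   (data.frame of pooled contrasts), \code{mi} (list of \code{mi_result}),
#'   \code{mtp_model}, \code{usual_rc}, \code{counts}, \code{failures}.
#' @export
run_three_stage <- function(daily, participants, outcomes, outcome = "homa_ir_z",
                            M = 500, seed = 1L, model = "basic",
                            k = 3, n_starts = 25,
                            lambda_grid = c(0, 0.25, 0.5, 0.75, 1),
                            plausible_only = FALSE,
                            engine = c("fast", "lmer"),
                            energy_threshold = 500) {
  engine <- match.arg(engine)
  pt <- data.table::as.data.table(participants)
  oz <- data.table::as.data.table(outcomes)
  excl <- exclude_low_energy(daily, energy_threshold)
  dd <- excl$retained
  counts <- c(days_in = nrow(data.table::as.data.table(daily)),
              days_low_energy = unname(excl$counts["excluded"]))
  lab <- label_plausibility(dd, pt)
  if (plausible_only) {
    mis <- participant_misreporter(lab)
    keep <- mis[misreporter == FALSE, participant_id]
    dd <- dd[participant_id %in% keep]
    pt <- pt[participant_id %in% keep]
  }
  pt <- pt[participant_id %in% unique(dd$participant_id)]
  counts <- c(counts, days_retained = nrow(dd), participants = nrow(pt))

  # participant covariate frame for prediction and Stage 3
  covs <- data.table::copy(pt)
  covs[, sleep_h := compute_sleep_duration(sleep_noct_we, sleep_nap_we,
                                           sleep_noct_wd, sleep_nap_wd)]
  oz_one <- oz[, .(participant_id, outcome_z = get(outcome))]
  covs <- oz_one[covs, on = "participant_id"]

  # Stage 1 (regression calibration) + Stage 2 (frozen patterns)
  fits_rc <- fit_usual_models(dd, pt, include_outcome = FALSE,
                              lambda_grid = lambda_grid)
  usual_rc <- predict_usual_table(fits_rc, covs)
  mtp_model <- fit_mtp(usual_rc, k = k, n_starts = n_starts,
                       seed = stage_seed(seed, 20L))

  # Stage 1 MI variant, conditioned on the outcome z-score
  covs_mi <- covs[!is.na(outcome_z)]
  fits_mi <- fit_usual_models(dd[participant_id %in% covs_mi$participant_id],
                              pt, include_outcome = TRUE,
                              outcome_z = oz_one, lambda_grid = lambda_grid)

  spec <- model_spec(outcome, model)
  base_frame <- merge(as.data.frame(covs_mi),
                      as.data.frame(usual_rc[, .(participant_id,
                                                 usual_energy, usual_healthy)]),
                      by = "participant_id")
  base_frame[[outcome]] <- base_frame$outcome_z

  est <- se2 <- list()
  failures <- 0L
  profiles <- usual_draw_profiles(fits_mi, covs_mi)
  for (m in seq_len(M)) {
    res <- tryCatch({
      drawn <- draw_usual_table(fits_mi, covs_mi, seed = stage_seed(seed, m),
                                draw_index = m, profiles = profiles)
      frame <- base_frame
      frame$mtp <- assign_mtp(mtp_model, drawn)
      # usual energy covariates follow the draw in the energy-adjusted models
      if (spec$model %in% c("energy_hfi", "fully_adjusted")) {
        frame$usual_energy <- drawn$usual_energy
        frame$usual_healthy <- drawn$usual_healthy
      }
      fit_lmm(frame, spec, engine = engine)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > max(1, ceiling(0.05 * M))) {
        stop("more than 5% of imputations failed; last error: ",
             conditionMessage(res))
      }
      next
    }
    cs <- res$contrasts
    for (j in seq_len(nrow(cs))) {
      trm <- cs$term[j]
      est[[trm]] <- c(est[[trm]], cs$estimate[j])
      se2[[trm]] <- c(se2[[trm]], cs$se[j]^2)
    }
  }
  mi <- lapply(names(est), function(trm) rubins_rule(est[[trm]], se2[[trm]]))
  names(mi) <- names(est)
  results <- do.call(rbind, lapply(names(mi), function(trm) {
    r <- mi[[trm]]
    data.frame(outcome = outcome, model = model, contrast = trm,
               reference = spec$reference, beta = r$beta,
               ci_lower = r$ci[1], ci_upper = r$ci[2],
               W = r$W, B = r$B, T = r$T, df = r$df, M = r$M)
  }))
  structure(list(results = results, mi = mi, mtp_model = mtp_model,
                 usual_rc = usual_rc, counts = counts, failures = failures,
                 spec = spec, seed = seed),
            class = "three_stage_result")
}

#' Naive single-day comparison analysis
#'
#' The uncorrected analysis the three-stage procedure improves on: each
#' participant's first retained recall day provides the exposures, patterns
#' are derived once by k-means on their z-scores, and the Stage-3 model is
#' fitted a single time. Subject to both measurement-error attenuation and
#' misclassification bias.
#'
#' @inheritParams run_three_stage
#' @return list with \code{fit} (an \code{lmm_fit}), \code{mtp_model} and
#'   the single-day exposure table.
#' @export
naive_association <- function(daily, participants, outcomes,
                              outcome = "homa_ir_z", seed = 1L,
                              model = "basic", k = 3, n_starts = 25,
                              engine = c("fast", "lmer"),
                              energy_threshold = 500) {
  engine <- match.arg(engine)
  dd <- exclude_low_energy(daily, energy_threshold)$retained
  data.table::setorder(dd, participant_id, recall_id)
  one <- dd[, .SD[1], by = participant_id]
  one <- one[!is.na(fasting_h)]
  one[, usual_energy := total_kcal]
  one[, usual_healthy := healthy_kcal]
  mtp_model <- fit_mtp(one, k = k, n_starts = n_starts,
                       seed = stage_seed(seed, 21L))
  pt <- data.table::as.data.table(participants)
  covs <- data.table::copy(pt)
  covs[, sleep_h := compute_sleep_duration(sleep_noct_we, sleep_nap_we,
                                           sleep_noct_wd, sleep_nap_wd)]
  frame <- merge(as.data.frame(covs),
                 as.data.frame(one[, c("participant_id", "usual_energy",
                                       "usual_healthy", exposure_names()),
                                   with = FALSE]),
                 by = "participant_id")
  frame <- merge(frame, as.data.frame(outcomes), by = "participant_id")
  frame$mtp <- assign_mtp(mtp_model, frame)
  spec <- model_spec(outcome, model)
  fit <- fit_lmm(frame, spec, engine = engine)
  list(fit = fit, mtp_model = mtp_model, single_day = one)
}
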