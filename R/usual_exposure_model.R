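# Stage 1: usual-exposure estimation.
#
# Every daily exposure component is modelled univariately ("amount-only"
# model: all components occur on every recall day, so no consumption-
# probability part is needed) with a Box-Cox transformed linear mixed model:
#
#   g_lambda(y_ij + shift) = x_ij' beta + u_i + eps_ij
#
# with a person random intercept u_i. Covariates: sex and sex-by-covariate
# interactions for age, ISCED and BMI z (the single-fit equivalent of
# sex-stratified fits), plus a weekend indicator, plus optionally the
# analysis outcome z-score (the multiple-imputation variant). lambda is
# chosen by profile maximum likelihood over a grid, ties broken toward 1.

boxcox_fwd <- function(y, lambda) {
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

boxcox_inv <- function(t, lambda) {
  if (lambda == 0) exp(t) else (lambda * t + 1)^(1 / lambda)
}

# second derivative of the inverse transform, for the back-transform
# bias correction E[g^-1(t + e)] ~ g^-1(t) + 0.5 g^-1''(t) var(e)
boxcox_inv_d2 <- function(t, lambda) {
  if (lambda == 0) exp(t)
  else (1 - lambda) * (lambda * t + 1)^(1 / lambda - 2)
}

error_model_design <- function(data, include_outcome) {
  # fixed factor codings so prediction designs align with the training fit
  data <- as.data.frame(data)
  data$sex <- factor(normalize_sex(data$sex), levels = c("female", "male"))
  data$isced <- factor(as.character(data$isced), levels = c("high", "low"))
  fml <- if (include_outcome) {
    ~ sex * (age + isced + bmi_z + outcome_z) + weekend
  } else {
    ~ sex * (age + isced + bmi_z) + weekend
  }
  model.matrix(fml, data = data)
}

#' Fit the measurement-error model for one daily exposure component
#'
#' Estimates the transformed random-intercept model by restricted maximum
#' likelihood, after selecting the Box-Cox parameter \eqn{\lambda} by
#' profile maximum likelihood over \code{lambda_grid} (Jacobian included;
#' ties broken toward 1, i.e. toward less transformation). Non-positive
#' values are accommodated by a recorded location shift.
#'
#' @param daily per-day exposure table (one row per participant-day) already
#'   joined with covariates, containing the modelled column plus
#'   \code{participant_id}, \code{weekend}, \code{sex}, \code{age},
#'   \code{isced}, \code{bmi_z} and, if \code{include_outcome},
#'   \code{outcome_z}.
#' @param component name of the column to model (e.g. \code{"window_h"} or
#'   \code{"morning_kcal"}).
#' @param include_outcome logical; condition the error model on the outcome
#'   z-score (the multiple-imputation variant).
#' @param lambda_grid candidate Box-Cox parameters; \code{lambda = 1} is a
#'   shifted identity.
#' @return An object of class \code{error_model_fit}: \code{lambda},
#'   \code{shift}, the REML \code{fit} (fixed effects, \eqn{\sigma_u^2},
#'   \eqn{\sigma_\epsilon^2}), per-person report summaries and the design
#'   metadata needed for prediction.
#' @export
fit_error_model <- function(daily, component, include_outcome = FALSE,
                            lambda_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  dt <- data.table::as.data.table(daily)
  if (!component %in% names(dt)) stop("no column `", component, "` in data")
  keep <- stats::complete.cases(
    dt[, c(component, "participant_id", "weekend", "sex", "age", "isced",
           "bmi_z", if (include_outcome) "outcome_z"), with = FALSE])
  dt <- dt[keep]
  nd <- table(dt$participant_id)
  if (sum(nd >= 2) < 2) {
    stop("need >= 2 participants with >= 2 recall days to separate within- ",
         "from between-person variance")
  }
  y_raw <- dt[[component]]
  shift <- if (min(y_raw) <= 0) -min(y_raw) + 0.1 * max(sd(y_raw), 1e-6) else 0
  y_pos <- y_raw + shift
  X <- error_model_design(dt, include_outcome)
  group <- dt$participant_id

  best <- NULL
  for (lam in sort(lambda_grid, decreasing = TRUE)) {  # ties go to larger lambda
    yt <- boxcox_fwd(y_pos, lam)
    fit_ml <- ri_fit(yt, X, group, reml = FALSE)
    ll <- -fit_ml$m2ll / 2 + (lam - 1) * sum(log(y_pos))
    if (is.null(best) || ll > best$ll + 1e-9) {
      best <- list(ll = ll, lambda = lam)
    }
  }
  lambda <- best$lambda
  yt <- boxcox_fwd(y_pos, lambda)
  fit <- ri_fit(yt, X, group, reml = TRUE)

  # per-person cached summaries on the transformed scale
  ord <- order(dt$participant_id)
  structure(list(
    component = component, lambda = lambda, shift = shift,
    include_outcome = include_outcome, fit = fit,
    profile_loglik = best$ll,
    n_days = fit$group_n, persons = fit$group_levels
  ), class = "error_model_fit")
}

# Person-level linear predictors for the weekday and weekend covariate
# profiles. `covariates` has one row per requested person.
person_profiles <- function(emfit, covariates) {
  cv <- data.table::as.data.table(covariates)
  need <- c("participant_id", "sex", "age", "isced", "bmi_z",
            if (emfit$include_outcome) "outcome_z")
  miss <- setdiff(need, names(cv))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  unknown <- setdiff(cv$participant_id, emfit$persons)
  if (length(unknown)) {
    stop("participants absent from the fitted error model: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  beta <- emfit$fit$beta
  mk <- function(wk) {
    cvx <- data.table::copy(cv); cvx$weekend <- wk
    X <- error_model_design(cvx, emfit$include_outcome)
    drop(X[, names(beta), drop = FALSE] %*% beta)
  }
  list(wd = mk(0L), we = mk(1L),
       ids = cv$participant_id,
       blup = ri_blup(emfit$fit, cv$participant_id),
       cond_var = ri_cond_var(emfit$fit, cv$participant_id))
}

# Back-transform a person-level transformed value into a usual amount with
# second-order bias correction for the within-day error.
usual_backtransform <- function(t_wd, t_we, emfit) {
  s2 <- emfit$fit$sigma2_e
  bt <- function(t) {
    arg <- if (emfit$lambda == 0) t else pmax(emfit$lambda * t + 1, 1e-8)
    tt <- if (emfit$lambda == 0) t else (arg - 1) / emfit$lambda
    boxcox_inv(tt, emfit$lambda) +
      0.5 * boxcox_inv_d2(tt, emfit$lambda) * s2 - emfit$shift
  }
  5 / 7 * bt(t_wd) + 2 / 7 * bt(t_we)
}

#' Regression-calibration prediction of usual exposure components
#'
#' Best linear unbiased prediction of each person's random effect on the
#' transformed scale (shrunken person-mean residual with shrinkage
#' \eqn{\sigma_u^2 / (\sigma_u^2 + \sigma_\epsilon^2 / n_i)}), added to the
#' person's covariate prediction, back-transformed with a second-order
#' Taylor bias correction for within-day error and combined over the week as
#' 5/7 weekday + 2/7 weekend.
#'
#' @param emfit an [fit_error_model()] result.
#' @param covariates one row per person (must appear in the fitted data).
#' @return numeric vector of usual amounts, one per row of
#'   \code{covariates}.
#' @export
predict_usual_rc <- function(emfit, covariates) {
  pp <- person_profiles(emfit, covariates)
  usual_backtransform(pp$wd + pp$blup, pp$we + pp$blup, emfit)
}

#' Conditional random draw of usual exposure components (MI variant)
#'
#' Draws each person's random effect from its conditional normal posterior
#' given the person's transformed reports and covariates (mean = BLUP,
#' variance = \eqn{(1/\sigma_u^2 + n_i/\sigma_\epsilon^2)^{-1}}), then
#' back-transforms exactly as [predict_usual_rc()]. With the error model
#' conditioned on the outcome this yields proper imputations of the usual
#' exposure for the three-stage procedure.
#'
#' @inheritParams predict_usual_rc
#' @param seed integer seed; identical seeds give identical draws.
#' @param require_outcome error unless the fit conditioned on the outcome
#'   (set \code{FALSE} for diagnostics).
#' @return numeric vector of drawn usual amounts.
#' @export
draw_usual_mi <- function(emfit, covariates, seed = NULL,
                          require_outcome = TRUE) {
  if (require_outcome && !emfit$include_outcome) {
    stop("error model was fitted without the outcome; ",
         "refit with include_outcome = TRUE for MI draws")
  }
  pp <- person_profiles(emfit, covariates)
  with_seed(seed, {
    u <- pp$blup + rnorm(length(pp$blup), 0, sqrt(pp$cond_var))
    usual_backtransform(pp$wd + u, pp$we + u, emfit)
  })
}

#' Usual energy proportion from usual window and total energy
#'
#' The usual proportion is the ratio of the usual window energy to the usual
#' total energy times 100, not the average of daily proportions.
#'
#' @param window_kcal usual energy in the clock window (kcal).
#' @param total_kcal usual total energy (kcal), must be positive.
#' @return percentage in \[0, 100\] (clamped after the ratio).
#' @export
usual_energy_proportion <- function(window_kcal, total_kcal) {
  if (any(total_kcal <= 0)) stop("total energy must be positive")
  pmin(pmax(100 * window_kcal / total_kcal, 0), 100)
}

usual_components <- function() {
  c("morning_kcal", "evening_kcal", "total_kcal", "healthy_kcal",
    "window_h", "fasting_h", "frequency")
}

#' Fit Stage-1 error models for all exposure components
#'
#' Fits [fit_error_model()] for the seven modelled components: morning,
#' evening, total and healthy energy (kcal scale), eating window, pre-sleep
#' fasting and eating frequency. Proportions are deliberately modelled on
#' the window-energy scale and converted to percentages only at prediction
#' time via [usual_energy_proportion()].
#'
#' @param daily per-day exposure table from [derive_daily_exposures()].
#' @param participants participant covariate table.
#' @param include_outcome,lambda_grid passed to [fit_error_model()].
#' @param outcome_z optional data.frame \code{participant_id, outcome_z}
#'   joined on when \code{include_outcome}.
#' @return named list of \code{error_model_fit}s, class
#'   \code{usual_model_set}.
#' @export
fit_usual_models <- function(daily, participants, include_outcome = FALSE,
                             outcome_z = NULL,
                             lambda_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  dt <- data.table::as.data.table(daily)
  pt <- data.table::as.data.table(participants)
  cols <- c("participant_id", "sex", "age", "isced", "bmi_z")
  dat <- pt[, cols, with = FALSE][dt, on = "participant_id"]
  if (include_outcome) {
    if (is.null(outcome_z)) stop("outcome_z required when include_outcome")
    oz <- data.table::as.data.table(outcome_z)
    dat <- oz[dat, on = "participant_id"]
    dat <- dat[!is.na(outcome_z)]
  }
  fits <- lapply(usual_components(), function(cmp)
    fit_error_model(dat, cmp, include_outcome, lambda_grid))
  names(fits) <- usual_components()
  structure(fits, class = "usual_model_set")
}

# Convert predicted/drawn usual components into the five usual exposures
# (plus usual total and healthy energy), enforcing natural-unit constraints.
components_to_exposures <- function(comp, ids, provenance) {
  out <- data.table::data.table(
    participant_id = ids,
    morning_pct = usual_energy_proportion(comp$morning_kcal, comp$total_kcal),
    evening_pct = usual_energy_proportion(comp$evening_kcal, comp$total_kcal),
    window_h = pmax(comp$window_h, 0.1),
    fasting_h = pmax(comp$fasting_h, 0.01),
    frequency = pmax(comp$frequency, 1),
    usual_energy = pmax(comp$total_kcal, 1),
    usual_healthy = pmax(comp$healthy_kcal, 0),
    provenance = provenance)
  out
}

#' Usual exposure table by regression calibration
#'
#' @param fits a \code{usual_model_set} from [fit_usual_models()].
#' @param covariates one row per person.
#' @return \code{data.table} of usual exposures on natural units with a
#'   \code{provenance} column.
#' @export
predict_usual_table <- function(fits, covariates) {
  ids <- covariates$participant_id
  comp <- lapply(fits, predict_usual_rc, covariates = covariates)
  components_to_exposures(comp, ids, "regression_calibration")
}

#' Usual exposure table from one conditional MI draw
#'
#' @inheritParams predict_usual_table
#' @param seed integer; component draws use deterministic sub-seeds.
#' @param draw_index recorded in the \code{provenance} column.
#' @param profiles optional cached result of [usual_draw_profiles()]; the
#'   per-person covariate profiles do not change across draws, so the MI
#'   loop computes them once.
#' @return \code{data.table} as [predict_usual_table()].
#' @export
draw_usual_table <- function(fits, covariates, seed, draw_index = 1L,
                             profiles = NULL) {
  ids <- covariates$participant_id
  if (is.null(profiles)) profiles <- usual_draw_profiles(fits, covariates)
  comp <- Map(function(f, pp, j) {
    with_seed(stage_seed(seed, 100L + j), {
      u <- pp$blup + rnorm(length(pp$blup), 0, sqrt(pp$cond_var))
      usual_backtransform(pp$wd + u, pp$we + u, f)
    })
  }, fits, profiles, seq_along(fits))
  names(comp) <- names(fits)
  components_to_exposures(comp, ids, sprintf("mi_draw_%03d", draw_index))
}

#' @rdname draw_usual_table
#' @export
usual_draw_profiles <- function(fits, covariates) {
  lapply(fits, person_profiles, covariates = covariates)
}
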