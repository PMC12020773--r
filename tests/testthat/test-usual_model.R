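test_that("error model recovers known variance components", {
  sim <- simulate_error_model(n = 500, d = 3, sigma_u = 1, sigma_e = 1, seed = 2)
  fit <- fit_error_model(sim$daily, "window_h", lambda_grid = 1)
  expect_lt(abs(fit$fit$sigma2_u - 1) / 1, 0.15)
  expect_lt(abs(fit$fit$sigma2_e - 1) / 1, 0.15)
  expect_equal(fit$lambda, 1)
})

test_that("zero within-person noise degenerates to the person mean", {
  sim <- simulate_error_model(n = 80, d = 3, sigma_u = 1, sigma_e = 0, seed = 3)
  fit <- fit_error_model(sim$daily, "window_h", lambda_grid = 1)
  expect_lt(fit$fit$sigma2_e, 1e-4)
  usual <- predict_usual_rc(fit, sim$covariates)
  # with no day noise and no weekend effect in the profile weighting beyond
  # the model's own estimate, the usual equals the fitted person value;
  # compare against the person mean of weekday-equivalent reports
  pm <- tapply(sim$daily$window_h - fit$fit$beta["weekend"] * sim$daily$weekend,
               sim$daily$participant_id, mean)
  wk <- fit$fit$beta["weekend"] * 2 / 7
  expect_equal(unname(usual),
               as.numeric(pm[sim$covariates$participant_id] + wk),
               tolerance = 1e-6)
})

test_that("profile likelihood selects the generating transform", {
  # lognormal-type data: identity-scale model is wrong, log (lambda = 0) right
  sim <- simulate_error_model(n = 300, d = 3, sigma_u = 0.5, sigma_e = 0.5,
                              seed = 4, mu = 3)
  sim$daily$window_h <- exp(sim$daily$window_h * 0.4)
  fit <- fit_error_model(sim$daily, "window_h")
  expect_lte(fit$lambda, 0.25)  # within one grid step of 0

  # gaussian data: lambda stays at 1 (ties broken toward identity)
  sim2 <- simulate_error_model(n = 300, d = 3, seed = 5)
  fit2 <- fit_error_model(sim2$daily, "window_h")
  expect_gte(fit2$lambda, 0.75)
})

test_that("identifiability requires repeated recalls", {
  sim <- simulate_error_model(n = 50, d = 1, seed = 6)
  expect_error(fit_error_model(sim$daily, "window_h"), ">= 2")
})

test_that("regression calibration is the closed-form shrinkage at lambda 1", {
  sim <- simulate_error_model(n = 200, d = 1, sigma_u = 1, sigma_e = 1, seed = 7)
  extra <- simulate_error_model(n = 200, d = 3, sigma_u = 1, sigma_e = 1,
                                seed = 8, id_prefix = "T")
  daily <- rbind(sim$daily, extra$daily)
  fit <- fit_error_model(daily, "window_h", lambda_grid = 1)
  one <- sim$covariates[1]
  usual <- predict_usual_rc(fit, one)
  # hand computation: population prediction + shrinkage * residual
  X <- chronomtp:::error_model_design(
    transform(as.data.frame(sim$daily[sim$daily$participant_id ==
                                        one$participant_id]), weekend = 0),
    FALSE)
  day <- sim$daily[sim$daily$participant_id == one$participant_id]
  pred_day <- drop(chronomtp:::error_model_design(as.data.frame(day), FALSE)
                   %*% fit$fit$beta)
  shrink <- fit$fit$sigma2_u / (fit$fit$sigma2_u + fit$fit$sigma2_e / 1)
  # lambda = 1 is the shifted identity (y - 1 on the model scale)
  u_hat <- shrink * ((day$window_h - 1) - pred_day)
  base_wd <- drop(X %*% fit$fit$beta)
  expected <- 5 / 7 * (base_wd + u_hat + 1) +
    2 / 7 * (base_wd + fit$fit$beta["weekend"] + u_hat + 1)
  expect_equal(unname(usual), unname(expected), tolerance = 1e-8)
})

test_that("shrinkage strengthens with fewer recall days", {
  fitobj <- fit_error_model(simulate_error_model(n = 300, d = 3, seed = 9)$daily,
                            "window_h", lambda_grid = 1)
  ng <- 1:4
  shrink <- fitobj$fit$theta * ng / (1 + fitobj$fit$theta * ng)
  expect_true(all(diff(shrink) > 0))        # more days -> less shrinkage
  cv <- fitobj$fit$sigma2_e * fitobj$fit$theta / (1 + ng * fitobj$fit$theta)
  expect_true(all(diff(cv) < 0))            # prediction variance non-increasing
})

test_that("MI draws are seeded and centred on the RC prediction", {
  sim <- simulate_error_model(n = 150, d = 2, sigma_u = 1, sigma_e = 0.8,
                              seed = 10)
  sim$daily$outcome_z <- rnorm(nrow(sim$daily))
  sim$covariates$outcome_z <- tapply(sim$daily$outcome_z,
                                     sim$daily$participant_id, mean)[
                                       sim$covariates$participant_id]
  fit <- fit_error_model(sim$daily, "window_h", include_outcome = TRUE,
                         lambda_grid = 1)
  d1 <- draw_usual_mi(fit, sim$covariates, seed = 5)
  d2 <- draw_usual_mi(fit, sim$covariates, seed = 5)
  d3 <- draw_usual_mi(fit, sim$covariates, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))

  rc <- predict_usual_rc(fit, sim$covariates[1])
  draws <- vapply(1:2000, function(s)
    draw_usual_mi(fit, sim$covariates[1], seed = s), numeric(1))
  mc_se <- sd(draws) / sqrt(2000)
  expect_lt(abs(mean(draws) - rc), 4 * mc_se + 1e-6)

  expect_error(draw_usual_mi(
    fit_error_model(sim$daily, "window_h", lambda_grid = 1),
    sim$covariates, seed = 1), "include_outcome")
})

test_that("draws degenerate to regression calibration without day noise", {
  sim <- simulate_error_model(n = 60, d = 2, sigma_u = 1, sigma_e = 0, seed = 11)
  fit <- fit_error_model(sim$daily, "window_h", lambda_grid = 1)
  rc <- predict_usual_rc(fit, sim$covariates)
  dr <- draw_usual_mi(fit, sim$covariates, seed = 2, require_outcome = FALSE)
  expect_equal(dr, rc, tolerance = 1e-3)
})

test_that("usual energy proportion is the guarded ratio times 100", {
  expect_equal(usual_energy_proportion(400, 1600), 25)
  expect_equal(usual_energy_proportion(1600, 1600), 100)
  expect_equal(usual_energy_proportion(0, 1600), 0)
  expect_error(usual_energy_proportion(10, 0), "positive")
})

test_that("variance decomposition and attenuation direction hold", {
  sim <- simulate_error_model(n = 400, d = 3, sigma_u = 1.3, sigma_e = 0.9,
                              seed = 12)
  fit <- fit_error_model(sim$daily, "window_h", lambda_grid = 1)
  # residualise days on the fixed effects, then compare total variance
  X <- chronomtp:::error_model_design(as.data.frame(sim$daily), FALSE)
  res <- sim$daily$window_h - drop(X %*% fit$fit$beta)
  expect_lt(abs((fit$fit$sigma2_u + fit$fit$sigma2_e) - var(res)) / var(res),
            0.10)

  truth <- sim$u
  usual <- predict_usual_rc(fit, sim$covariates)
  day1 <- sim$daily[!duplicated(sim$daily$participant_id)]
  expect_gt(cor(usual, truth), cor(day1$window_h, truth))
})

test_that("full model set predicts usual exposures for the cohort", {
  co <- small_cohort()
  ret <- exclude_low_energy(co$daily)$retained
  fits <- fit_usual_models(ret, co$participants, lambda_grid = c(0.5, 1))
  expect_named(fits, chronomtp:::usual_components())
  covs <- co$participants
  usual <- predict_usual_table(fits, covs)
  expect_equal(nrow(usual), nrow(covs))
  expect_true(all(usual$morning_pct >= 0 & usual$morning_pct <= 100))
  expect_true(all(usual$window_h > 0 & usual$frequency > 0))
  # usual exposures correlate strongly with the generating truth
  m <- merge(usual, co$true_exposures, by = "participant_id")
  expect_gt(cor(m$morning_pct.x, m$morning_pct.y), 0.55)
  expect_gt(cor(m$window_h.x, m$window_h.y), 0.55)
})
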