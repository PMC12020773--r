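test_that("outcome standardisation removes the age trend within sex", {
  withr::with_seed(1, {
    n <- 400
    age <- runif(n, 8, 15)
    sex <- sample(c("male", "female"), n, TRUE)
    raw <- 2 + 0.4 * age + 0.1 * (sex == "male") + rnorm(n)
    z <- standardize_outcome(raw, age, sex)
    for (s in c("male", "female")) {
      expect_equal(mean(z[sex == s]), 0, tolerance = 1e-9)
      expect_equal(sd(z[sex == s]), 1, tolerance = 1e-9)
    }
    expect_lt(abs(cor(z, age)), 0.05)
    # age-independent input: plain standardisation
    raw2 <- rnorm(n)
    z2 <- standardize_outcome(raw2, age, sex)
    for (s in c("male", "female")) {
      i <- sex == s
      expect_gt(cor(z2[i], (raw2[i] - mean(raw2[i])) / sd(raw2[i])), 0.99)
    }
    expect_error(standardize_outcome(raw[1:20], age[1:20], sex[1:20]),
                 "fewer than 30")
  })
})

test_that("HOMA-IR follows the insulin x glucose / 22.5 form", {
  expect_equal(compute_homa_ir(4.5, 10), 2.0)
  expect_equal(compute_homa_ir(4.5, 20), 2 * compute_homa_ir(4.5, 10))
  expect_error(compute_homa_ir(4.5, 0), "positive")
  expect_error(compute_homa_ir(-1, 10), "positive")
})

lmm_frame <- function(n = 600, contrast = c(0, 0.5), family_sd = 0.3,
                      seed = 1) {
  withr::with_seed(seed, {
    fam <- sample(sprintf("F%03d", 1:(n / 2)), n, TRUE)
    mtp <- sample(c("early-often", "late-long", "late-infrequent-short"), n,
                  TRUE)
    eff <- c(`early-often` = 0, `late-long` = contrast[1],
             `late-infrequent-short` = contrast[2])
    age <- runif(n, 8, 15)
    bmi <- rnorm(n)
    fameff <- rnorm(length(unique(fam)), 0, family_sd)
    names(fameff) <- unique(fam)
    data.frame(
      participant_id = sprintf("P%04d", 1:n), family_id = fam, mtp = mtp,
      age = age, bmi_z = bmi,
      isced = sample(c("low", "high"), n, TRUE),
      sex = sample(c("male", "female"), n, TRUE),
      country = sample(c("Italy", "Estonia", "Sweden"), n, TRUE),
      homa_ir_z = 0.05 * age + 0.1 * bmi + eff[mtp] + fameff[fam] + rnorm(n))
  })
}

test_that("fit_lmm matches OLS when family variance is absent", {
  d <- lmm_frame(family_sd = 0, seed = 2)
  d$family_id <- sprintf("F%04d", seq_len(nrow(d)))  # all singletons
  spec <- model_spec("homa_ir_z", "basic")
  fit <- fit_lmm(d, spec)
  ols <- lm(homa_ir_z ~ factor(mtp, levels = c("early-often",
                                               "late-infrequent-short",
                                               "late-long")) +
              age + bmi_z + isced + sex + country, data = d)
  expect_equal(unname(fit$contrasts$estimate),
               unname(coef(ols)[2:3]), tolerance = 1e-6)
})

test_that("fit_lmm engines agree and recover a known contrast", {
  d <- lmm_frame(n = 2000, contrast = c(0, 0.5), seed = 3)
  spec <- model_spec("homa_ir_z", "basic")
  fast <- fit_lmm(d, spec, engine = "fast")
  lmer <- fit_lmm(d, spec, engine = "lmer")
  expect_equal(fast$contrasts$estimate, lmer$contrasts$estimate,
               tolerance = 1e-5)
  expect_equal(fast$contrasts$se, lmer$contrasts$se, tolerance = 1e-4)
  lis <- fast$contrasts[fast$contrasts$term == "late-infrequent-short", ]
  expect_lt(abs(lis$estimate - 0.5), 3 * lis$se)
  # row order is irrelevant
  perm <- fit_lmm(d[sample(nrow(d)), ], spec)
  expect_equal(perm$contrasts$estimate, fast$contrasts$estimate,
               tolerance = 1e-6)
  expect_error(fit_lmm(transform(d, mtp = "late-long"), spec), "reference")
})

test_that("Rubin's rule reproduces the closed forms", {
  r <- rubins_rule(c(0.1, 0.3), c(0.01, 0.01))
  expect_equal(r$beta, 0.2)
  expect_equal(r$W, 0.01)
  expect_equal(r$B, 0.02)
  expect_equal(r$T, 0.01 + 1.5 * 0.02)
  expect_equal(r$df, (2 - 1) * (1 + 0.01 / (1.5 * 0.02))^2)

  r2 <- rubins_rule(rep(0.2, 5), rep(0.04, 5))
  expect_equal(r2$beta, 0.2)
  expect_equal(r2$B, 0)
  expect_equal(r2$T, 0.04)

  # translation equivariance
  est <- c(0.05, 0.12, 0.2, 0.01)
  v <- c(0.01, 0.02, 0.015, 0.012)
  r3 <- rubins_rule(est, v)
  r4 <- rubins_rule(est + 1, v)
  expect_equal(r4$beta, r3$beta + 1)
  expect_equal(r4$T, r3$T)
  expect_equal(r4$df, r3$df)

  expect_error(rubins_rule(1:3, 1:2), "equal length")
  expect_warning(r1 <- rubins_rule(0.2, 0.04), "M = 1")
  expect_equal(r1$T, 0.04)
})

test_that("three-stage run is seed-deterministic and pools coherently", {
  co <- small_cohort()
  ts1 <- run_three_stage(co$daily, co$participants, co$outcomes,
                         M = 8, seed = 5, n_starts = 5)
  ts2 <- run_three_stage(co$daily, co$participants, co$outcomes,
                         M = 8, seed = 5, n_starts = 5)
  expect_identical(ts1$results, ts2$results)
  expect_equal(ts1$failures, 0L)
  # Rubin identities hold for every pooled contrast
  for (r in ts1$mi) {
    expect_equal(r$T, r$W + (1 + 1 / r$M) * r$B, tolerance = 1e-12)
    if (r$B > 0) {
      expect_equal(r$df,
                   (r$M - 1) * (1 + r$W / ((1 + 1 / r$M) * r$B))^2,
                   tolerance = 1e-12)
    }
    expect_equal(mean(r$ci), r$beta, tolerance = 1e-12)
  }
  expect_s3_class(ts1$mtp_model, "mtp_model")
  expect_equal(sort(unique(ts1$results$contrast)),
               c("late-infrequent-short", "late-long"))
})

test_that("covariate-set models accept the extended adjustments", {
  co <- small_cohort()
  for (mdl in c("puberty", "energy_hfi", "fully_adjusted")) {
    ts <- run_three_stage(co$daily, co$participants, co$outcomes,
                          M = 3, seed = 6, model = mdl, n_starts = 3,
                          lambda_grid = 1)
    expect_equal(nrow(ts$results), 2)
    expect_true(all(is.finite(ts$results$beta)))
  }
})

test_that("plausible-only restriction drops misreporting participants", {
  co <- small_cohort()
  ts <- run_three_stage(co$daily, co$participants, co$outcomes,
                        M = 3, seed = 7, n_starts = 3, lambda_grid = 1,
                        plausible_only = TRUE)
  lab <- label_plausibility(exclude_low_energy(co$daily)$retained,
                            co$participants)
  mis <- chronomtp:::participant_misreporter(lab)
  expected <- mis[mis$misreporter == FALSE, ]$participant_id
  expect_setequal(ts$usual_rc$participant_id, expected)
  expect_lt(nrow(ts$usual_rc), nrow(co$participants))
})
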