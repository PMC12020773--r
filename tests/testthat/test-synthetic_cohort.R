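test_that("archetype and population specs validate their fields", {
  expect_error(archetype_spec("x", 1.2, rep(0, 5)), "mix_weight")
  expect_error(archetype_spec("x", 0.5, rep(0, 4)), "exposure_mean_z")
  expect_error(population_spec(n_participants = 1), "n_participants")
  expect_error(population_spec(recall_count_probs = c(0.5, 0.5, 0.5)),
               "recall_count_probs")
  expect_error(population_spec(exposure_sd = c(-1, 1, 1, 1, 1)), "SD")
  w <- default_archetypes()
  expect_equal(sum(vapply(w, `[[`, numeric(1), "mix_weight")), 1)
  bad <- w; bad[[1]]$mix_weight <- 0.9
  expect_error(generate_participants(population_spec(seed = 1), bad), "sum to 1")
})

test_that("participant generation is seeded, mixes archetypes, nests siblings", {
  spec <- population_spec(n_participants = 1000, seed = 99)
  p1 <- generate_participants(spec)
  p2 <- generate_participants(spec)
  expect_identical(p1, p2)
  expect_false(anyDuplicated(p1$participant_id) > 0)

  counts <- table(p1$archetype)
  w <- c(`early-often` = 791, `late-long` = 819,
         `late-infrequent-short` = 585) / 2195
  for (nm in names(w)) {
    expect_lt(abs(counts[[nm]] - 1000 * w[[nm]]),
              3 * sqrt(1000 * w[[nm]] * (1 - w[[nm]])))
  }
  # siblings share family id and country
  fam <- split(p1$country, p1$family_id)
  expect_true(all(vapply(fam, function(x) length(unique(x)) == 1, logical(1))))
  expect_gt(sum(table(p1$family_id) == 2), 0)
  p0 <- generate_participants(population_spec(n_participants = 100,
                                              sibling_rate = 0, seed = 1))
  expect_equal(anyDuplicated(p0$family_id), 0L)
  # the two "late" archetypes are older on average
  mage <- tapply(p1$age, p1$archetype, mean)
  expect_gt(mage[["late-long"]], mage[["early-often"]])
  expect_gt(mage[["late-infrequent-short"]], mage[["early-often"]])
})

test_that("true exposures place archetypes on the stated z positions", {
  spec <- population_spec(n_participants = 400, person_sd_z = 0, seed = 3)
  p <- generate_participants(spec)
  te <- generate_true_exposures(p, spec = spec)
  eo <- te[p$archetype == "early-often", ]
  # morning mean 25.5, SD 5.8, z = 0.83 -> 30.314 exactly (no person noise)
  expect_equal(unique(round(eo$morning_pct, 10)), 25.5 + 0.83 * 5.8)
  expect_equal(25.5 + 0.83 * 5.8, 30.314)

  # degenerate archetypes: everyone at the population mean
  flat <- lapply(default_archetypes(), function(a) {
    a$exposure_mean_z <- rep(0, 5); a
  })
  te0 <- generate_true_exposures(p, flat, spec)
  expect_equal(unique(round(te0$window_h, 10)), 11.5)

  # cluster-wise morning ordering: early-often > late-long > late-infreq.
  spec2 <- population_spec(n_participants = 900, seed = 4)
  p2 <- generate_participants(spec2)
  te2 <- generate_true_exposures(p2, spec = spec2)
  mm <- tapply(te2$morning_pct, p2$archetype, mean)
  expect_gt(mm[["early-often"]], mm[["late-long"]])
  expect_gt(mm[["late-long"]], mm[["late-infrequent-short"]])

  p2$archetype[1] <- "no-such-pattern"
  expect_error(generate_true_exposures(p2, spec = spec2), "unknown archetype")
})

test_that("recall counts follow the configured availability distribution", {
  spec <- population_spec(n_participants = 2000, seed = 12)
  co <- simulate_cohort(spec)
  n_rec <- table(table(co$days$participant_id))
  share1 <- n_rec[["1"]] / 2000
  expect_lt(abs(share1 - 0.494), 3 * sqrt(0.494 * 0.506 / 2000))
  share2 <- n_rec[["2"]] / 2000
  expect_lt(abs(share2 - 0.273), 3 * sqrt(0.273 * 0.727 / 2000))

  one <- population_spec(n_participants = 150, recall_count_probs = c(1, 0, 0),
                         seed = 13)
  co1 <- simulate_cohort(one)
  expect_true(all(table(co1$days$participant_id) == 1))
})

test_that("noiseless recall days round-trip through exposure derivation", {
  spec <- population_spec(n_participants = 120,
                          within_person_sd = rep(0, 5),
                          weekend_shift = rep(0, 5),
                          misreport_rate = 0, seed = 21)
  co <- simulate_cohort(spec)
  daily <- derive_daily_exposures(co$meals)
  m <- merge(daily, co$days, by = c("participant_id", "recall_id"))
  for (v in c("morning_pct", "evening_pct", "window_h", "fasting_h")) {
    expect_lt(max(abs(m[[paste0(v, ".x")]] - m[[paste0(v, ".y")]])), 1e-9)
  }
  expect_equal(m$frequency.x, m$frequency.y)
  # day targets equal the true exposures up to frequency rounding
  t2 <- merge(co$days, co$true_exposures, by = "participant_id")
  for (v in c("morning_pct", "evening_pct", "window_h", "fasting_h")) {
    expect_lt(max(abs(t2[[paste0(v, ".x")]] - t2[[paste0(v, ".y")]])), 1e-9)
  }
  expect_equal(t2$frequency.x, pmax(3, round(t2$frequency.y)))
})

test_that("generated exposure grand means track the target marginals", {
  spec <- population_spec(n_participants = 900, seed = 31)
  p <- generate_participants(spec)
  te <- generate_true_exposures(p, spec = spec)
  x <- as.matrix(as.data.frame(te)[, exposure_names()])
  target_mean <- spec$exposure_mean
  # model-implied SD: scale * sqrt(between-archetype var + person var)
  zmat <- do.call(rbind, lapply(default_archetypes(), `[[`, "exposure_mean_z"))
  wts <- vapply(default_archetypes(), `[[`, numeric(1), "mix_weight")
  vz <- colSums(wts * zmat^2) - colSums(wts * zmat)^2
  target_sd <- spec$exposure_sd * sqrt(vz + spec$person_sd_z^2)
  for (j in seq_len(5)) {
    se_mean <- target_sd[j] / sqrt(900)
    expect_lt(abs(mean(x[, j]) - target_mean[j]), 3.5 * se_mean)
    se_sd <- target_sd[j] / sqrt(2 * 900)
    expect_lt(abs(sd(x[, j]) - target_sd[j]), 3.5 * se_sd)
  }
})

test_that("outcome generation honours effects, family structure and seeds", {
  spec0 <- population_spec(n_participants = 200, family_sd = 0,
                           residual_sd = 0, age_effect = 0, bmi_effect = 0,
                           outcome_effects = list(homa_ir_z = c(0, 0)),
                           seed = 41)
  p0 <- generate_participants(spec0)
  o0 <- generate_outcomes(p0, spec0)
  expect_true(all(o0$homa_ir_z == 0))

  spec1 <- population_spec(n_participants = 4000, family_sd = 0,
                           residual_sd = 1, age_effect = 0, bmi_effect = 0,
                           outcome_effects = list(homa_ir_z = c(0, 0.5)),
                           seed = 42)
  p1 <- generate_participants(spec1)
  o1 <- generate_outcomes(p1, spec1)
  grp <- p1$archetype == "late-infrequent-short"
  expect_lt(abs(mean(o1$homa_ir_z[grp]) - 0.5), 3 / sqrt(sum(grp)))
  expect_lt(abs(mean(o1$homa_ir_z[p1$archetype == "early-often"])),
            3 / sqrt(sum(p1$archetype == "early-often")))

  # sibling correlation appears iff family_sd > 0
  sib_cor <- function(family_sd, seed) {
    sp <- population_spec(n_participants = 3000, sibling_rate = 0.9,
                          family_sd = family_sd, residual_sd = 1,
                          age_effect = 0, bmi_effect = 0,
                          outcome_effects = list(homa_ir_z = c(0, 0)),
                          seed = seed)
    pp <- generate_participants(sp)
    oo <- generate_outcomes(pp, sp)
    fam <- split(oo$homa_ir_z, pp$family_id)
    pairs <- do.call(rbind, fam[lengths(fam) == 2])
    cor(pairs[, 1], pairs[, 2])
  }
  expect_gt(sib_cor(1, 43), 0.3)   # ICC 0.5 at family_sd = residual_sd = 1
  expect_lt(abs(sib_cor(0, 44)), 0.1)
})
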