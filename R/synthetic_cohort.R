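#' Meal-timing pattern archetypes
#'
#' The three latent archetypes used by the synthetic cohort generator, each
#' defined by a mixing weight and a 5-vector of cluster-mean z-scores on the
#' exposure axes (morning energy \%, evening energy \%, eating window h,
#' pre-sleep fasting h, eating frequency). The defaults reproduce the
#' signature of the three observed patterns: "early-often" (front-loaded
#' energy, frequent eating, short pre-sleep fast), "late-long" (evening-
#' shifted energy, longest window) and "late-infrequent-short"
#' (evening-shifted, few occasions, short window, long pre-sleep fast).
#'
#' @param name pattern label.
#' @param mix_weight mixing proportion in (0, 1); weights over a list of
#'   archetypes must sum to 1.
#' @param exposure_mean_z numeric 5-vector of cluster-mean z-scores, each in
#'   \[-3, 3\].
#' @return An object of class \code{archetype_spec}.
#' @export
archetype_spec <- function(name, mix_weight, exposure_mean_z) {
  stopifnot_named(is.character(name) && nchar(name) > 0, "name", "non-empty string")
  stopifnot_named(is.numeric(mix_weight) && mix_weight > 0 && mix_weight < 1,
                  "mix_weight", "must lie in (0, 1)")
  stopifnot_named(length(exposure_mean_z) == 5 && all(abs(exposure_mean_z) <= 3),
                  "exposure_mean_z", "must be 5 values in [-3, 3]")
  structure(list(name = name, mix_weight = mix_weight,
                 exposure_mean_z = setNames(as.numeric(exposure_mean_z),
                                            exposure_names())),
            class = "archetype_spec")
}

#' @rdname archetype_spec
#' @export
default_archetypes <- function() {
  list(
    archetype_spec("early-often", 791 / 2195,
                   c(0.83, -0.54, 0.17, -0.66, 0.64)),
    archetype_spec("late-long", 819 / 2195,
                   c(-0.42, 0.23, 0.53, 0.00, 0.08)),
    archetype_spec("late-infrequent-short", 585 / 2195,
                   c(-0.53, 0.41, -0.98, 0.89, -0.98))
  )
}

#' @rdname archetype_spec
#' @export
exposure_names <- function() {
  c("morning_pct", "evening_pct", "window_h", "fasting_h", "frequency")
}

check_archetypes <- function(archetypes) {
  if (!length(archetypes)) stop("need at least one archetype")
  w <- vapply(archetypes, `[[`, numeric(1), "mix_weight")
  if (abs(sum(w) - 1) > 1e-6) stop("invalid `mix_weight`: weights must sum to 1")
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("archetype names must be unique")
  invisible(archetypes)
}

#' Population specification for the synthetic cohort
#'
#' Bundles every tunable of the generator. Defaults emulate the marginal
#' structure of a multi-country child cohort of 8-15 year olds: exposure
#' means/SDs (morning 25.5 (5.8) \%, evening 35.8 (4.3) \%, window 11.5
#' (0.6) h, fasting 2.5 (0.4) h, frequency 4.16 (0.4)), repeated-recall
#' availability (49.4\% one recall, 27.3\% two, 23.3\% three or more), a
#' 20\% rate of low-energy misreported days, sibling clustering and
#' outcome contrasts of the magnitude seen in the source cohort
#' (HOMA-IR z: +0.06 late-long, +0.19 late-infrequent-short vs early-often).
#'
#' @param n_participants number of children (>= 2).
#' @param sibling_rate proportion of participants who share a family with a
#'   sibling (families of two).
#' @param exposure_mean,exposure_sd numeric 5-vectors, natural units, in the
#'   order of [exposure_names()].
#' @param person_sd_z SD of person-level deviations around the archetype mean
#'   on the z-score scale (controls archetype separation).
#' @param within_person_sd day-to-day error SDs, natural units (5-vector).
#' @param recall_count_probs probabilities of 1, 2, >= 3 recalls; must sum to 1.
#' @param misreport_rate fraction of recall days generated as low-energy
#'   misreports (EI/BMR below the Goldberg lower cutoff).
#' @param energy_ratio_mean,energy_between_sd,energy_within_sd the EI/BMR
#'   ratio of plausibly reported days: person-level usual ratio
#'   \eqn{r_i \sim N(mean, between^2)} and day-level noise with SD
#'   \code{energy_within_sd}, both kept inside the Goldberg interval by
#'   resampling so that only injected misreports are flagged.
#' @param weekend_shift additive shift applied to the five exposure targets
#'   on weekend days (default: energy shifted from morning to evening,
#'   emulating a later first meal).
#' @param outcome_effects named list; per outcome a length-2 vector of MTP
#'   contrast effects (late-long, late-infrequent-short) vs "early-often".
#' @param age_effect,bmi_effect confounder effects on every outcome z-score
#'   (archetypes differ in age and BMI, so adjustment matters).
#' @param family_sd,residual_sd SD of the family random intercept and of the
#'   residual in the outcome model.
#' @param age_by_archetype,age_sd_by_archetype,bmi_by_archetype means/SDs of
#'   age and BMI z per archetype (older, heavier children in the two "late"
#'   patterns by default).
#' @param healthy_share probability an eating occasion is flagged healthy.
#' @param seed integer seed; all generator functions are deterministic given
#'   the spec (the seed lives in the spec so one object states the world).
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(n_participants = 1000,
                            sibling_rate = 0.3,
                            exposure_mean = c(25.5, 35.8, 11.5, 2.5, 4.16),
                            exposure_sd = c(5.8, 4.3, 0.6, 0.4, 0.4),
                            person_sd_z = 0.45,
                            within_person_sd = 0.75 * exposure_sd,
                            recall_count_probs = c(0.494, 0.273, 0.233),
                            misreport_rate = 0.20,
                            energy_ratio_mean = 1.18,
                            energy_between_sd = 0.12,
                            energy_within_sd = 0.15,
                            weekend_shift = c(-2, 2, 0, 0, 0),
                            outcome_effects = list(
                              homa_ir_z = c(0.06, 0.19),
                              hba1c_z = c(-0.02, -0.02),
                              triglycerides_z = c(0.02, 0.05)),
                            age_effect = 0.05,
                            bmi_effect = 0.15,
                            family_sd = 0.3,
                            residual_sd = 1.0,
                            age_by_archetype = c(10.5, 12.27, 12.7),
                            age_sd_by_archetype = c(1.4, 1.6, 1.5),
                            bmi_by_archetype = c(0.25, 0.66, 0.95),
                            healthy_share = 0.30,
                            seed = 20240301) {
  stopifnot_named(n_participants >= 2, "n_participants", "must be >= 2")
  stopifnot_named(abs(sum(recall_count_probs) - 1) < 1e-8,
                  "recall_count_probs", "must sum to 1")
  stopifnot_named(all(recall_count_probs >= 0), "recall_count_probs",
                  "must be non-negative")
  stopifnot_named(all(exposure_sd >= 0) && all(within_person_sd >= 0) &&
                    family_sd >= 0 && residual_sd >= 0 && person_sd_z >= 0,
                  "sd", "all SDs must be >= 0")
  stopifnot_named(length(exposure_mean) == 5 && length(exposure_sd) == 5 &&
                    length(within_person_sd) == 5 && length(weekend_shift) == 5,
                  "exposure vectors", "must have 5 entries")
  stopifnot_named(sibling_rate >= 0 && sibling_rate <= 1, "sibling_rate",
                  "must lie in [0, 1]")
  stopifnot_named(misreport_rate >= 0 && misreport_rate < 1, "misreport_rate",
                  "must lie in [0, 1)")
  stopifnot_named(is.numeric(seed) && length(seed) == 1 && !is.na(seed),
                  "seed", "must be a single integer")
  spec <- list(
    n_participants = as.integer(n_participants), sibling_rate = sibling_rate,
    exposure_mean = setNames(exposure_mean, exposure_names()),
    exposure_sd = setNames(exposure_sd, exposure_names()),
    person_sd_z = person_sd_z,
    within_person_sd = setNames(within_person_sd, exposure_names()),
    recall_count_probs = recall_count_probs,
    misreport_rate = misreport_rate,
    energy_ratio_mean = energy_ratio_mean,
    energy_between_sd = energy_between_sd,
    energy_within_sd = energy_within_sd,
    weekend_shift = setNames(weekend_shift, exposure_names()),
    outcome_effects = outcome_effects,
    age_effect = age_effect, bmi_effect = bmi_effect,
    family_sd = family_sd, residual_sd = residual_sd,
    age_by_archetype = age_by_archetype,
    age_sd_by_archetype = age_sd_by_archetype,
    bmi_by_archetype = bmi_by_archetype,
    healthy_share = healthy_share,
    seed = as.integer(seed))
  structure(spec, class = "population_spec")
}

country_table <- function() {
  # marginal country frequencies of the emulated cohort
  c(Italy = 587, Estonia = 549, Cyprus = 171, Belgium = 176, Sweden = 233,
    Germany = 289, Hungary = 87, Spain = 103) / 2195
}

#' Generate the participant table
#'
#' Draws participants with family structure (a \code{sibling_rate} fraction
#' paired into two-child families sharing family id, country and parental
#' education), latent archetype labels from the mixing weights, and
#' covariates whose distribution depends on the archetype (the two "late"
#' patterns are older and have higher BMI z, mirroring the emulated cohort).
#'
#' @param spec a [population_spec()].
#' @param archetypes list of [archetype_spec()]s (default three patterns).
#' @return \code{data.table} with one row per participant: ids, family id,
#'   age, sex, country, ISCED, BMI z, puberty flag, weight, sleep components
#'   and the latent \code{archetype} label.
#' @export
generate_participants <- function(spec, archetypes = default_archetypes()) {
  check_archetypes(archetypes)
  n <- spec$n_participants
  with_seed(stage_seed(spec$seed, 1L), {
    # family structure: paired siblings then singletons
    n_sib <- 2L * floor(spec$sibling_rate * n / 2)
    fam_pair <- rep(seq_len(n_sib / 2), each = 2)
    fam_single <- if (n > n_sib) (n_sib / 2) + seq_len(n - n_sib) else integer(0)
    family_id <- sprintf("F%05d", c(fam_pair, fam_single))
    n_fam <- length(unique(family_id))

    w <- vapply(archetypes, `[[`, numeric(1), "mix_weight")
    nm <- vapply(archetypes, `[[`, character(1), "name")
    arch_idx <- sample.int(length(w), n, replace = TRUE, prob = w)

    ctab <- country_table()
    fam_country <- sample(names(ctab), n_fam, replace = TRUE, prob = ctab)
    fam_isced <- sample(c("low", "high"), n_fam, replace = TRUE,
                        prob = c(0.49, 0.51))
    fam_key <- as.integer(factor(family_id, levels = unique(family_id)))

    age <- rnorm_bounded(n, spec$age_by_archetype[arch_idx],
                         spec$age_sd_by_archetype[arch_idx], lo = 8, hi = 15)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    bmi_z <- rnorm_bounded(n, spec$bmi_by_archetype[arch_idx], 1.1,
                           lo = -4, hi = 5)
    weight <- rnorm_bounded(n, 4.1 * age - 5, 5, lo = 18, hi = 120)
    puberty <- rbinom(n, 1, stats::plogis(age - 11.9))
    sleep_noct_wd <- rnorm_bounded(n, 9.3, 0.8, lo = 5, hi = 13)
    sleep_noct_we <- rnorm_bounded(n, 9.6, 0.9, lo = 5, hi = 14)
    sleep_nap_wd <- pmax(0, rnorm(n, 0, 0.15))
    sleep_nap_we <- pmax(0, rnorm(n, 0.1, 0.25))

    data.table::data.table(
      participant_id = sprintf("P%05d", seq_len(n)),
      family_id = family_id,
      age = age, sex = sex,
      country = fam_country[fam_key],
      isced = fam_isced[fam_key],
      bmi_z = bmi_z, puberty = puberty, weight_kg = weight,
      sleep_noct_wd = sleep_noct_wd, sleep_nap_wd = sleep_nap_wd,
      sleep_noct_we = sleep_noct_we, sleep_nap_we = sleep_nap_we,
      archetype = nm[arch_idx])
  })
}

#' Generate true (usual) exposures from archetype membership
#'
#' Each participant's true usual exposure vector is the population mean plus
#' the archetype mean z-score times the population SD plus person-level
#' Gaussian noise with SD \code{person_sd_z} on the z-scale. Natural-unit
#' constraints (proportions in \[0, 100\] with morning + evening <= 100,
#' positive window/fasting/frequency) are enforced by resampling, never by
#' truncation, to avoid point masses at the bounds.
#'
#' @param participants table from [generate_participants()].
#' @param archetypes list of [archetype_spec()]s.
#' @param spec a [population_spec()].
#' @return \code{data.table}: participant id plus the five true exposures.
#' @export
generate_true_exposures <- function(participants,
                                    archetypes = default_archetypes(),
                                    spec) {
  check_archetypes(archetypes)
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (!all(participants$archetype %in% nm)) {
    stop("unknown archetype label: ",
         paste(setdiff(unique(participants$archetype), nm), collapse = ", "))
  }
  zmat <- do.call(rbind, lapply(archetypes, `[[`, "exposure_mean_z"))
  rownames(zmat) <- nm
  n <- nrow(participants)
  mu <- spec$exposure_mean; sdv <- spec$exposure_sd
  with_seed(stage_seed(spec$seed, 2L), {
    z_centre <- zmat[participants$archetype, , drop = FALSE]
    draw <- function() {
      eps <- matrix(rnorm(n * 5, 0, spec$person_sd_z), n, 5)
      sweep(sweep(z_centre + eps, 2, sdv, `*`), 2, mu, `+`)
    }
    x <- draw()
    ok <- function(x) {
      x[, 1] >= 0 & x[, 1] <= 100 & x[, 2] >= 0 & x[, 2] <= 100 &
        (x[, 1] + x[, 2]) <= 100 & x[, 3] >= 6.2 & x[, 3] <= 18.8 &
        x[, 4] >= 0.25 & x[, 4] <= 8 & x[, 5] >= 2.5
    }
    bad <- which(!ok(x)); tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > 1000L) stop("resampling cap reached for true exposures")
      x2 <- draw()
      x[bad, ] <- x2[bad, ]
      bad <- which(!ok(x))
    }
    out <- data.table::data.table(participant_id = participants$participant_id)
    for (j in seq_len(5)) out[[exposure_names()[j]]] <- x[, j]
    out
  })
}

# Build one recall day's occasion times and energies so the derived
# exposures reproduce the day targets exactly. Returns NULL when the
# geometry is infeasible (caller resamples the day).
build_day <- function(m_pct, e_pct, window_h, fasting_h, freq, total_kcal,
                      healthy_share) {
  lo_t1 <- max(300, 1020 - 60 * window_h)
  hi_t1 <- min(659, 1439 - 60 * window_h)
  if (lo_t1 >= hi_t1) return(NULL)
  t1 <- rnorm_bounded(1, min(max(498, lo_t1 + 1), hi_t1 - 1),
                      25, lo = lo_t1, hi = hi_t1)
  tL <- t1 + 60 * window_h
  k <- as.integer(freq)
  mid_lo <- max(t1 + 20, 661)
  mid_hi <- min(tL - 20, 1019)
  mids <- if (k > 2L) {
    if (mid_lo < mid_hi) sort(runif(k - 2L, mid_lo, mid_hi))
    else sort(runif(k - 2L, t1 + 1, tL - 1))
  } else numeric(0)
  times <- c(t1, mids, tL)
  in_morning <- times >= 300 & times < 660
  in_evening <- times >= 1020 & times < 1440
  in_mid <- !in_morning & !in_evening
  e_m <- total_kcal * m_pct / 100
  e_e <- total_kcal * e_pct / 100
  e_mid <- total_kcal - e_m - e_e
  if ((e_m > 0 && !any(in_morning)) || (e_e > 0 && !any(in_evening)) ||
      (e_mid > 1e-9 && !any(in_mid))) return(NULL)
  energy <- numeric(length(times))
  split_into <- function(total, idx) {
    if (!length(idx)) return()
    w <- runif(length(idx), 0.5, 1.5)
    energy[idx] <<- total * w / sum(w)
  }
  split_into(e_m, which(in_morning))
  split_into(e_e, which(in_evening))
  split_into(e_mid, which(in_mid))
  list(time_min = times, energy_kcal = energy,
       healthy = rbinom(length(times), 1, healthy_share),
       wake_min = t1 - runif(1, 15, 60),
       bed_min = tL + 60 * fasting_h)
}

#' Generate meal-level recall records
#'
#' The number of recall days per participant follows
#' \code{recall_count_probs} (the ">= 3" class is realised as 3 days). Each
#' day's exposure targets are the participant's true exposures plus
#' day-to-day Gaussian error (\code{within_person_sd}); weekend days (drawn
#' with probability 2/7) additionally receive \code{weekend_shift}. Occasion
#' times and energies are then solved so the day's derived exposures equal
#' the targets exactly: first occasion in the morning window, last occasion
#' in the evening window, energy split across window membership. A
#' \code{misreport_rate} fraction of days scales total energy below the
#' Goldberg lower cutoff (proportions are unaffected by the rescaling).
#' Infeasible geometry is resampled up to a retry cap, then errors.
#'
#' @param participants table from [generate_participants()].
#' @param true_exposures table from [generate_true_exposures()].
#' @param spec a [population_spec()].
#' @return list with \code{meals} (one row per eating occasion:
#'   \code{participant_id, recall_id, weekend, time_min, energy_kcal,
#'   healthy, wake_min, bed_min}) and \code{days} (one row per recall day
#'   with the realised exposure targets and the misreport flag).
#' @export
generate_recalls <- function(participants, true_exposures, spec) {
  if (!all(participants$participant_id %in% true_exposures$participant_id)) {
    stop("true exposures missing for some participants")
  }
  te <- data.table::as.data.table(true_exposures)
  data.table::setkey(te, participant_id)
  wsd <- spec$within_person_sd
  with_seed(stage_seed(spec$seed, 3L), {
    n <- nrow(participants)
    n_rec <- sample.int(3L, n, replace = TRUE, prob = spec$recall_count_probs)
    bmr <- compute_bmr(participants$age, participants$sex,
                       participants$weight_kg)
    meals_list <- vector("list", sum(n_rec))
    days_list <- vector("list", sum(n_rec))
    row <- 0L
    for (i in seq_len(n)) {
      pid <- participants$participant_id[i]
      tru <- as.numeric(te[pid, exposure_names(), with = FALSE])
      # person-level usual EI/BMR ratio; day noise is within-person error
      r_i <- rnorm_bounded(1, spec$energy_ratio_mean, spec$energy_between_sd,
                           lo = 1.09, hi = 2.20)
      for (d in seq_len(n_rec[i])) {
        row <- row + 1L
        weekend <- rbinom(1, 1, 2 / 7)
        misreport <- rbinom(1, 1, spec$misreport_rate)
        built <- NULL
        for (try in 1:50) {
          tgt <- tru + weekend * spec$weekend_shift + rnorm(5, 0, wsd)
          tgt[1] <- max(tgt[1], 0); tgt[2] <- max(tgt[2], 0)
          if (tgt[1] + tgt[2] > 100) next
          if (tgt[3] < 6.2 || tgt[3] > 18.8) next
          if (tgt[4] < 0.1) next
          k <- max(3L, as.integer(round(tgt[5])))
          tgt[5] <- k
          ratio <- if (misreport) runif(1, 0.55, 1.0) else
            rnorm_bounded(1, r_i, spec$energy_within_sd, lo = 1.07, hi = 2.25)
          total <- ratio * bmr[i]
          built <- build_day(tgt[1], tgt[2], tgt[3], tgt[4], k, total,
                             spec$healthy_share)
          if (!is.null(built)) break
        }
        if (is.null(built)) stop("retry cap reached building a recall day for ", pid)
        recall_id <- paste0(pid, "_R", d)
        meals_list[[row]] <- data.table::data.table(
          participant_id = pid, recall_id = recall_id, weekend = weekend,
          time_min = built$time_min, energy_kcal = built$energy_kcal,
          healthy = built$healthy, wake_min = built$wake_min,
          bed_min = built$bed_min)
        days_list[[row]] <- data.table::data.table(
          participant_id = pid, recall_id = recall_id, weekend = weekend,
          misreport = misreport, total_kcal = total,
          morning_pct = tgt[1], evening_pct = tgt[2], window_h = tgt[3],
          fasting_h = tgt[4], frequency = tgt[5])
      }
    }
    list(meals = data.table::rbindlist(meals_list),
         days = data.table::rbindlist(days_list))
  })
}

#' Generate metabolic outcome z-scores
#'
#' Outcome z-score = confounder effects (age, BMI z, centred at the
#' population values) + archetype contrast effect vs "early-often" + family
#' random intercept + residual. Default contrasts follow the emulated
#' cohort: HOMA-IR z (+0.06, +0.19), HbA1c z (-0.02, -0.02), triglycerides z
#' (+0.02, +0.05) for (late-long, late-infrequent-short).
#'
#' @param participants table from [generate_participants()].
#' @param spec a [population_spec()].
#' @param archetypes list of [archetype_spec()]s; contrast effects are
#'   matched positionally to archetypes 2..k (archetype 1 is the reference).
#' @return \code{data.table}: participant id plus one z-score column per
#'   outcome named in \code{spec$outcome_effects}.
#' @export
generate_outcomes <- function(participants, spec,
                              archetypes = default_archetypes()) {
  nm <- vapply(archetypes, `[[`, character(1), "name")
  with_seed(stage_seed(spec$seed, 4L), {
    n <- nrow(participants)
    fam <- factor(participants$family_id)
    fam_eff <- rnorm(nlevels(fam), 0, spec$family_sd)[fam]
    base <- spec$age_effect * (participants$age - 11.75) +
      spec$bmi_effect * (participants$bmi_z - 0.59)
    out <- data.table::data.table(participant_id = participants$participant_id)
    for (oc in names(spec$outcome_effects)) {
      eff <- c(0, spec$outcome_effects[[oc]])
      names(eff) <- nm[seq_along(eff)]
      out[[oc]] <- base + unname(eff[participants$archetype]) + fam_eff +
        rnorm(n, 0, spec$residual_sd)
    }
    out
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_participants()],
#' [generate_true_exposures()], [generate_recalls()] and
#' [generate_outcomes()] under one spec.
#'
#' @inheritParams generate_participants
#' @return list with \code{participants}, \code{true_exposures},
#'   \code{meals}, \code{days} and \code{outcomes} tables.
#' @export
simulate_cohort <- function(spec, archetypes = default_archetypes()) {
  participants <- generate_participants(spec, archetypes)
  true_exposures <- generate_true_exposures(participants, archetypes, spec)
  rec <- generate_recalls(participants, true_exposures, spec)
  outcomes <- generate_outcomes(participants, spec, archetypes)
  list(participants = participants, true_exposures = true_exposures,
       meals = rec$meals, days = rec$days, outcomes = outcomes)
}
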