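#' Derive daily meal-timing exposures from meal-level recall records
#'
#' Each 24-hour dietary recall day is reduced to the five meal-timing
#' exposures used throughout the package: the energy proportion consumed
#' between 05:00 and 11:00 (morning, \%), the proportion between 17:00 and
#' midnight (evening, \%), the eating window (hours between first and last
#' occasion), the pre-sleep fasting time (hours between last occasion and
#' bedtime) and the eating frequency (number of occasions), together with
#' total / healthy / unhealthy energy.
#'
#' Clock windows are half-open, \code{[05:00, 11:00)} and \code{[17:00,
#' 24:00)}, so an occasion at exactly 11:00 contributes nothing to the
#' morning window and occasions timestamped past midnight (>= 1440 min) fall
#' outside both windows unless \code{post_midnight_evening = TRUE}, in which
#' case intake up to 05:00 the next day is counted as evening intake.
#'
#' If bedtime precedes the last occasion, pre-sleep fasting would be
#' negative; the day keeps a \code{fasting_flag} and fasting is reported as
#' \code{NA} rather than clipped.
#'
#' @param meals data.frame/data.table of meal-level records with columns
#'   \code{participant_id}, \code{recall_id}, \code{weekend} (0/1),
#'   \code{time_min} (minutes since midnight, may exceed 1440),
#'   \code{energy_kcal} (>= 0), \code{healthy} (0/1), \code{wake_min},
#'   \code{bed_min} (may be \code{NA}).
#' @param merge_gap occasions closer than this many minutes are merged into
#'   one eating occasion before counting frequency (default 0 = no merging).
#' @param post_midnight_evening logical; count intake in \code{[24:00,
#'   29:00)} as evening intake (default \code{FALSE}).
#' @return A \code{data.table} with one row per (participant, recall) day:
#'   energy aggregates, the five exposures, \code{weekend} and a
#'   \code{fasting_flag}.
#' @export
derive_daily_exposures <- function(meals, merge_gap = 0,
                                   post_midnight_evening = FALSE) {
  dt <- data.table::as.data.table(meals)
  req <- c("participant_id", "recall_id", "time_min", "energy_kcal")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) stop("no eating occasions supplied")
  if (any(dt$energy_kcal < 0)) stop("negative occasion energy")
  if (!"healthy" %in% names(dt)) dt[, healthy := 0L]
  if (!"weekend" %in% names(dt)) dt[, weekend := 0L]
  if (!"bed_min" %in% names(dt)) dt[, bed_min := NA_real_]
  data.table::setorder(dt, participant_id, recall_id, time_min)

  one_day <- function(time_min, energy, healthy, bed, weekend) {
    total <- sum(energy)
    morning <- sum(energy[time_min >= 300 & time_min < 660])
    evening <- sum(energy[time_min >= 1020 & time_min < 1440])
    if (post_midnight_evening) {
      evening <- evening + sum(energy[time_min >= 1440 & time_min < 1740])
    }
    n_occ <- if (merge_gap > 0 && length(time_min) > 1L) {
      1L + sum(diff(time_min) >= merge_gap)
    } else length(time_min)
    last <- max(time_min)
    bed1 <- bed[1]
    fast <- if (is.na(bed1)) NA_real_ else (bed1 - last) / 60
    flag <- !is.na(fast) && fast < 0
    if (flag) fast <- NA_real_
    list(
      total_kcal = total,
      healthy_kcal = sum(energy[healthy > 0]),
      unhealthy_kcal = sum(energy[healthy <= 0]),
      morning_kcal = morning,
      evening_kcal = evening,
      morning_pct = if (total > 0) 100 * morning / total else 0,
      evening_pct = if (total > 0) 100 * evening / total else 0,
      window_h = (last - min(time_min)) / 60,
      fasting_h = fast,
      frequency = n_occ,
      weekend = as.integer(weekend[1]),
      fasting_flag = flag
    )
  }
  out <- dt[, one_day(time_min, energy_kcal, healthy, bed_min, weekend),
            by = .(participant_id, recall_id)]
  out[]
}

#' Apply the low-energy exclusion rule to recall days
#'
#' Recall days reporting less than 500 kcal total energy intake are excluded
#' from analysis (strictly below: a 500 kcal day is retained).
#'
#' @param daily per-day exposure table from [derive_daily_exposures()].
#' @param threshold exclusion threshold in kcal (default 500).
#' @return list with elements \code{retained} and \code{excluded}
#'   (data.tables) and integer \code{counts}.
#' @export
exclude_low_energy <- function(daily, threshold = 500) {
  dt <- data.table::as.data.table(daily)
  drop <- dt$total_kcal < threshold
  list(retained = dt[!drop], excluded = dt[drop],
       counts = c(retained = sum(!drop), excluded = sum(drop)))
}

#' Total daily sleep duration from weekday/weekend components
#'
#' Weighted average of weekend and weekday sleep,
#' \deqn{2/7\,(noct_{WE} + nap_{WE}) + 5/7\,(noct_{WD} + nap_{WD}),}
#' i.e. two weekend days and five weekdays per week.
#'
#' @param nocturnal_we,nap_we,nocturnal_wd,nap_wd sleep components in hours,
#'   all non-negative; vectors are recycled element-wise.
#' @return Hours of sleep per day.
#' @export
compute_sleep_duration <- function(nocturnal_we, nap_we, nocturnal_wd, nap_wd) {
  comps <- cbind(nocturnal_we, nap_we, nocturnal_wd, nap_wd)
  if (any(comps < 0, na.rm = TRUE)) stop("sleep components must be >= 0")
  2 / 7 * (nocturnal_we + nap_we) + 5 / 7 * (nocturnal_wd + nap_wd)
}

#' Basal metabolic rate by Schofield weight-based equations
#'
#' Affine in body weight with sex- and age-band-specific constants
#' (kcal/day). Default constants are the widely used Schofield values for the
#' 3-10 and 10-18 year bands.
#'
#' @param age years, must lie in \code{[3, 18]}.
#' @param sex \code{"male"}/\code{"female"} (or 1/2).
#' @param weight_kg body weight, > 0.
#' @param constants named list of \code{c(a, b)} per sex and band; BMR =
#'   \code{a * weight + b}.
#' @return kcal/day.
#' @export
compute_bmr <- function(age, sex, weight_kg, constants = schofield_constants()) {
  if (any(age < 3 | age > 18)) stop("age outside [3, 18]")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  sex <- normalize_sex(sex)
  band <- ifelse(age < 10, "child", "adolescent")
  key <- paste(sex, band, sep = ".")
  a <- vapply(key, function(k) constants[[k]][1], numeric(1))
  b <- vapply(key, function(k) constants[[k]][2], numeric(1))
  unname(a * weight_kg + b)
}

#' @rdname compute_bmr
#' @export
schofield_constants <- function() {
  list(
    male.child = c(22.706, 504.3),
    male.adolescent = c(17.686, 658.2),
    female.child = c(20.315, 485.9),
    female.adolescent = c(13.384, 692.6)
  )
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("1", "m", "male", "boy")] <- "male"
  s[s %in% c("2", "f", "female", "girl")] <- "female"
  if (!all(s %in% c("male", "female"))) stop("sex must be male/female")
  s
}

#' Goldberg plausibility classification of a recall day
#'
#' A day is plausibly reported when the ratio of reported energy intake to
#' basal metabolic rate lies inside the Goldberg cutoff interval; otherwise
#' it is a misreport (under- or over-reporting). Cutoff constants are
#' configuration, defaulting to a common paediatric adaptation.
#'
#' @param energy_kcal reported daily energy intake.
#' @param bmr basal metabolic rate, kcal/day, > 0.
#' @param cutoffs length-2 numeric \code{(lower, upper)} on the EI/BMR scale.
#' @return character vector, \code{"plausible"} or \code{"misreporter"}.
#' @export
classify_goldberg <- function(energy_kcal, bmr, cutoffs = c(1.05, 2.28)) {
  if (any(bmr <= 0)) stop("bmr must be positive")
  ratio <- energy_kcal / bmr
  ifelse(ratio >= cutoffs[1] & ratio <= cutoffs[2], "plausible", "misreporter")
}

#' Flag exposure days with energy exclusion and Goldberg labels
#'
#' Convenience wrapper: joins participant BMR onto the per-day table and adds
#' a \code{plausibility} column with levels \code{excluded_low_energy},
#' \code{misreporter}, \code{plausible}.
#'
#' @param daily per-day exposure table.
#' @param participants participant table with \code{participant_id},
#'   \code{age}, \code{sex}, \code{weight_kg}.
#' @param cutoffs,threshold see [classify_goldberg()], [exclude_low_energy()].
#' @return the per-day table with \code{bmr} and \code{plausibility} added.
#' @export
label_plausibility <- function(daily, participants, cutoffs = c(1.05, 2.28),
                               threshold = 500) {
  dt <- data.table::as.data.table(daily)
  pt <- data.table::as.data.table(participants)
  pt <- pt[, .(participant_id,
               bmr = compute_bmr(age, sex, weight_kg))]
  dt <- pt[dt, on = "participant_id"]
  dt[, plausibility := ifelse(
    total_kcal < threshold, "excluded_low_energy",
    classify_goldberg(total_kcal, bmr, cutoffs))]
  dt[]
}
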