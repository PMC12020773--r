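# Shared fixtures, all generated in code. The small default cohort is built
# once per test run and memoised.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- population_spec(n_participants = 250, seed = 424242)
      cache <<- c(simulate_cohort(spec), list(spec = spec))
      cache$daily <<- derive_daily_exposures(cache$meals)
    }
    cache
  }
})

# A deterministic meal-level day for hand checks.
hand_day <- function() {
  data.table::data.table(
    participant_id = "P1", recall_id = "P1_R1", weekend = 0L,
    time_min = c(450, 780, 1050, 1200),   # 07:30 13:00 17:30 20:00
    energy_kcal = c(400, 600, 300, 300),
    healthy = c(1L, 0L, 0L, 1L),
    wake_min = 420, bed_min = 1350)       # 07:00, 22:30
}

# Simulate directly from the Stage-1 error model: n persons, d days each,
# identity transform, known variance components. Returns a per-day table
# with covariates, plus the true person effects.
simulate_error_model <- function(n = 200, d = 3, sigma_u = 1, sigma_e = 1,
                                 beta_weekend = 0.3, seed = 1,
                                 component = "window_h", mu = 10,
                                 id_prefix = "S") {
  withr::with_seed(seed, {
    ids <- sprintf("%s%04d", id_prefix, seq_len(n))
    u <- rnorm(n, 0, sigma_u)
    sex <- sample(c("male", "female"), n, TRUE)
    age <- runif(n, 8, 15)
    isced <- sample(c("low", "high"), n, TRUE)
    bmi <- rnorm(n)
    rows <- data.table::data.table(
      participant_id = rep(ids, each = d),
      weekend = rbinom(n * d, 1, 2 / 7),
      sex = rep(sex, each = d), age = rep(age, each = d),
      isced = rep(isced, each = d), bmi_z = rep(bmi, each = d))
    rows[[component]] <- mu + 0.1 * rows$age + beta_weekend * rows$weekend +
      rep(u, each = d) + rnorm(n * d, 0, sigma_e)
    list(daily = rows, u = u, ids = ids,
         covariates = data.table::data.table(
           participant_id = ids, sex = sex, age = age, isced = isced,
           bmi_z = bmi))
  })
}
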