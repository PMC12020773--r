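# Orchestration: one reproducible run from (optionally simulated) recall
# tables to pattern, association and selection results. All tables are plain
# delimited text, model artifacts are JSON, and a single global seed fans
# out to per-stage seeds through a fixed splitting rule, so a rerun with the
# same config reproduces every output byte for byte.

#' Default pipeline configuration
#'
#' @param out_dir run directory (created if absent).
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param n_participants cohort size when simulating.
#' @param M imputations for the three-stage analysis.
#' @param B bootstrap replicates for the selection CIs.
#' @param model covariate-set label for the association models.
#' @param outcome outcome z column analysed.
#' @param k,n_starts clustering parameters.
#' @param lambda_grid Box-Cox grid for the Stage-1 error models.
#' @param plausible_only sensitivity switch: restrict to plausible reporters.
#' @param simulate generate the cohort (\code{TRUE}) or read existing tables
#'   from \code{recalls_file}/\code{participants_file}/\code{outcomes_file}.
#' @param recalls_file,participants_file,outcomes_file input paths when
#'   \code{simulate = FALSE}.
#' @return named list of class \code{run_config}.
#' @export
default_config <- function(out_dir = tempfile("mtp_run_"), seed = 1L,
                           n_participants = 600, M = 50, B = 200,
                           model = "basic", outcome = "homa_ir_z",
                           k = 3, n_starts = 25,
                           lambda_grid = c(0, 0.25, 0.5, 0.75, 1),
                           plausible_only = FALSE, simulate = TRUE,
                           recalls_file = NULL, participants_file = NULL,
                           outcomes_file = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = n_participants, M = M, B = B,
                 model = model, outcome = outcome, k = k,
                 n_starts = n_starts, lambda_grid = lambda_grid,
                 plausible_only = plausible_only, simulate = simulate,
                 recalls_file = recalls_file,
                 participants_file = participants_file,
                 outcomes_file = outcomes_file),
            class = "run_config")
}

validate_config <- function(config) {
  # the *_file fields are legitimately NULL when simulating
  req <- setdiff(names(default_config()),
                 c("recalls_file", "participants_file", "outcomes_file"))
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  if (!config$simulate) {
    for (f in c("recalls_file", "participants_file", "outcomes_file")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("config path not resolvable: ", f)
      }
    }
  }
  invisible(config)
}

config_hash <- function(config) {
  # hash the scientific configuration only: output location must not change
  # the run identity
  config <- config[setdiff(names(config), "out_dir")]
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  # small stable rolling hash in double space; avoids digest dependencies
  # and integer overflow (doubles hold exact integers up to 2^53)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 127 + b) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full meal-timing pipeline
#'
#' Executes simulate (optional) -> derive -> usual -> cluster -> associate ->
#' select, writing every artifact plus a config snapshot and a deterministic
#' log with row counts at every filter step into \code{config$out_dir}.
#'
#' @param config a [default_config()] list (or a superset of it).
#' @return Invisibly, a list with the result objects and all output paths.
#' @export
run_full_pipeline <- function(config = default_config()) {
  config <- validate_config(modifyList(default_config(), as.list(config)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- c(sprintf("chronomtp run  config_hash=%s  seed=%d",
                         config_hash(config), config$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  wr <- function(x, name) {
    p <- file.path(config$out_dir, name)
    data.table::fwrite(x, p)
    paths[[name]] <<- p
    p
  }

  # stage: simulate or load -------------------------------------------------
  if (config$simulate) {
    spec <- population_spec(n_participants = config$n_participants,
                            seed = stage_seed(config$seed, 11L))
    cohort <- simulate_cohort(spec)
    meals <- cohort$meals
    participants <- cohort$participants
    outcomes <- cohort$outcomes
    wr(meals, "recalls.csv")
    wr(participants, "participants.csv")
    wr(outcomes, "outcomes.csv")
    say("simulate: %d participants, %d recall days, %d meal rows",
        nrow(participants), length(unique(meals$recall_id)), nrow(meals))
  } else {
    meals <- data.table::fread(config$recalls_file)
    participants <- data.table::fread(config$participants_file)
    outcomes <- data.table::fread(config$outcomes_file)
    say("load: %d participants, %d meal rows", nrow(participants), nrow(meals))
  }

  # stage: derive ------------------------------------------------------------
  daily <- derive_daily_exposures(meals)
  daily <- label_plausibility(daily, participants)
  wr(daily, "daily_exposures.csv")
  say("derive: %d recall days (%d flagged misreported, %d below 500 kcal)",
      nrow(daily), sum(daily$plausibility == "misreporter"),
      sum(daily$plausibility == "excluded_low_energy"))

  # stage: associate (includes usual + cluster internally) -------------------
  ts <- run_three_stage(daily, participants, outcomes,
                        outcome = config$outcome, M = config$M,
                        seed = stage_seed(config$seed, 12L),
                        model = config$model, k = config$k,
                        n_starts = config$n_starts,
                        lambda_grid = config$lambda_grid,
                        plausible_only = config$plausible_only)
  wr(ts$usual_rc, "usual_rc.csv")
  paths[["mtp_model.json"]] <-
    write_mtp_model(ts$mtp_model, file.path(config$out_dir, "mtp_model.json"))
  wr(ts$results, "association_results.csv")
  say("usual+cluster: %d participants; pattern shares %s",
      nrow(ts$usual_rc),
      paste(sprintf("%s=%.2f", names(table(ts$mtp_model$training_assignment)),
                    as.numeric(table(ts$mtp_model$training_assignment)) /
                      nrow(ts$usual_rc)), collapse = " "))
  say("associate: outcome=%s model=%s M=%d failures=%d",
      config$outcome, config$model, config$M, ts$failures)
  for (i in seq_len(nrow(ts$results))) {
    say("  %s beta=%.4f CI=(%.4f, %.4f)", ts$results$contrast[i],
        ts$results$beta[i], ts$results$ci_lower[i], ts$results$ci_upper[i])
  }

  # stage: select ------------------------------------------------------------
  sel_frame <- merge(as.data.frame(ts$usual_rc),
                     as.data.frame(participants), by = "participant_id")
  sel_frame <- merge(sel_frame, as.data.frame(outcomes), by = "participant_id")
  sel <- best_subset(sel_frame, outcome = config$outcome)
  boot <- bootstrap_ci(sel_frame, outcome = config$outcome,
                       selected = sel$selected, B = config$B,
                       seed = stage_seed(config$seed, 13L))
  selection <- merge(sel$coefficients, boot$ci[, c("exposure", "lower", "upper")],
                     by = "exposure", sort = FALSE)
  wr(selection, "selection_results.csv")
  say("select: criterion=%s value=%.2f selected={%s} B=%d",
      sel$criterion, sel$criterion_value,
      paste(sel$selected, collapse = ", "), config$B)

  # snapshot + log -----------------------------------------------------------
  snap <- file.path(config$out_dir, "config_snapshot.json")
  jsonlite::write_json(unclass(config), snap, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths[["config_snapshot.json"]] <- snap
  logp <- file.path(config$out_dir, "log.txt")
  writeLines(log_lines, logp)
  paths[["log.txt"]] <- logp

  invisible(list(config = config, paths = paths, three_stage = ts,
                 selection = sel, bootstrap = boot, daily = daily))
}

#' Re-read a config snapshot
#'
#' Parsing the emitted \code{config_snapshot.json} reproduces the run
#' configuration (round-trip property).
#'
#' @param path path to a snapshot written by [run_full_pipeline()].
#' @return a \code{run_config} list.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(modifyList(default_config(), obj), class = "run_config")
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{derive}, \code{usual}, \code{cluster},
#' \code{run-all} (and \code{associate}/\code{select}, which run the full
#' pipeline). Flags: \code{--config <json>}, \code{--seed <int>},
#' \code{--out-dir <dir>}, \code{--M <int>}, \code{--B <int>},
#' \code{--plausible-only}. Exit codes: 0 ok, 1 validation error, 2 stage
#' failure. Invoke via \code{Rscript -e 'chronomtp::mtp_main()' <args>} or
#' the installed \code{cli/chronomtp.R} script.
#'
#' @param args character vector (defaults to the command line).
#' @return exit code, invisibly.
#' @export
mtp_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: chronomtp <simulate|derive|usual|cluster|associate|select|run-all> [--config f] [--seed i] [--out-dir d] [--M i] [--B i] [--plausible-only]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--plausible-only") { opts$plausible_only <- TRUE; i <- i + 1 }
    else if (startsWith(a, "--")) {
      if (i == length(args)) { message("missing value for ", a); return(invisible(1L)) }
      key <- gsub("-", "_", substring(a, 3))
      opts[[key]] <- args[i + 1]; i <- i + 2
    } else { message(usage); return(invisible(1L)) }
  }
  config <- tryCatch({
    base <- if (!is.null(opts$config)) read_config(opts$config) else default_config()
    for (k in c("seed", "M", "B", "n_participants")) {
      if (!is.null(opts[[k]])) base[[k]] <- as.integer(opts[[k]])
    }
    if (!is.null(opts$out_dir)) base$out_dir <- opts$out_dir
    if (isTRUE(opts$plausible_only)) base$plausible_only <- TRUE
    validate_config(base)
  }, error = function(e) { message("config error: ", conditionMessage(e)); NULL })
  if (is.null(config)) return(invisible(1L))

  run_stage <- function(expr) {
    tryCatch({ expr; invisible(0L) },
             error = function(e) {
               message("stage failed: ", conditionMessage(e))
               invisible(2L)
             })
  }
  switch(cmd,
    "simulate" = run_stage({
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      spec <- population_spec(n_participants = config$n_participants,
                              seed = stage_seed(config$seed, 11L))
      cohort <- simulate_cohort(spec)
      data.table::fwrite(cohort$meals, file.path(config$out_dir, "recalls.csv"))
      data.table::fwrite(cohort$participants,
                         file.path(config$out_dir, "participants.csv"))
      data.table::fwrite(cohort$outcomes, file.path(config$out_dir, "outcomes.csv"))
      message("wrote cohort tables to ", config$out_dir)
    }),
    "derive" = run_stage({
      meals <- data.table::fread(config$recalls_file)
      participants <- data.table::fread(config$participants_file)
      daily <- label_plausibility(derive_daily_exposures(meals), participants)
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(daily, file.path(config$out_dir, "daily_exposures.csv"))
      message("wrote daily exposures to ", config$out_dir)
    }),
    "usual" = run_stage({
      daily <- data.table::fread(file.path(config$out_dir, "daily_exposures.csv"))
      participants <- data.table::fread(file.path(config$out_dir, "participants.csv"))
      fits <- fit_usual_models(exclude_low_energy(daily)$retained,
                               participants, lambda_grid = config$lambda_grid)
      usual <- predict_usual_table(fits, participants)
      data.table::fwrite(usual, file.path(config$out_dir, "usual_rc.csv"))
      message("wrote usual exposures to ", config$out_dir)
    }),
    "cluster" = run_stage({
      usual <- data.table::fread(file.path(config$out_dir, "usual_rc.csv"))
      model <- fit_mtp(usual, k = config$k, n_starts = config$n_starts,
                       seed = stage_seed(config$seed, 20L))
      write_mtp_model(model, file.path(config$out_dir, "mtp_model.json"))
      message("wrote MTP model to ", config$out_dir)
    }),
    "run-all" = ,
    "associate" = ,
    "select" = run_stage(run_full_pipeline(config)),
    { message(usage); invisible(1L) })
}
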