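#' Write a synthetic cohort to CSV
#'
#' Emits `participants.csv` (one row per participant) and `choices.csv`
#' (long format: participant_id, social_distance, trial_index,
#' selfish_amount, choice). Both files start with a `#` header comment
#' carrying the config hash and seed, so any downstream table can be traced
#' to the generating configuration.
#'
#' @param cohort An [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# config_hash: %s seed: %d", cohort$config_hash,
                    cohort$config$seed)
  paths <- file.path(dir, c("participants.csv", "choices.csv"))
  tables <- list(cohort$participants, cohort$choices)
  for (i in 1:2) {
    writeLines(header, paths[i])
    readr::write_csv(tables[[i]], paths[i], append = TRUE, col_names = TRUE)
  }
  invisible(paths)
}

#' Read a long-format choices table
#'
#' Validates and loads a `choices.csv`: required columns, canonical social
#' distances, exactly nine uniquely-indexed trials per (participant,
#' distance) block, and choice labels in `{selfish, generous}`. Violations
#' are reported with the offending rows or blocks.
#'
#' @param path Path to a CSV with columns `participant_id`,
#'   `social_distance`, `trial_index`, `selfish_amount`, `choice`; `#` lines
#'   are treated as comments.
#' @return A validated tibble of choices.
#' @export
read_choices <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("participant_id", "social_distance", "trial_index",
           "selfish_amount", "choice")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("choices file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_label <- which(!raw$choice %in% c("selfish", "generous"))
  if (length(bad_label)) {
    stop("invalid choice label at data row(s) ",
         paste(utils::head(bad_label, 5), collapse = ", "),
         " (must be selfish/generous)", call. = FALSE)
  }
  bad_n <- setdiff(unique(raw$social_distance), social_distances())
  if (length(bad_n)) {
    stop("non-canonical social distance(s): ",
         paste(bad_n, collapse = ", "), call. = FALSE)
  }
  blocks <- raw |>
    dplyr::group_by(.data$participant_id, .data$social_distance) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_unique = dplyr::n_distinct(.data$trial_index),
                     .groups = "drop")
  bad_block <- blocks |>
    dplyr::filter(.data$n_trials != 9L | .data$n_unique != 9L)
  if (nrow(bad_block)) {
    stop("malformed block(s) (need 9 uniquely-indexed trials): ",
         paste(utils::head(
           paste0(bad_block$participant_id, "/N=", bad_block$social_distance),
           5), collapse = ", "), call. = FALSE)
  }
  raw
}

#' Read a participants table written by [write_cohort()]
#' @param path Path to `participants.csv`.
#' @return A tibble.
#' @export
read_participants <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write / read a cohort configuration as YAML
#' @param config An [cohort_config()] object.
#' @param path YAML file path.
#' @return `write_cohort_config()` returns the path invisibly;
#'   `read_cohort_config()` returns the config.
#' @export
write_cohort_config <- function(config, path) {
  cfg <- unclass(config)
  # named vectors become YAML maps (plain numeric vectors drop their names)
  for (f in c("stab_coefs", "subscale_shares")) cfg[[f]] <- as.list(cfg[[f]])
  cfg$gender_probs_by_group <- lapply(cfg$gender_probs_by_group, as.list)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$gender_probs_by_group <- lapply(cfg$gender_probs_by_group, unlist)
  cfg$income_probs_by_group <- lapply(cfg$income_probs_by_group, unlist)
  for (f in c("tripm_mean_by_group", "tripm_sd_by_group", "logk_mean_by_group",
              "stab_coefs", "subscale_shares", "age_mean_by_group",
              "age_sd_by_group", "fluid_mean_by_group", "fluid_sd_by_group",
              "attention_probs")) {
    cfg[[f]] <- unlist(cfg[[f]])
  }
  do.call(cohort_config, cfg[setdiff(names(cfg), character())])
}

#' Configuration for a full pipeline run
#'
#' Exactly one input source: either a synthetic [cohort_config()] or a pair
#' of CSV paths (participants + choices).
#'
#' @param cohort A [cohort_config()] (synthetic source), or `NULL`.
#' @param participants_csv,choices_csv File paths (file source), or `NULL`.
#' @param fit An [fit_options()] list (V0 mode, k floor, AIC vs AICc).
#' @param mediation_sims,mediation_method,seed Mediation engine settings and
#'   the run-level seed.
#' @param matching_caliper Caliper for [propensity_match()].
#' @param cv_folds Folds for [kfold_cv()].
#' @param output_dir Where [run_pipeline()] writes its tables, or `NULL` to
#'   keep results in memory only.
#' @return A list of class `sd_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       participants_csv = NULL, choices_csv = NULL,
                       fit = fit_options(),
                       mediation_sims = 1000L,
                       mediation_method = "quasi_bayesian",
                       seed = 1L,
                       matching_caliper = 0.2,
                       cv_folds = 10L,
                       output_dir = NULL) {
  from_files <- !is.null(participants_csv) || !is.null(choices_csv)
  if (from_files && !is.null(cohort)) {
    stop("configure exactly one input source: synthetic cohort or CSV files",
         call. = FALSE)
  }
  if (from_files && (is.null(participants_csv) || is.null(choices_csv))) {
    stop("file input needs both participants_csv and choices_csv",
         call. = FALSE)
  }
  structure(
    list(cohort = cohort, participants_csv = participants_csv,
         choices_csv = choices_csv, fit = fit,
         mediation_sims = as.integer(mediation_sims),
         mediation_method = mediation_method, seed = as.integer(seed),
         matching_caliper = matching_caliper, cv_folds = as.integer(cv_folds),
         output_dir = output_dir),
    class = "sd_run_config"
  )
}

#' Run the full social-discounting analysis pipeline
#'
#' End-to-end orchestration: attention-check exclusions -> income recoding
#' -> indifference profiles -> per-participant hyperbolic fits (logk) and
#' AUC (the two metrics are always produced together: higher logk = steeper
#' discounting, higher AUC = more generosity) -> pooled model comparison
#' across families -> group and continuous regressions with covariates ->
#' subscale regression -> mediation (group-based and continuous) ->
#' discounting-by-group moderation and age moderation -> reliability ->
#' 10-fold CV and propensity-matching robustness. When the cohort contains
#' no high-psychopathy participants the group-based analyses are skipped
#' with an explicit notice while continuous analyses still run.
#'
#' @param config An [run_config()] object.
#' @return A list of class `sd_result_bundle` with elements `participants`
#'   (analysis table), `profiles`, `fits`, `auc`, `model_comparison`,
#'   `group_tests`, `regressions` (list of `sd_ols`), `mediation`,
#'   `moderation`, `reliability`, `robustness`, `exclusions`, `notes`,
#'   `config_hash`, `seed`. If `output_dir` is set, tables are also written
#'   as CSV/JSON plus a plain-text summary and run log.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "sd_run_config"))
  notes <- character()
  log_line <- function(...) notes <<- c(notes, sprintf(...))

  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
    participants <- cohort$participants
    choices <- cohort$choices
    config_hash <- cohort$config_hash
    log_line("generated synthetic cohort: %d participants, seed %d",
             nrow(participants), config$cohort$seed)
  } else {
    participants <- read_participants(config$participants_csv)
    choices <- read_choices(config$choices_csv)
    config_hash <- rlang::hash(config)
    log_line("loaded %d participants / %d choice rows from files",
             nrow(participants), nrow(choices))
  }

  excl <- apply_exclusions(participants)
  log_line("excluded %d participant(s) for attention-check failures; %d retained",
           nrow(excl$excluded), nrow(excl$retained))
  participants <- recode_income(excl$retained)
  n_recode <- sum(is.na(excl$retained$income_bracket))
  log_line("recoded %d don't-know income bracket(s) to the sample mean bracket",
           n_recode)
  choices <- dplyr::semi_join(choices, participants, by = "participant_id")

  profiles <- build_profiles(choices)
  log_line("%d monotonicity violation(s) across %d blocks (flagged, retained)",
           sum(profiles$violation), nrow(profiles))

  fits <- fit_discounting(profiles, "hyperbolic", config$fit)
  auc <- compute_auc(profiles)
  pooled <- dplyr::bind_rows(lapply(
    c("hyperbolic", "exponential", "linear"),
    function(f) fit_pooled(profiles, f, config$fit)
  ))
  model_comparison <- compare_models(pooled)

  analysis <- participants |>
    dplyr::inner_join(dplyr::select(fits, "participant_id", "logk",
                                    "k_floored"),
                      by = "participant_id") |>
    dplyr::inner_join(dplyr::select(auc, "participant_id", "auc"),
                      by = "participant_id")

  covs <- c("age", "gender", "income_bracket", "fluid_intelligence")
  has_groups <- length(unique(analysis$group)) == 2

  group_tests <- NULL
  regressions <- list()
  mediation <- list()
  moderation <- list()
  robustness <- list()

  if (has_groups) {
    analysis$group_high <- as.numeric(analysis$group == "high")
    group_tests <- dplyr::bind_rows(
      dplyr::mutate(welch_test(analysis, "tripm_total", "group"),
                    variable = "tripm_total", .before = 1),
      dplyr::mutate(welch_test(analysis, "stab_total", "group"),
                    variable = "stab_total", .before = 1),
      dplyr::mutate(welch_test(analysis, "logk", "group"),
                    variable = "logk", .before = 1)
    )
    regressions$group_logk <- fit_ols(analysis, "logk", "group_high", covs)
    regressions$group_auc <- fit_ols(analysis, "auc", "group_high", covs)
    mediation$group <- mediate_effects(
      analysis, outcome = "stab_total", mediator = "logk",
      treatment = "group_high", covariates = covs,
      sims = config$mediation_sims, seed = config$seed,
      method = config$mediation_method)
    moderation$logk_by_group <- fit_moderation(
      analysis, "stab_total", "logk", "group_high", covs)
    moderation$age_by_group <- fit_moderation(
      analysis, "logk", "group_high", "age",
      setdiff(covs, "age"))
    robustness$cv_group <- kfold_cv(analysis, "logk", "group_high", covs,
                                    k = config$cv_folds, seed = config$seed)
    match <- propensity_match(analysis, "group_high", c("age", "gender",
                                                        "income_bracket",
                                                        "fluid_intelligence"),
                              caliper = config$matching_caliper)
    robustness$matching <- match
    if (nrow(match$pairs) > 1) {
      robustness$matched_group_logk <- fit_ols(match$matched_data, "logk",
                                               "group_high", covs)
    }
  } else {
    log_line("NOTICE: only one group present; group-based analyses skipped")
  }

  regressions$tripm_logk <- fit_ols(analysis, "logk", "tripm_total", covs)
  regressions$tripm_auc <- fit_ols(analysis, "auc", "tripm_total", covs)
  regressions$subscales_logk <- fit_ols(
    analysis, "logk",
    c("tripm_meanness", "tripm_disinhibition", "tripm_boldness"), covs)
  regressions$logk_stab <- fit_ols(analysis, "stab_total", "logk", covs)
  mediation$continuous <- mediate_effects(
    analysis, outcome = "stab_total", mediator = "logk",
    treatment = "tripm_total", covariates = covs,
    sims = config$mediation_sims, seed = config$seed,
    method = config$mediation_method)
  moderation$logk_by_tripm <- fit_moderation(
    analysis, "stab_total", "logk", "tripm_total", covs)
  moderation$age_by_tripm <- fit_moderation(
    analysis, "logk", "tripm_total", "age", setdiff(covs, "age"))
  robustness$cv_tripm <- kfold_cv(analysis, "logk", "tripm_total", covs,
                                  k = config$cv_folds, seed = config$seed)

  reliability <- cronbach_alpha(
    analysis[, c("tripm_boldness", "tripm_meanness", "tripm_disinhibition")])

  bundle <- structure(
    list(participants = analysis, profiles = profiles, fits = fits,
         auc = auc, pooled_fits = pooled,
         model_comparison = model_comparison,
         best_family = attr(model_comparison, "best_family"),
         group_tests = group_tests, regressions = regressions,
         mediation = mediation, moderation = moderation,
         reliability = reliability, robustness = robustness,
         exclusions = excl$excluded, notes = notes,
         config_hash = config_hash, seed = config$seed),
    class = "sd_result_bundle"
  )
  if (!is.null(config$output_dir)) {
    write_result_bundle(bundle, config$output_dir)
  }
  bundle
}

#' Write a result bundle to disk
#'
#' CSV for tabular results (profiles, fits, AUC, regression term tables in
#' the study-style layout `Variable b (se) CI Std. B (se) Std. CI p`),
#' JSON for model comparison / mediation / reliability, and a plain-text
#' summary. Every table carries the config hash in a header comment;
#' timestamps appear only in `run.log` so bundles are byte-reproducible.
#'
#' @param bundle An `sd_result_bundle`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# config_hash: %s seed: %d", bundle$config_hash,
                    bundle$seed)
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    writeLines(header, p)
    readr::write_csv(x, p, append = TRUE, col_names = TRUE)
  }
  wcsv(bundle$profiles, "profiles.csv")
  wcsv(bundle$fits, "fits.csv")
  wcsv(bundle$auc, "auc.csv")
  if (!is.null(bundle$group_tests)) wcsv(bundle$group_tests, "group_tests.csv")
  for (nm in names(bundle$regressions)) {
    wcsv(tidy(bundle$regressions[[nm]]), paste0("regression_", nm, ".csv"))
  }
  for (nm in names(bundle$moderation)) {
    wcsv(tidy(bundle$moderation[[nm]]), paste0("moderation_", nm, ".csv"))
  }
  jsonlite::write_json(
    list(config_hash = bundle$config_hash,
         comparison = bundle$model_comparison,
         best_family = bundle$best_family),
    file.path(dir, "model_comparison.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(bundle$mediation, function(m) {
      list(effects = tidy(m), sims = m$sims, seed = m$seed, method = m$method)
    }),
    file.path(dir, "mediation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, reliability = bundle$reliability),
    file.path(dir, "reliability.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$robustness$matching)) {
    wcsv(bundle$robustness$matching$pairs, "matching_pairs.csv")
    wcsv(bundle$robustness$matching$smd, "matching_smd.csv")
  }
  writeLines(c(header, summary_lines(bundle)), file.path(dir, "summary.txt"))
  writeLines(c(paste0("timestamp: ", format(Sys.time())), header,
               bundle$notes),
             file.path(dir, "run.log"))
  invisible(dir)
}

summary_lines <- function(bundle) {
  mc <- bundle$model_comparison
  c(
    sprintf("participants analysed: %d", nrow(bundle$participants)),
    sprintf("best-fitting family (pooled AIC): %s", bundle$best_family),
    sprintf("akaike weights: %s",
            paste(sprintf("%s=%.3f", mc$family, mc$akaike_weight),
                  collapse = " ")),
    sprintf("mean logk: %.3f; mean AUC: %.3f",
            mean(bundle$participants$logk), mean(bundle$participants$auc)),
    if (!is.null(bundle$group_tests)) {
      d <- bundle$group_tests[bundle$group_tests$variable == "logk", ]
      sprintf("group difference in logk: t(%.2f) = %.2f, d = %.2f",
              d$df, d$statistic, d$cohens_d)
    }
  )
}

#' @export
print.sd_result_bundle <- function(x, ...) {
  cat("<sd_result_bundle>\n")
  cat(paste0("  ", summary_lines(x)), sep = "\n")
  invisible(x)
}
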