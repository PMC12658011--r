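#' Configuration for a synthetic social-discounting cohort
#'
#' Defines the statistical structure the downstream analysis assumes: two
#' groups (control, high-psychopathy) with group-separated TriPM total
#' distributions, a latent per-participant log discount rate logk that
#' generates the task choices through the hyperbolic model, and an
#' antisocial-behaviour (STAB) outcome built from group and logk so that the
#' group difference in antisociality is partially mediated by discounting.
#'
#' Defaults mirror the study conditions the analysis is aimed at: group
#' sizes 427/288; TriPM moments 55.86 (19.90) and 122.25 (16.92); latent
#' logk means -4.5 / -3.0 with common SD 1.65 (standardized group difference
#' 0.91); STAB coefficients chosen so the group STAB means/SDs are ~58.8
#' (18.1) and ~95.3 (18.7) and the planted indirect (group -> logk -> STAB)
#' path is ~4% of the total group effect.
#'
#' @param n_control,n_high Group sizes (> 0).
#' @param tripm_mean_by_group,tripm_sd_by_group Length-2 numeric
#'   (control, high) TriPM total moments.
#' @param logk_mean_by_group Length-2 numeric (control, high) latent logk
#'   means.
#' @param logk_sd Common latent logk SD (> 0).
#' @param stab_coefs Named numeric `c(intercept, group, logk, sigma)`: STAB =
#'   intercept + group * \[high\] + logk * latent_logk + N(0, sigma). A zero
#'   `logk` entry removes the indirect path.
#' @param subscale_shares Length-3 shares (boldness, meanness, disinhibition)
#'   of the TriPM total; subscales are share * total plus zero-sum noise, so
#'   they always sum exactly to the total.
#' @param subscale_noise_sd SD of the subscale noise before centring.
#' @param age_mean_by_group,age_sd_by_group Age moments (years); ages are
#'   truncated to \[18, 79\].
#' @param gender_probs_by_group List of two length-3 probability vectors
#'   (male, female, other), control then high.
#' @param income_probs_by_group List of two length-9 probability vectors over
#'   brackets 1-8 plus "don't know", control then high.
#' @param fluid_mean_by_group,fluid_sd_by_group Fluid-intelligence moments;
#'   scores are rounded and truncated to 0-13.
#' @param attention_probs Length-5 probabilities of 0-4 failed attention
#'   checks.
#' @param v0 Undiscounted value V0 used when simulating choices (dollars).
#' @param choice_temperature Softmax temperature in dollars (>= 0); 0 gives
#'   deterministic threshold responding.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config (including this seed).
#' @return A list of class `sd_cohort_config`.
#' @export
cohort_config <- function(n_control = 427L,
                          n_high = 288L,
                          tripm_mean_by_group = c(55.86, 122.25),
                          tripm_sd_by_group = c(19.90, 16.92),
                          logk_mean_by_group = c(-4.5, -3.0),
                          logk_sd = 1.65,
                          stab_coefs = c(intercept = 63.3, group = 35.0,
                                         logk = 1.0, sigma = 18.0),
                          subscale_shares = c(boldness = 0.33, meanness = 0.35,
                                              disinhibition = 0.32),
                          subscale_noise_sd = 5,
                          age_mean_by_group = c(40.21, 31.50),
                          age_sd_by_group = c(11.59, 8.92),
                          gender_probs_by_group = list(
                            control = c(male = 0.447, female = 0.525, other = 0.028),
                            high = c(male = 0.427, female = 0.510, other = 0.063)),
                          income_probs_by_group = list(
                            control = c(0.131, 0.260, 0.208, 0.143, 0.066,
                                        0.049, 0.042, 0.084, 0.017),
                            high = c(0.125, 0.226, 0.198, 0.111, 0.094,
                                     0.035, 0.066, 0.104, 0.041)),
                          fluid_mean_by_group = c(5.57, 5.16),
                          fluid_sd_by_group = c(2.09, 1.96),
                          attention_probs = c(0.90, 0.08, 0.013, 0.005, 0.002),
                          v0 = 80,
                          choice_temperature = 2,
                          seed = 20251126L) {
  cfg <- list(
    n_control = as.integer(n_control), n_high = as.integer(n_high),
    tripm_mean_by_group = tripm_mean_by_group,
    tripm_sd_by_group = tripm_sd_by_group,
    logk_mean_by_group = logk_mean_by_group, logk_sd = logk_sd,
    stab_coefs = stab_coefs,
    subscale_shares = subscale_shares,
    subscale_noise_sd = subscale_noise_sd,
    age_mean_by_group = age_mean_by_group, age_sd_by_group = age_sd_by_group,
    gender_probs_by_group = gender_probs_by_group,
    income_probs_by_group = income_probs_by_group,
    fluid_mean_by_group = fluid_mean_by_group,
    fluid_sd_by_group = fluid_sd_by_group,
    attention_probs = attention_probs,
    v0 = v0, choice_temperature = choice_temperature,
    seed = as.integer(seed)
  )
  .validate_cohort_config(cfg)
  structure(cfg, class = "sd_cohort_config")
}

.validate_cohort_config <- function(cfg) {
  err <- function(field, why) {
    stop("invalid cohort config: field '", field, "' ", why, call. = FALSE)
  }
  if (cfg$n_control <= 0) err("n_control", "must be > 0")
  if (cfg$n_high <= 0) err("n_high", "must be > 0")
  for (f in c("tripm_mean_by_group", "tripm_sd_by_group",
              "logk_mean_by_group", "age_mean_by_group", "age_sd_by_group",
              "fluid_mean_by_group", "fluid_sd_by_group")) {
    if (length(cfg[[f]]) != 2) err(f, "must have exactly two entries (control, high)")
  }
  if (any(cfg$tripm_sd_by_group <= 0)) err("tripm_sd_by_group", "must be > 0")
  if (cfg$logk_sd <= 0) err("logk_sd", "must be > 0")
  if (cfg$choice_temperature < 0) err("choice_temperature", "must be >= 0")
  if (length(cfg$stab_coefs) != 4 || cfg$stab_coefs[["sigma"]] < 0) {
    err("stab_coefs", "must be c(intercept, group, logk, sigma) with sigma >= 0")
  }
  if (abs(sum(cfg$subscale_shares) - 1) > 1e-8) {
    err("subscale_shares", "must sum to 1")
  }
  for (g in 1:2) {
    if (abs(sum(cfg$gender_probs_by_group[[g]]) - 1) > 1e-6) {
      err("gender_probs_by_group", "probabilities must sum to 1")
    }
    if (abs(sum(cfg$income_probs_by_group[[g]]) - 1) > 1e-6) {
      err("income_probs_by_group", "probabilities must sum to 1")
    }
  }
  if (abs(sum(cfg$attention_probs) - 1) > 1e-6) {
    err("attention_probs", "probabilities must sum to 1")
  }
  invisible(cfg)
}

#' Simulate one participant's choice blocks from a latent discount rate
#'
#' The probability of the generous choice on a trial is
#' logistic((v_N - forgone) / temperature), where v_N = V0 / (1 + k N) is
#' the hyperbolic discounted value at that distance and `forgone` is the
#' dollar sacrifice the generous choice entails on that trial. Temperature 0
#' gives deterministic threshold responding: generous exactly when the
#' forgone amount does not exceed v_N.
#'
#' @param latent_logk Latent log discount rate.
#' @param schedule A [trial_schedule()] tibble.
#' @param v0 Undiscounted value V0 (dollars).
#' @param temperature Softmax temperature in dollars (>= 0).
#' @param seed Integer seed (ignored at temperature 0).
#' @return A tibble with columns `social_distance`, `trial_index`,
#'   `selfish_amount`, `choice`.
#' @export
simulate_choices <- function(latent_logk, schedule = trial_schedule(),
                             v0 = 80, temperature = 2, seed = 1L) {
  stopifnot(temperature >= 0)
  distances <- attr(schedule, "social_distances")
  k <- exp(latent_logk)
  grid <- tidyr::expand_grid(
    social_distance = distances,
    schedule[, c("trial_index", "selfish_amount", "forgone_amount")]
  )
  v_n <- model_value("hyperbolic", v0, k, grid$social_distance)
  if (temperature == 0) {
    generous <- grid$forgone_amount <= v_n
  } else {
    p <- stats::plogis((v_n - grid$forgone_amount) / temperature)
    generous <- withr::with_seed(seed, stats::runif(nrow(grid)) < p)
  }
  grid |>
    dplyr::mutate(choice = ifelse(generous, "generous", "selfish")) |>
    dplyr::select("social_distance", "trial_index", "selfish_amount", "choice")
}

#' Assign participants to groups by gender-specific TriPM cutoffs
#'
#' Group membership follows estimated 95th-percentile TriPM cutoffs for the
#' participant's gender: scores at or above the cutoff are high-psychopathy,
#' scores below are control (only those who fall below a cutoff are moved
#' out of the high group, so the boundary score itself stays high). The
#' default cutoffs (male 105, female/other 91) are placeholder estimates
#' taken from the within-group score ranges such samples report; supply
#' norm-derived cutoffs where available.
#'
#' @param data A data frame with columns `tripm_total` and `gender`.
#' @param cutoffs Named numeric vector mapping every gender level present in
#'   `data` to a cutoff score.
#' @return `data` with a `group` column (`"control"`/`"high"`) added or
#'   replaced.
#' @export
assign_group <- function(data, cutoffs = c(male = 105, female = 91, other = 91)) {
  missing_g <- setdiff(unique(data$gender), names(cutoffs))
  if (length(missing_g)) {
    stop("no TriPM cutoff configured for gender(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::mutate(group = ifelse(.data$tripm_total >= unname(cutoffs[.data$gender]),
                                 "high", "control"))
}

#' Exclude participants who failed attention checks
#'
#' Participants failing two or more of the four attention checks are
#' excluded; everyone else is retained. Reasons are logged per excluded
#' participant.
#'
#' @param participants A data frame with `participant_id` and
#'   `attention_failures` (0-4).
#' @return A list with `retained` and `excluded` tibbles; `excluded` gains a
#'   `reason` column.
#' @export
apply_exclusions <- function(participants) {
  af <- participants$attention_failures
  if (any(is.na(af)) || any(af < 0 | af > 4)) {
    stop("attention_failures must lie in 0-4", call. = FALSE)
  }
  out <- participants |>
    dplyr::mutate(.excluded = .data$attention_failures >= 2)
  list(
    retained = out |> dplyr::filter(!.data$.excluded) |> dplyr::select(-".excluded"),
    excluded = out |>
      dplyr::filter(.data$.excluded) |>
      dplyr::select(-".excluded") |>
      dplyr::mutate(reason = paste0("failed ", .data$attention_failures,
                                    " of 4 attention checks"))
  )
}

#' Recode "don't know" household income to the sample mean bracket
#'
#' Participants who did not know their household income are assigned the
#' mean bracket of those who did, rounded half-up to the nearest ordinal
#' code. All other entries are unchanged.
#'
#' @param participants A data frame with an `income_bracket` column: ordinal
#'   codes 1-8 or `NA` for "don't know".
#' @return The data frame with `income_bracket` completed.
#' @export
recode_income <- function(participants) {
  known <- participants$income_bracket[!is.na(participants$income_bracket)]
  if (!length(known)) {
    stop("cannot recode income: every participant answered \"don't know\"",
         call. = FALSE)
  }
  mean_bracket <- floor(mean(known) + 0.5) # round half-up
  participants |>
    dplyr::mutate(income_bracket = dplyr::coalesce(.data$income_bracket,
                                                   mean_bracket))
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws participant-level variables group by group from the configured
#' distributions, builds the TriPM subscales as shares of the total plus
#' zero-sum noise, plants the mediation structure STAB = b0 + b1 group +
#' b2 logk + noise, and simulates every participant's 63 task choices from
#' their latent logk through the hyperbolic value rule. Identical configs
#' (including seed) give identical cohorts.
#'
#' @param config An [cohort_config()] object.
#' @return A list of class `sd_cohort` with tibbles `participants` (one row
#'   per participant) and `choices` (long, 63 rows per participant), plus
#'   the `config` and its hash.
#' @export
generate_cohort <- function(config = cohort_config()) {
  .validate_cohort_config(config)
  cfg <- config
  n <- c(cfg$n_control, cfg$n_high)
  groups <- c("control", "high")

  participants <- withr::with_seed(cfg$seed, {
    per_group <- lapply(1:2, function(g) {
      ng <- n[g]
      tripm <- stats::rnorm(ng, cfg$tripm_mean_by_group[g], cfg$tripm_sd_by_group[g])
      logk <- stats::rnorm(ng, cfg$logk_mean_by_group[g], cfg$logk_sd)
      # subscales: shares of the total plus zero-sum noise so they sum exactly
      eps <- matrix(stats::rnorm(ng * 3, 0, cfg$subscale_noise_sd), ncol = 3)
      eps <- eps - rowMeans(eps)
      sub <- outer(tripm, cfg$subscale_shares) + eps
      income_draw <- sample.int(9L, ng, replace = TRUE,
                                prob = cfg$income_probs_by_group[[g]])
      tibble::tibble(
        group = groups[g],
        tripm_total = tripm,
        tripm_boldness = sub[, 1],
        tripm_meanness = sub[, 2],
        tripm_disinhibition = sub[, 3],
        latent_logk = logk,
        age = round(.rtrunc_norm(ng, cfg$age_mean_by_group[g],
                                 cfg$age_sd_by_group[g], 18, 79)),
        gender = sample(c("male", "female", "other"), ng, replace = TRUE,
                        prob = cfg$gender_probs_by_group[[g]]),
        income_bracket = ifelse(income_draw == 9L, NA_integer_, income_draw),
        fluid_intelligence = round(.rtrunc_norm(ng, cfg$fluid_mean_by_group[g],
                                                cfg$fluid_sd_by_group[g], 0, 13)),
        attention_failures = sample(0:4, ng, replace = TRUE,
                                    prob = cfg$attention_probs)
      )
    })
    dat <- dplyr::bind_rows(per_group)
    b <- cfg$stab_coefs
    dat$stab_total <- b[["intercept"]] + b[["group"]] * (dat$group == "high") +
      b[["logk"]] * dat$latent_logk +
      stats::rnorm(nrow(dat), 0, b[["sigma"]])
    dat$participant_id <- sprintf("P%04d", seq_len(nrow(dat)))
    dat$choice_seed <- sample.int(.Machine$integer.max, nrow(dat))
    dplyr::relocate(dat, "participant_id")
  })

  sched <- trial_schedule()
  choices <- participants |>
    dplyr::select("participant_id", "latent_logk", "choice_seed") |>
    purrr::pmap(function(participant_id, latent_logk, choice_seed) {
      simulate_choices(latent_logk, sched, v0 = cfg$v0,
                       temperature = cfg$choice_temperature,
                       seed = choice_seed) |>
        dplyr::mutate(participant_id = participant_id)
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("participant_id")

  participants$choice_seed <- NULL
  structure(
    list(participants = participants, choices = choices, config = cfg,
         config_hash = rlang::hash(cfg)),
    class = "sd_cohort"
  )
}

#' @export
print.sd_cohort <- function(x, ...) {
  cat("<sd_cohort> ", nrow(x$participants), " participants (",
      sum(x$participants$group == "control"), " control, ",
      sum(x$participants$group == "high"), " high), ",
      nrow(x$choices), " choices; seed ", x$config$seed,
      ", hash ", substr(x$config_hash, 1, 8), "\n", sep = "")
  invisible(x)
}
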