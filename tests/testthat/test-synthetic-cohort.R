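test_that("cohort generation is deterministic and respects group sizes", {
  cfg <- cohort_config(n_control = 30, n_high = 20, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$choices, b$choices)
  expect_identical(a$config_hash, b$config_hash)
  expect_equal(sum(a$participants$group == "control"), 30)
  expect_equal(sum(a$participants$group == "high"), 20)
  expect_equal(nrow(a$choices), 50 * 63)
  # different seed, different draws
  c2 <- generate_cohort(cohort_config(n_control = 30, n_high = 20, seed = 43))
  expect_false(identical(a$participants$tripm_total, c2$participants$tripm_total))
})

test_that("configured moments are recovered at n = 500 per group", {
  cfg <- cohort_config(n_control = 500, n_high = 500,
                       logk_mean_by_group = c(-3, -1.5), logk_sd = 1,
                       seed = 99)
  co <- generate_cohort(cfg)
  p <- co$participants
  for (g in 1:2) {
    grp <- p[p$group == c("control", "high")[g], ]
    se_t <- cfg$tripm_sd_by_group[g] / sqrt(500)
    expect_lt(abs(mean(grp$tripm_total) - cfg$tripm_mean_by_group[g]), 3 * se_t)
    expect_lt(abs(mean(grp$latent_logk) - cfg$logk_mean_by_group[g]),
              3 * cfg$logk_sd / sqrt(500))
  }
  # standardized latent group difference within +/- 0.15 of 1.5
  d_std <- (mean(p$latent_logk[p$group == "high"]) -
            mean(p$latent_logk[p$group == "control"])) / 1
  expect_lt(abs(d_std - 1.5), 0.15)
  # subscales decompose the total exactly (zero-sum noise construction)
  expect_equal(p$tripm_boldness + p$tripm_meanness + p$tripm_disinhibition,
               p$tripm_total)
})

test_that("choice simulation follows the logistic value rule", {
  # deterministic threshold at temperature 0: v_N = 40 -> switch at $115
  ch <- simulate_choices(latent_logk = 0, v0 = 80, temperature = 0)
  blk <- ch[ch$social_distance == 1, ] # v_1 = 80 / (1 + 1) = 40
  expect_equal(blk$choice, ifelse(blk$selfish_amount - 75 <= 40,
                                  "generous", "selfish"))
  blk_ip <- extract_indifference(blk$choice)
  expect_equal(blk_ip$indifference_point, 115)
  # k -> Inf: every v_N ~ 0, all selfish at every N >= 1
  ch_inf <- simulate_choices(latent_logk = 30, temperature = 0)
  expect_true(all(ch_inf$choice[ch_inf$selfish_amount > 75] == "selfish"))
  # huge temperature: generous frequency -> 0.5
  freq <- mean(vapply(1:40, function(s) {
    mean(simulate_choices(-2, temperature = 1e6, seed = s)$choice == "generous")
  }, numeric(1)))
  expect_lt(abs(freq - 0.5), 0.05)
})

test_that("group assignment applies gender-specific cutoffs at the boundary", {
  cuts <- c(male = 105, female = 91, other = 91)
  d <- tibble::tibble(
    tripm_total = c(105, 104, 91, 90, 300),
    gender = c("male", "male", "female", "female", "other")
  )
  got <- assign_group(d, cuts)$group
  expect_equal(got, c("high", "control", "high", "control", "high"))
  expect_error(assign_group(tibble::tibble(tripm_total = 1, gender = "x"), cuts),
               "no TriPM cutoff")
})

test_that("attention-check exclusions drop >= 2 of 4 failures with reasons", {
  d <- tibble::tibble(participant_id = paste0("P", 1:5),
                      attention_failures = c(0, 1, 2, 3, 4))
  res <- apply_exclusions(d)
  expect_equal(res$retained$participant_id, c("P1", "P2"))
  expect_equal(res$excluded$participant_id, c("P3", "P4", "P5"))
  expect_match(res$excluded$reason[1], "2 of 4")
  expect_error(apply_exclusions(tibble::tibble(participant_id = "P1",
                                               attention_failures = 5)),
               "0-4")
})

test_that("don't-know income is recoded to the round-half-up mean bracket", {
  d <- tibble::tibble(income_bracket = c(2, 2, 4, NA))
  expect_equal(recode_income(d)$income_bracket, c(2, 2, 4, 3)) # 8/3 -> 3
  d5 <- tibble::tibble(income_bracket = c(5, 5, NA))
  expect_equal(recode_income(d5)$income_bracket, c(5, 5, 5))
  known <- tibble::tibble(income_bracket = c(1, 8))
  expect_identical(recode_income(known), known) # no-op without don't-knows
  # round-half-up at the .5 boundary: mean(2, 3) = 2.5 -> 3
  expect_equal(recode_income(tibble::tibble(income_bracket = c(2, 3, NA)))$income_bracket[3], 3)
  expect_error(recode_income(tibble::tibble(income_bracket = NA_real_)),
               "don't know")
})

test_that("invalid configs fail naming the offending field", {
  expect_error(cohort_config(n_control = 0), "n_control")
  expect_error(cohort_config(logk_sd = -1), "logk_sd")
  expect_error(cohort_config(choice_temperature = -0.1), "choice_temperature")
  expect_error(cohort_config(tripm_mean_by_group = 1:3), "tripm_mean_by_group")
})

test_that("the planted indirect path is recovered by the mediation engine", {
  cfg <- cohort_config(n_control = 500, n_high = 500, seed = 314)
  p <- generate_cohort(cfg)$participants
  p$group_high <- as.numeric(p$group == "high")
  med <- mediate_effects(p, outcome = "stab_total", mediator = "latent_logk",
                         treatment = "group_high", sims = 500, seed = 27)
  eff <- tidy(med)
  truth <- diff(cfg$logk_mean_by_group) * cfg$stab_coefs[["logk"]] # a x b
  acme <- eff[eff$effect == "acme", ]
  mc_halfwidth <- (acme$ci_high - acme$ci_low) / 2
  expect_lt(abs(acme$estimate - truth), mc_halfwidth)
  # null indirect path by construction: logk coefficient zero
  cfg0 <- cohort_config(n_control = 300, n_high = 300, seed = 314,
                        stab_coefs = c(intercept = 63.3, group = 35.0,
                                       logk = 0.0, sigma = 18.0))
  p0 <- generate_cohort(cfg0)$participants
  p0$group_high <- as.numeric(p0$group == "high")
  eff0 <- tidy(mediate_effects(p0, "stab_total", "latent_logk", "group_high",
                               sims = 500, seed = 27))
  acme0 <- eff0[eff0$effect == "acme", ]
  expect_true(acme0$ci_low <= 0 && 0 <= acme0$ci_high)
})
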