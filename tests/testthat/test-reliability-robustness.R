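test_that("Cronbach's alpha matches the covariance formula on a toy table", {
  # 5 x 3 spreadsheet-style oracle: direct variances/covariances
  items <- tibble::tibble(i1 = c(2, 4, 4, 5, 7),
                          i2 = c(3, 4, 5, 5, 6),
                          i3 = c(1, 5, 4, 6, 7))
  m <- 3
  want <- (m / (m - 1)) *
    (1 - (stats::var(items$i1) + stats::var(items$i2) + stats::var(items$i3)) /
       stats::var(items$i1 + items$i2 + items$i3))
  got <- cronbach_alpha(items)
  expect_equal(got$value, want, tolerance = 1e-12)
  expect_lte(got$value, 1)
  # identical items: alpha = 1
  x <- stats::rnorm(10)
  expect_equal(cronbach_alpha(data.frame(a = x, b = x, c = x))$value, 1)
  # equal variances, zero covariances: alpha = 0
  ortho <- data.frame(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1),
                      c = c(1, -1, -1, 1))
  expect_equal(cronbach_alpha(ortho)$value, 0)
  # invariant to adding a constant to one item
  shifted <- items; shifted$i2 <- shifted$i2 + 100
  expect_equal(cronbach_alpha(shifted)$value, got$value)
  expect_error(cronbach_alpha(items[1, ]), ">= 2 items")
  expect_error(cronbach_alpha(data.frame(a = rep(1, 5), b = rep(2, 5))),
               "zero variance")
})

test_that("ICC(1,1) matches a hand one-way ANOVA oracle", {
  # 4 targets x 2 raters; mean squares computed from first principles
  r <- rbind(c(9, 10), c(6, 5), c(8, 8), c(2, 3))
  n <- 4; k <- 2
  grand <- mean(r)
  msb <- k * sum((rowMeans(r) - grand)^2) / (n - 1)
  msw <- sum((r - rowMeans(r))^2) / (n * (k - 1))
  want <- (msb - msw) / (msb + (k - 1) * msw)
  got <- icc_oneway(r)
  expect_equal(got$value, want, tolerance = 1e-12)
  expect_true(got$ci_low < got$value && got$value < got$ci_high)
  # perfect agreement with between-target spread: ICC = 1
  perfect <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_oneway(perfect)$value, 1)
  # identical targets + rater noise: ICC <= 0 on average
  set.seed(8)
  vals <- vapply(1:40, function(i) {
    icc_oneway(matrix(stats::rnorm(20), ncol = 2))$value
  }, numeric(1))
  expect_lt(mean(vals), 0.15)
  # invariant to adding a constant to all ratings
  expect_equal(icc_oneway(r + 50)$value, got$value)
  expect_error(icc_oneway(matrix(1, 3, 2)), "degenerate")
})

test_that("k-fold CV partitions deterministically and predicts well-specified data", {
  set.seed(5)
  d <- tibble::tibble(x = stats::rnorm(100), y = stats::rnorm(100))
  cv1 <- kfold_cv(d, "y", "x", k = 10, seed = 3)
  cv2 <- kfold_cv(d, "y", "x", k = 10, seed = 3)
  expect_identical(cv1$folds, cv2$folds)
  sizes <- cv1$folds |>
    dplyr::distinct(fold, n_test)
  expect_equal(sort(sizes$n_test), rep(10, 10))
  expect_error(kfold_cv(d[1:5, ], "y", "x", k = 10), "k <= n")
  # well-specified model: out-of-fold R^2 near in-sample adjusted R^2
  set.seed(6)
  big <- tibble::tibble(x = stats::rnorm(2000), z = stats::rnorm(2000))
  big$y <- 1 + 0.8 * big$x - 0.5 * big$z + stats::rnorm(2000)
  cv <- kfold_cv(big, "y", c("x", "z"), k = 10, seed = 4)
  in_sample <- glance(fit_ols(big, "y", c("x", "z")))$adj_r2
  expect_lt(abs(cv$oof_r2 - in_sample), 0.05)
})

test_that("greedy propensity matching agrees with a brute-force oracle", {
  # toy: 3 treated, 5 controls; oracle enumerates greedily in treated order
  d <- tibble::tibble(
    participant_id = sprintf("P%d", 1:8),
    tr = c(1, 1, 1, 0, 0, 0, 0, 0),
    x = c(2.0, 1.0, 0.5, 1.9, 1.2, 0.4, -0.5, 2.2)
  )
  res <- propensity_match(d, "tr", "x", caliper = 5)
  # oracle on the same logit scores, descending treated score order
  ps <- stats::glm(tr ~ x, data = d, family = stats::binomial())
  lp <- stats::predict(ps, type = "link")
  cal <- 5 * stats::sd(lp)
  t_ord <- order(-lp[1:3])
  want <- oracle_greedy_match(lp[1:3], lp[4:8], t_ord, cal)
  expect_equal(nrow(res$pairs), nrow(want))
  got_pairs <- res$pairs[order(res$pairs$treated_id), ]
  want_ids <- tibble::tibble(
    treated_id = d$participant_id[want[, "treated"]],
    control_id = d$participant_id[3 + want[, "control"]]
  )
  want_ids <- want_ids[order(want_ids$treated_id), ]
  expect_equal(got_pairs$treated_id, want_ids$treated_id)
  expect_equal(got_pairs$control_id, want_ids$control_id)
})

test_that("matching never reuses controls and respects the caliper", {
  set.seed(30)
  n <- 300
  d <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n),
    tr = rep(c(1, 0), c(100, 200)),
    age = stats::rnorm(n, 40 - 5 * rep(c(1, 0), c(100, 200)), 8),
    iq = stats::rnorm(n, 5, 2)
  )
  res <- propensity_match(d, "tr", c("age", "iq"))
  expect_equal(anyDuplicated(res$pairs$control_id), 0)
  expect_true(all(res$pairs$distance <= res$caliper))
  expect_equal(nrow(res$pairs) + length(res$unmatched_treated), 100)
  # exchangeable covariates: post-match SMDs small
  set.seed(31)
  bal <- tibble::tibble(participant_id = sprintf("B%03d", 1:400),
                        tr = rep(c(1, 0), 200),
                        age = stats::rnorm(400), iq = stats::rnorm(400))
  res_bal <- propensity_match(bal, "tr", c("age", "iq"))
  expect_true(all(abs(res_bal$smd$smd_after) < 0.1))
  # caliper 0: generically nothing matches
  expect_warning(res0 <- propensity_match(d, "tr", c("age", "iq"), caliper = 0),
                 "caliper")
  expect_equal(nrow(res0$pairs), 0)
})

test_that("a planted group effect survives matched-subsample regression", {
  for (s in 1:3) {
    cfg <- cohort_config(n_control = 120, n_high = 80, seed = 400 + s)
    co <- generate_cohort(cfg)
    p <- co$participants
    p$group_high <- as.numeric(p$group == "high")
    p$logk <- p$latent_logk # latent stands in for fitted rates here
    m <- propensity_match(p, "group_high",
                          c("age", "gender", "fluid_intelligence"))
    td <- tidy(fit_ols(m$matched_data, "logk", "group_high",
                       c("age", "gender", "fluid_intelligence")))
    expect_gt(td$b[td$term == "group_high"], 0)
  }
})
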