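test_that("model_value evaluates the three families", {
  expect_equal(model_value("hyperbolic", 80, 0, 50), 80)
  expect_equal(model_value("hyperbolic", 80, 1, 1), 40)
  expect_equal(model_value("hyperbolic", 80, 0.05, 100), 80 / 6)
  expect_equal(model_value("exponential", 80, 0.1, 10), 80 * exp(-1))
  expect_equal(model_value("linear", 80, 1, 100), 0) # clipped at zero
  expect_error(model_value("cubic", 80, 1, 1))
})

test_that("noiseless hyperbolic profiles are recovered exactly", {
  for (k_true in c(0.01, 0.05, 0.3)) {
    prof <- noiseless_profile(k_true)
    fit <- fit_discounting(prof)
    expect_equal(fit$k, k_true, tolerance = 1e-4)
    expect_equal(fit$v0, 80, tolerance = 1e-3)
    expect_lt(fit$rss, 1e-6)
    expect_true(fit$converged)
    expect_false(fit$k_floored)
  }
})

test_that("flat and degenerate profiles hit the configured bounds", {
  flat <- noiseless_profile(0 + 1e-12) # v = 80 everywhere
  flat$v <- rep(80, 7)
  fit <- fit_discounting(flat)
  expect_true(fit$k_floored)
  expect_equal(fit$logk, log(1e-6))
  zero <- flat
  zero$v <- rep(0, 7)
  fit0 <- fit_discounting(zero)
  expect_true(fit0$degenerate)
  expect_true(fit0$converged)
})

test_that("noisy fits agree with a dense grid-search oracle", {
  set.seed(2024)
  n <- social_distances()
  for (rep in 1:25) {
    k_true <- 10^stats::runif(1, -3, -0.5)
    v <- model_value("hyperbolic", 80, k_true, n) + stats::rnorm(7, 0, 5)
    prof <- tibble::tibble(participant_id = "P1", social_distance = n, v = v)
    fit <- fit_discounting(prof)
    oracle <- oracle_grid_fit(n, v, "hyperbolic")
    # the optimizer should do at least as well as the dense grid, and land
    # within one grid step of the oracle's k
    grid_step <- 7 / 599 # log10 spacing of the oracle grid
    expect_lte(fit$rss, oracle$rss * (1 + 1e-3))
    expect_lt(abs(log10(fit$k) - log10(oracle$k)), 2 * grid_step + 1e-6)
  }
})

test_that("median k error shrinks as noise vanishes and logk correlates at sigma 5", {
  n <- social_distances()
  k_true <- 0.05
  med_err <- vapply(c(0, 2, 5), function(sigma) {
    set.seed(300 + sigma)
    errs <- vapply(1:60, function(i) {
      v <- model_value("hyperbolic", 80, k_true, n) + stats::rnorm(7, 0, sigma)
      prof <- tibble::tibble(participant_id = "P1", social_distance = n,
                             v = pmin(pmax(v, 0), 80))
      abs(fit_discounting(prof)$k - k_true)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_lt(med_err[1], 1e-5)
  expect_true(all(diff(med_err) >= -1e-9)) # bias grows with noise
  # logk recovery correlation > 0.9 at sigma = 5 over 200 participants
  set.seed(77)
  logk_true <- stats::rnorm(200, -3, 1)
  logk_hat <- vapply(logk_true, function(lk) {
    v <- model_value("hyperbolic", 80, exp(lk), n) + stats::rnorm(7, 0, 5)
    prof <- tibble::tibble(participant_id = "P1", social_distance = n,
                           v = pmin(pmax(v, 0), 80))
    fit_discounting(prof)$logk
  }, numeric(1))
  expect_gt(stats::cor(logk_true, logk_hat), 0.9)
})

test_that("pooled fit equals the per-participant fit for one participant", {
  prof <- noiseless_profile(0.07)
  prof$v <- prof$v + c(1, -2, 0.5, 1, -1, 0, 2)
  single <- fit_discounting(prof)
  pooled <- fit_pooled(prof)
  expect_equal(pooled$k, single$k, tolerance = 1e-8)
  expect_equal(pooled$aic, single$aic, tolerance = 1e-8)
})

test_that("Akaike weights follow the closed form and sum to one", {
  # printed-value worked example: hyperbolic wins with weight 1.00
  cmp <- compare_models(c(hyperbolic = 46142.77, exponential = 49021.74,
                          linear = 48269.92))
  expect_equal(attr(cmp, "best_family"), "hyperbolic")
  expect_equal(round(cmp$akaike_weight[cmp$family == "hyperbolic"], 2), 1)
  expect_equal(cmp$delta_aic[cmp$family == "linear"], 2127.15)
  expect_equal(cmp$delta_aic[cmp$family == "exponential"], 2878.97)
  # symmetry and the e^1 ratio
  eq <- compare_models(c(a = 100, b = 100, c = 100))
  expect_equal(eq$akaike_weight, rep(1 / 3, 3))
  two <- compare_models(c(a = 100, b = 102))
  expect_equal(two$akaike_weight[1] / two$akaike_weight[2], exp(1))
  # invariants: weights sum to 1, permutation-equivariant
  set.seed(1)
  for (i in 1:20) {
    aics <- stats::setNames(stats::runif(3, 100, 200), c("x", "y", "z"))
    w <- compare_models(aics)
    expect_equal(sum(w$akaike_weight), 1)
    perm <- compare_models(aics[c(3, 1, 2)])
    expect_equal(dplyr::arrange(w, family)$akaike_weight,
                 dplyr::arrange(perm, family)$akaike_weight)
  }
  expect_error(compare_models(c(a = 1)), "at least 2")
  expect_error(compare_models(c(a = 1, b = Inf)), "non-finite")
})

test_that("logk is the natural log with a floor contract", {
  expect_equal(compute_logk(1), 0)
  expect_equal(compute_logk(exp(1)), 1)
  expect_equal(compute_logk(1e-6), -13.8155, tolerance = 1e-4)
  expect_error(compute_logk(1e-8), "floor")
})

test_that("AUC matches hand trapezoids and decreases with k", {
  n <- social_distances()
  full <- tibble::tibble(participant_id = 1, social_distance = n, v = rep(80, 7))
  expect_equal(compute_auc(full)$auc, 1)
  none <- dplyr::mutate(full, v = 0)
  expect_equal(compute_auc(none)$auc, 0)
  spike <- dplyr::mutate(full, v = c(80, rep(0, 6)))
  expect_equal(compute_auc(spike)$auc, 0.5 * 80 * (2 - 1) / (99 * 80))
  # monotone non-increasing in k for noiseless hyperbolic profiles
  aucs <- vapply(10^seq(-4, 0.5, length.out = 12), function(k) {
    compute_auc(noiseless_profile(k))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  expect_error(compute_auc(tibble::tibble(participant_id = 1,
                                          social_distance = 1, v = 1)),
               "2 points")
})

test_that("each generating family is selected by pooled AIC", {
  # scaled-down check; the acceptance suite runs the 100-replicate version
  set.seed(505)
  n <- social_distances()
  params <- list(hyperbolic = 0.08, exponential = 0.03, linear = 0.6)
  for (fam in names(params)) {
    wins <- 0
    for (r in 1:20) {
      profs <- dplyr::bind_rows(lapply(1:15, function(i) {
        v <- model_value(fam, 80, params[[fam]] * stats::runif(1, 0.8, 1.25), n) +
          stats::rnorm(7, 0, 5)
        tibble::tibble(participant_id = i, social_distance = n,
                       v = pmin(pmax(v, 0), 80))
      }))
      pooled <- dplyr::bind_rows(lapply(names(params), function(f) {
        fit_pooled(profs, f)
      }))
      wins <- wins + (attr(compare_models(pooled), "best_family") == fam)
    }
    expect_gte(wins, 18)
  }
})
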