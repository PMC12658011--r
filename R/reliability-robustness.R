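#' Cronbach's alpha internal consistency
#'
#' alpha = (m / (m - 1)) (1 - sum of item variances / variance of the item
#' sums) for m items. The 95% CI uses the Feldt F-distribution bounds.
#'
#' @param items A data frame or matrix, one row per unit, one column per
#'   item; no missing values.
#' @return One-row tibble: `statistic` (`"alpha"`), `value`, `ci_low`,
#'   `ci_high`, `n_units`, `n_items`.
#' @examples
#' x <- rnorm(20)
#' cronbach_alpha(data.frame(a = x, b = x + rnorm(20, 0, 0.3),
#'                           c = x + rnorm(20, 0, 0.3)))
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  m <- ncol(items)
  n <- nrow(items)
  if (m < 2 || n < 3) stop("need >= 2 items and >= 3 units", call. = FALSE)
  if (anyNA(items)) stop("missing values in item table", call. = FALSE)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero variance of item sums", call. = FALSE)
  alpha <- (m / (m - 1)) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  # Feldt (1965) CI: (1 - alpha) scales as an F(n-1, (n-1)(m-1)) variate
  df1 <- n - 1
  df2 <- (n - 1) * (m - 1)
  ci_low <- 1 - (1 - alpha) * stats::qf(0.975, df1, df2)
  ci_high <- 1 - (1 - alpha) * stats::qf(0.025, df1, df2)
  tibble::tibble(statistic = "alpha", value = alpha,
                 ci_low = ci_low, ci_high = ci_high,
                 n_units = n, n_items = m)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Single-rater, absolute-agreement ICC from a one-way random-effects
#' ANOVA: ICC = (MSB - MSW) / (MSB + (k - 1) MSW), with MSB/MSW the
#' between- and within-target mean squares and k the raters per target. The
#' 95% CI uses the standard F-distribution bounds for ICC(1,1).
#'
#' @param ratings A data frame or matrix, one row per target, one column per
#'   rater (>= 2 of each); no missing values.
#' @return One-row tibble: `statistic` (`"icc1"`), `value`, `ci_low`,
#'   `ci_high`, `p` (one-sided F test of ICC = 0), `n_targets`, `n_raters`.
#' @export
icc_oneway <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  if (anyNA(x)) stop("missing values in rating table", call. = FALSE)
  row_means <- rowMeans(x)
  grand <- mean(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((x - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    stop("degenerate ratings: no between- or within-target variance",
         call. = FALSE)
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f_obs <- msb / msw
  df1 <- n - 1
  df2 <- n * (k - 1)
  f_low <- f_obs / stats::qf(0.975, df1, df2)
  f_high <- f_obs * stats::qf(0.975, df2, df1)
  tibble::tibble(
    statistic = "icc1", value = icc,
    ci_low = (f_low - 1) / (f_low + k - 1),
    ci_high = (f_high - 1) / (f_high + k - 1),
    p = stats::pf(f_obs, df1, df2, lower.tail = FALSE),
    n_targets = n, n_raters = k
  )
}

#' k-fold cross-validation of a regression model
#'
#' Deterministically partitions the rows into k folds (sizes differing by at
#' most one), refits the model on each training set, and reports per-fold
#' coefficients plus the pooled out-of-fold R-squared
#' 1 - sum((y - yhat_oof)^2) / sum((y - mean(y))^2).
#'
#' @inheritParams fit_ols
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `folds` (tibble of per-fold coefficients and fold
#'   sizes), `coef_summary` (mean and SD of each coefficient across folds),
#'   and `oof_r2`.
#' @export
kfold_cv <- function(data, outcome, predictors, covariates = NULL,
                     k = 10L, seed = 1L) {
  n <- nrow(data)
  if (k > n || k < 2) stop("need 2 <= k <= n rows", call. = FALSE)
  fold_id <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  vars <- c(outcome, predictors, covariates)
  mf <- .model_frame(data, vars)
  rhs <- setdiff(vars, outcome)
  form <- stats::reformulate(sprintf("`%s`", rhs),
                             response = sprintf("`%s`", outcome))
  y <- mf[[outcome]]
  yhat <- numeric(n)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_id == f
    fit <- stats::lm(form, data = mf[!test, , drop = FALSE])
    yhat[test] <- stats::predict(fit, newdata = mf[test, , drop = FALSE])
    cf <- stats::coef(fit)
    names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = sum(test),
                                     term = names(cf), coef = unname(cf))
  }
  folds <- dplyr::bind_rows(fold_rows)
  list(
    folds = folds,
    coef_summary = folds |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(mean = mean(.data$coef), sd = stats::sd(.data$coef),
                       .groups = "drop"),
    oof_r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  )
}

#' Greedy 1:1 propensity-score matching with a caliper
#'
#' Fits a logistic propensity model of treatment on the covariates, then
#' matches each treated unit to the nearest control on the logit propensity
#' score, 1:1 without replacement, within a caliper expressed in SDs of the
#' logit score. Treated units are matched in descending propensity order
#' (hardest to match first), ties broken by id. Standardized mean
#' differences (difference in means over the pre-match pooled SD) are
#' reported per covariate before and after matching.
#'
#' @param data A data frame with an id column `participant_id` (created if
#'   absent).
#' @param treatment Binary treatment column name.
#' @param covariates Character vector of covariate column names.
#' @param caliper Caliper width in logit-propensity SD units (default 0.2).
#' @param seed Unused (the greedy match is deterministic); kept so every
#'   robustness routine shares the same signature.
#' @return A list of class `sd_match`: `pairs` (tibble `treated_id`,
#'   `control_id`, `distance`), `smd` (tibble `covariate`, `smd_before`,
#'   `smd_after`), `unmatched_treated` (ids), `caliper`, `matched_data`
#'   (the matched subsample of `data`).
#' @export
propensity_match <- function(data, treatment, covariates, caliper = 0.2,
                             seed = 1L) {
  if (!"participant_id" %in% names(data)) {
    data$participant_id <- sprintf("row%05d", seq_len(nrow(data)))
  }
  mf <- .model_frame(data, c(treatment, covariates))
  tr <- mf[[treatment]]
  if (length(unique(tr)) != 2) {
    stop("both treatment classes must be present", call. = FALSE)
  }
  form <- stats::reformulate(sprintf("`%s`", covariates),
                             response = sprintf("`%s`", treatment))
  ps_fit <- suppressWarnings(stats::glm(form, data = mf,
                                        family = stats::binomial()))
  lp <- stats::predict(ps_fit, type = "link") # logit propensity
  cal <- caliper * stats::sd(lp)

  ids <- data$participant_id
  t_idx <- which(tr == 1)
  c_idx <- which(tr == 0)
  # hardest-to-match first: descending treated logit PS; ties by id
  t_idx <- t_idx[order(-lp[t_idx], ids[t_idx])]

  available <- rep(TRUE, length(c_idx))
  pairs <- vector("list", length(t_idx))
  unmatched <- character()
  for (i in seq_along(t_idx)) {
    ti <- t_idx[i]
    d <- abs(lp[c_idx] - lp[ti])
    d[!available] <- Inf
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[order(ids[c_idx[j]])][1]
    if (!is.finite(d[j]) || d[j] > cal) {
      unmatched <- c(unmatched, ids[ti])
      next
    }
    available[j] <- FALSE
    pairs[[i]] <- tibble::tibble(treated_id = ids[ti],
                                 control_id = ids[c_idx[j]],
                                 distance = d[j])
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(treated_id = character(), control_id = character(),
                            distance = numeric())
    warning("no treated unit found a control within the caliper",
            call. = FALSE)
  }

  smd_one <- function(x, t, sd_ref) {
    (mean(x[t == 1]) - mean(x[t == 0])) / sd_ref
  }
  matched_ids <- c(pairs$treated_id, pairs$control_id)
  keep <- ids %in% matched_ids
  smd <- purrr::map_dfr(covariates, function(cv) {
    x <- mf[[cv]]
    sd_ref <- sqrt((stats::var(x[tr == 1]) + stats::var(x[tr == 0])) / 2)
    tibble::tibble(
      covariate = cv,
      smd_before = smd_one(x, tr, sd_ref),
      smd_after = if (any(keep)) smd_one(x[keep], tr[keep], sd_ref) else NA_real_
    )
  })

  structure(
    list(pairs = pairs, smd = smd, unmatched_treated = unmatched,
         caliper = cal, caliper_sd_units = caliper,
         matched_data = data[keep, , drop = FALSE],
         propensity_model = ps_fit),
    class = "sd_match"
  )
}

#' @export
print.sd_match <- function(x, ...) {
  cat("<sd_match> ", nrow(x$pairs), " pairs, ",
      length(x$unmatched_treated), " unmatched treated; caliper ",
      format(x$caliper_sd_units), " logit-PS SDs\n", sep = "")
  print(x$smd)
  invisible(x)
}
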