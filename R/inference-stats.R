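#' Welch two-sample t-test with Cohen's d
#'
#' Two-tailed Welch t-test (Welch-Satterthwaite fractional df) comparing a
#' continuous outcome between two groups, with a standardized mean
#' difference. Cohen's d uses the pooled SD even though the test is Welch;
#' its 95% CI uses the usual normal approximation
#' se_d = sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))).
#'
#' @param data A data frame.
#' @param outcome Name of the continuous outcome column (string).
#' @param group Name of a two-level grouping column. The difference is taken
#'   first level minus second level (levels sorted unless the column is a
#'   factor).
#' @return One-row tibble: `statistic_kind`, `statistic`, `df`, `p`,
#'   `cohens_d`, `d_ci_low`, `d_ci_high`, `mean_1`, `mean_2`, `n_1`, `n_2`.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 3, 4, 5, 6),
#'                     g = rep(c("a", "b"), each = 4))
#' welch_test(d, "y", "g")
#' @export
welch_test <- function(data, outcome, group) {
  g <- data[[group]]
  lev <- if (is.factor(g)) levels(g) else sort(unique(g))
  if (length(lev) != 2) stop("group must have exactly two levels", call. = FALSE)
  x <- data[[outcome]][g == lev[1]]
  y <- data[[outcome]][g == lev[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  tibble::tibble(
    statistic_kind = "welch_t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = d,
    d_ci_low = d - stats::qnorm(0.975) * se_d,
    d_ci_high = d + stats::qnorm(0.975) * se_d,
    mean_1 = mean(x), mean_2 = mean(y), n_1 = n1, n_2 = n2
  )
}

#' Pearson chi-squared test on a contingency table
#'
#' Chi-squared test of independence without continuity correction (the
#' samples these tables come from are large).
#'
#' @param data A data frame (rows are observations) or a 2-D count table /
#'   matrix.
#' @param var,group Column names when `data` is a data frame; ignored for a
#'   count table.
#' @return One-row tibble: `statistic_kind`, `statistic`, `df`, `p`.
#' @examples
#' chi_squared_test(matrix(c(20, 10, 10, 20), nrow = 2))
#' @export
chi_squared_test <- function(data, var = NULL, group = NULL) {
  tab <- if (is.matrix(data) || is.table(data)) {
    as.table(as.matrix(data))
  } else {
    table(data[[var]], data[[group]])
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic_kind = "chi_squared",
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value
  )
}

# z-score every column of a numeric model frame
.zscore_df <- function(df) {
  as.data.frame(lapply(df, function(col) {
    s <- stats::sd(col)
    if (s == 0) col - mean(col) else (col - mean(col)) / s
  }))
}

# Build the numeric model frame used by the regression functions: gender is
# recoded to a male-vs-(female/other) indicator, everything else is numeric.
.model_frame <- function(data, vars) {
  out <- lapply(vars, function(v) {
    col <- data[[v]]
    if (is.null(col)) stop("column '", v, "' not found", call. = FALSE)
    if (v == "gender" || is.character(col) || is.factor(col)) {
      col <- as.character(col)
      if (v == "gender") {
        as.numeric(col == "male") # female/other is the reference
      } else {
        lev <- sort(unique(col))
        if (length(lev) != 2) {
          stop("categorical predictor '", v, "' must have 2 levels", call. = FALSE)
        }
        as.numeric(col == lev[2])
      }
    } else {
      as.numeric(col)
    }
  })
  names(out) <- vars
  as.data.frame(out)
}

#' Multiple regression with fully standardized coefficients
#'
#' Ordinary least squares of an outcome on predictors plus covariates,
#' reporting both unstandardized coefficients and "Std. B" coefficients
#' obtained by z-scoring every variable before fitting — including the
#' outcome and binary indicators (group, gender), the convention under
#' which a binary group term can have b = 1.56 but Std. B = 0.38. Gender is
#' coded male vs female/other (female/other the reference); income enters as
#' the ordinal numeric bracket. Two-tailed p-values throughout.
#'
#' @param data A data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of focal predictor column names.
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @return An object of class `sd_ols`: use [tidy()] for the term table
#'   (`term`, `b`, `se`, `ci_low`, `ci_high`, `std_b`, `std_se`,
#'   `std_ci_low`, `std_ci_high`, `p`) and [glance()] for `model_f`, `df1`,
#'   `df2`, `model_p`, `adj_r2`, `n`.
#' @examples
#' d <- tibble::tibble(x = c(0, 1, 2, 3), y = c(1, 3, 5, 7))
#' tidy(fit_ols(d, "y", "x"))
#' @export
fit_ols <- function(data, outcome, predictors, covariates = NULL) {
  vars <- c(outcome, predictors, covariates)
  mf <- .model_frame(data, vars)
  if (!all(stats::complete.cases(mf))) {
    stop("missing values in model variables", call. = FALSE)
  }
  rhs <- setdiff(vars, outcome)
  form <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", outcome))
  fit <- stats::lm(form, data = mf)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit_std <- stats::lm(form, data = .zscore_df(mf))
  structure(
    list(fit = fit, fit_std = fit_std, outcome = outcome,
         predictors = predictors, covariates = covariates,
         formula = deparse(form)),
    class = "sd_ols"
  )
}

#' @rdname fit_ols
#' @param x An `sd_ols` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sd_ols <- function(x, ...) {
  su <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit)
  ss <- summary(x$fit_std)$coefficients
  cis <- stats::confint(x$fit_std)
  tibble::tibble(
    term = gsub("`", "", rownames(su), fixed = TRUE),
    b = unname(su[, 1]), se = unname(su[, 2]),
    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
    std_b = unname(ss[, 1]), std_se = unname(ss[, 2]),
    std_ci_low = unname(cis[, 1]), std_ci_high = unname(cis[, 2]),
    p = unname(su[, 4])
  )
}

#' @rdname fit_ols
#' @exportS3Method generics::glance
glance.sd_ols <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    model_f = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
    model_p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    adj_r2 = s$adj.r.squared,
    n = length(stats::residuals(x$fit))
  )
}

#' @export
print.sd_ols <- function(x, ...) {
  cat("<sd_ols> ", x$formula, "\n", sep = "")
  print(tidy.sd_ols(x))
  invisible(x)
}

#' Moderation model: focal x moderator interaction
#'
#' Fits the standardized regression of the outcome on the focal predictor,
#' the moderator, their product and covariates. The interaction term is the
#' product of the two z-scored variables (itself entered unscaled), so its
#' coefficient is read on the standardized scale.
#'
#' @inheritParams fit_ols
#' @param focal,moderator Column names of the interacting variables.
#' @return An `sd_ols` object whose term table contains
#'   `<focal>:<moderator>`.
#' @export
fit_moderation <- function(data, outcome, focal, moderator, covariates = NULL) {
  vars <- c(outcome, focal, moderator, covariates)
  mf <- .model_frame(data, vars)
  modsd <- stats::sd(mf[[moderator]])
  focsd <- stats::sd(mf[[focal]])
  if (modsd == 0 || focsd == 0) {
    stop("moderation model is degenerate: '",
         if (modsd == 0) moderator else focal,
         "' is constant (collinear with the intercept)", call. = FALSE)
  }
  inter <- paste0(focal, ":", moderator)
  mf_raw <- mf
  mf_raw[[inter]] <- mf[[focal]] * mf[[moderator]]
  mf_std <- .zscore_df(mf)
  mf_std[[inter]] <- mf_std[[focal]] * mf_std[[moderator]]
  rhs <- c(setdiff(vars, outcome), inter)
  form <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", outcome))
  structure(
    list(fit = stats::lm(form, data = mf_raw),
         fit_std = stats::lm(form, data = mf_std),
         outcome = outcome, predictors = c(focal, moderator, inter),
         covariates = covariates, formula = deparse(form)),
    class = "sd_ols"
  )
}

#' Covariate-adjusted odds ratio from logistic regression
#'
#' Maximum-likelihood logistic regression of a binary outcome on group plus
#' covariates; the group odds ratio is exp(coefficient) with a Wald 95% CI.
#' Without covariates this reproduces the 2x2 cross-product odds ratio.
#'
#' @inheritParams fit_ols
#' @param outcome Binary outcome column (0/1 or logical).
#' @param group Column whose odds ratio is reported (binary).
#' @return One-row tibble: `or_value`, `ci_low`, `ci_high`, `p`,
#'   `adjusted_for`.
#' @export
fit_logistic_or <- function(data, outcome, group, covariates = NULL) {
  vars <- c(outcome, group, covariates)
  mf <- .model_frame(data, vars)
  y <- mf[[outcome]]
  if (length(unique(y)) != 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  rhs <- setdiff(vars, outcome)
  form <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", outcome))
  fit <- suppressWarnings(stats::glm(form, data = mf, family = stats::binomial()))
  su <- summary(fit)$coefficients
  rownames(su) <- gsub("`", "", rownames(su), fixed = TRUE)
  if (any(abs(su[, 1]) > 15)) {
    stop("(quasi-)complete separation detected; a penalized fit would be ",
         "needed (not implemented)", call. = FALSE)
  }
  b <- su[group, 1]; se <- su[group, 2]
  z <- stats::qnorm(0.975)
  tibble::tibble(
    or_value = exp(b),
    ci_low = exp(b - z * se),
    ci_high = exp(b + z * se),
    p = su[group, 4],
    adjusted_for = paste(covariates %||% character(), collapse = ",")
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise alpha (0 < alpha < 1).
#' @param m Number of comparisons (>= 1).
#' @return `family_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 3) # 0.0167
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(m >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / m
}
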