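#' Simulation-based causal mediation analysis
#'
#' Decomposes the effect of a treatment on an outcome into the average
#' causal mediation effect (ACME, the indirect path through the mediator),
#' the average direct effect (ADE) and their sum, the total effect, plus the
#' proportion mediated (ACME / total). Two linear models are fitted on the
#' same rows: the mediator model (mediator ~ treatment + covariates) and the
#' outcome model (outcome ~ treatment + mediator + covariates; no
#' treatment-mediator interaction), so per draw ACME = a * b * (t1 - t0) and
#' ADE = c' * (t1 - t0), where a is the treatment coefficient in the
#' mediator model and b, c' are the mediator and treatment coefficients in
#' the outcome model.
#'
#' Uncertainty is simulation-based:
#' * `quasi_bayesian` (default) — draw parameter vectors from each fitted
#'   model's asymptotic multivariate normal and recompute the effects per
#'   draw;
#' * `bootstrap` — resample rows with replacement and refit both models.
#'
#' Point estimates are means over draws, so `acme + ade = total` holds
#' exactly. CIs are percentile intervals; two-tailed p-values are
#' 2 min(fraction of draws <= 0, fraction >= 0), floored at 2/sims. The
#' proportion mediated is summarised by the median across draws (ratio
#' draws are heavy-tailed) and, because its sign tracks the indirect path
#' whenever the total effect is bounded away from zero, it shares the ACME
#' p-value.
#'
#' For a binary treatment the contrast is 0 -> 1; for a continuous
#' treatment it is mean -/+ 1 SD.
#'
#' @param data A data frame containing all model variables.
#' @param outcome,mediator,treatment Column names.
#' @param covariates Character vector of covariate column names.
#' @param sims Number of simulation draws (>= 100).
#' @param seed Integer seed; results are reproducible given
#'   (data, sims, seed, method).
#' @param method `"quasi_bayesian"` or `"bootstrap"`.
#' @return An object of class `sd_mediation`; [tidy()] gives one row per
#'   effect (`acme`, `ade`, `total`, `prop_mediated`) with `estimate`,
#'   `ci_low`, `ci_high`, `p`.
#' @examples
#' d <- tibble::tibble(t = rep(0:1, 50),
#'                     m = rep(0:1, 50) + rnorm(100),
#'                     y = 0.5 * rep(0:1, 50) + 0.5 * (rep(0:1, 50) + rnorm(100)))
#' mediate_effects(d, outcome = "y", mediator = "m", treatment = "t",
#'                 sims = 200, seed = 1)
#' @export
mediate_effects <- function(data, outcome, mediator, treatment,
                            covariates = NULL, sims = 1000L, seed = 1L,
                            method = c("quasi_bayesian", "bootstrap")) {
  method <- match.arg(method)
  if (sims < 100) stop("sims must be at least 100", call. = FALSE)
  vars <- c(outcome, mediator, treatment, covariates)
  mf <- .model_frame(data, vars)

  med_rhs <- c(treatment, covariates)
  out_rhs <- c(treatment, mediator, covariates)
  med_form <- stats::reformulate(sprintf("`%s`", med_rhs),
                                 response = sprintf("`%s`", mediator))
  out_form <- stats::reformulate(sprintf("`%s`", out_rhs),
                                 response = sprintf("`%s`", outcome))

  tr <- mf[[treatment]]
  is_binary <- all(tr %in% c(0, 1))
  contrast <- if (is_binary) 1 else 2 * stats::sd(tr) # t1 - t0

  coef_name <- function(fit, nm) {
    cn <- gsub("`", "", names(stats::coef(fit)), fixed = TRUE)
    which(cn == nm)
  }

  effects_from <- function(med_coefs, out_coefs, a_idx, b_idx, c_idx) {
    a <- med_coefs[a_idx]
    b <- out_coefs[b_idx]
    cp <- out_coefs[c_idx]
    c(acme = a * b * contrast, ade = cp * contrast)
  }

  med_fit <- stats::lm(med_form, data = mf)
  out_fit <- stats::lm(out_form, data = mf)
  if (!(mediator %in% gsub("`", "", names(stats::coef(out_fit)), fixed = TRUE))) {
    stop("mediator must appear in the outcome model", call. = FALSE)
  }
  a_idx <- coef_name(med_fit, treatment)
  b_idx <- coef_name(out_fit, mediator)
  c_idx <- coef_name(out_fit, treatment)

  draws <- withr::with_seed(seed, {
    if (method == "quasi_bayesian") {
      med_draws <- MASS::mvrnorm(sims, stats::coef(med_fit), stats::vcov(med_fit))
      out_draws <- MASS::mvrnorm(sims, stats::coef(out_fit), stats::vcov(out_fit))
      t(vapply(seq_len(sims), function(i) {
        effects_from(med_draws[i, ], out_draws[i, ], a_idx, b_idx, c_idx)
      }, numeric(2)))
    } else {
      n <- nrow(mf)
      t(vapply(seq_len(sims), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        mfi <- mf[idx, , drop = FALSE]
        effects_from(stats::coef(stats::lm(med_form, data = mfi)),
                     stats::coef(stats::lm(out_form, data = mfi)),
                     a_idx, b_idx, c_idx)
      }, numeric(2)))
    }
  })

  acme_d <- draws[, 1]
  ade_d <- draws[, 2]
  total_d <- acme_d + ade_d
  prop_d <- acme_d / total_d

  pval <- function(x) max(2 * min(mean(x <= 0), mean(x >= 0)), 2 / sims)
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

  eff <- tibble::tibble(
    effect = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(mean(acme_d), mean(ade_d), mean(total_d),
                 stats::median(prop_d)),
    ci_low = c(ci(acme_d)[1], ci(ade_d)[1], ci(total_d)[1], ci(prop_d)[1]),
    ci_high = c(ci(acme_d)[2], ci(ade_d)[2], ci(total_d)[2], ci(prop_d)[2]),
    p = c(pval(acme_d), pval(ade_d), pval(total_d), pval(acme_d))
  )

  structure(
    list(effects = eff, sims = as.integer(sims), seed = as.integer(seed),
         method = method, contrast = contrast,
         mediator_model = med_fit, outcome_model = out_fit,
         treatment = treatment, mediator = mediator),
    class = "sd_mediation"
  )
}

#' @rdname mediate_effects
#' @param x An `sd_mediation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sd_mediation <- function(x, ...) x$effects

#' @rdname mediate_effects
#' @exportS3Method generics::glance
glance.sd_mediation <- function(x, ...) {
  tibble::tibble(sims = x$sims, seed = x$seed, method = x$method,
                 contrast = x$contrast,
                 n = length(stats::residuals(x$outcome_model)))
}

#' @export
print.sd_mediation <- function(x, ...) {
  cat("<sd_mediation> method = ", x$method, ", sims = ", x$sims,
      ", treatment contrast = ", format(x$contrast, digits = 3), "\n", sep = "")
  print(x$effects)
  invisible(x)
}
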