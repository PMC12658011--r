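#' Discounted value under a model family
#'
#' The hyperbolic model is v = V0 / (1 + kN): the amount a participant will
#' forgo, v, declines hyperbolically with the social distance N at rate k,
#' from the undiscounted value V0. Alternatives considered for model
#' selection are the exponential decay v = V0 exp(-kN) and the linear ramp
#' v = max(V0 - kN, 0).
#'
#' @param family One of `"hyperbolic"`, `"exponential"`, `"linear"`.
#' @param v0 Undiscounted value V0 (dollars, > 0).
#' @param k Discount rate per unit social distance (>= 0).
#' @param n Social distance N (>= 0). Vectorized over `n`.
#' @return Discounted value v in dollars.
#' @examples
#' model_value("hyperbolic", v0 = 80, k = 1, n = 1) # 40
#' model_value("hyperbolic", v0 = 80, k = 0.05, n = 100) # 80/6
#' @export
model_value <- function(family, v0, k, n) {
  stopifnot(n >= 0, k >= 0, v0 > 0)
  switch(
    match.arg(family, c("hyperbolic", "exponential", "linear")),
    hyperbolic = v0 / (1 + k * n),
    exponential = v0 * exp(-k * n),
    linear = pmax(v0 - k * n, 0)
  )
}

# residual sum of squares for a (v0, k) pair on one family
.discount_rss <- function(family, v0, k, n, v) {
  sum((v - model_value(family, v0, k, n))^2)
}

#' Options controlling discounting fits
#'
#' @param v0_mode `"free"` (V0 jointly estimated, bounded in (0, 160\]) or
#'   `"fixed"` (V0 held at `v0_fixed`).
#' @param v0_fixed Value of V0 when `v0_mode = "fixed"`.
#' @param k_floor Lower bound on k; non-discounters are clipped here so that
#'   logk = ln(k) stays finite, and flagged via `k_floored`.
#' @param k_max Upper bound on k (degenerate all-zero profiles end up here).
#' @param use_aicc If `TRUE`, report small-sample corrected AICc instead of
#'   AIC.
#' @param n_starts Number of multistart values of k, log-spaced in
#'   \[1e-4, 1\].
#' @return A list of class `sd_fit_options`.
#' @export
fit_options <- function(v0_mode = c("free", "fixed"), v0_fixed = 85,
                        k_floor = 1e-6, k_max = 1e3, use_aicc = FALSE,
                        n_starts = 5L) {
  v0_mode <- match.arg(v0_mode)
  stopifnot(k_floor > 0, k_max > k_floor, v0_fixed > 0, n_starts >= 1)
  structure(
    list(v0_mode = v0_mode, v0_fixed = v0_fixed, k_floor = k_floor,
         k_max = k_max, use_aicc = use_aicc, n_starts = n_starts),
    class = "sd_fit_options"
  )
}

# Bounded least squares for one family on (n, v) observations.
# Multistart over k (log-spaced), lowest rss wins, ties toward smaller k.
.fit_discount_one <- function(n, v, family, options) {
  stopifnot(length(n) == length(v), length(v) >= 2)
  k_starts <- 10^seq(-4, 0, length.out = options$n_starts)
  v0_free <- options$v0_mode == "free"
  v0_start <- if (v0_free) max(max(v), 1) else options$v0_fixed

  # optimize over log k (and V0 when free): the log scale keeps the problem
  # well conditioned across the k range spanned by the bounds
  obj <- function(par) {
    if (v0_free) {
      .discount_rss(family, par[1], exp(par[2]), n, v)
    } else {
      .discount_rss(family, options$v0_fixed, exp(par[1]), n, v)
    }
  }
  lk_lo <- log(options$k_floor)
  lk_hi <- log(options$k_max)
  lower <- if (v0_free) c(1e-6, lk_lo) else lk_lo
  upper <- if (v0_free) c(160, lk_hi) else lk_hi

  ctrl <- list(factr = 1e3, maxit = 500)
  best <- NULL
  for (k0 in k_starts) {
    par0 <- if (v0_free) c(v0_start, log(k0)) else log(k0)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) next
    # polish from the candidate optimum
    res2 <- tryCatch(
      stats::optim(res$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(res2) && res2$value <= res$value) res <- res2
    k_hat <- exp(if (v0_free) res$par[2] else res$par[1])
    if (is.null(best) ||
        res$value < best$value * (1 - 1e-9) ||
        (abs(res$value - best$value) <= 1e-9 * max(best$value, 1) &&
         k_hat < best$k_hat)) {
      best <- list(value = res$value, par = res$par, k_hat = k_hat,
                   conv = res$convergence == 0)
    }
  }
  if (is.null(best)) {
    stop("discounting fit failed to converge for family '", family,
         "' after multistart (n_obs = ", length(v), ")", call. = FALSE)
  }

  v0_hat <- if (v0_free) best$par[1] else options$v0_fixed
  k_hat <- max(best$k_hat, options$k_floor)
  rss <- best$value
  n_obs <- length(v)
  p <- if (v0_free) 2L else 1L
  aic <- n_obs * log(max(rss, 1e-300) / n_obs) + 2 * p
  if (options$use_aicc) aic <- aic + 2 * p * (p + 1) / (n_obs - p - 1)

  tibble::tibble(
    family = family,
    v0 = v0_hat,
    k = k_hat,
    logk = log(k_hat),
    rss = rss,
    n_obs = n_obs,
    aic = aic,
    converged = best$conv,
    k_floored = k_hat <= options$k_floor * (1 + 1e-8),
    degenerate = all(v == 0)
  )
}

#' Fit a discounting model to every participant's profile
#'
#' Bounded nonlinear least squares of the chosen family to each
#' participant's seven (N, v) observations, with multistart over k. AIC uses
#' the Gaussian profile-likelihood form n log(rss/n) + 2p with the shared
#' additive constant dropped; the constant cancels in within-participant
#' family comparisons.
#'
#' @param profiles A profile tibble from [build_profiles()] (columns
#'   `participant_id`, `social_distance`, `v`).
#' @param family Model family, default `"hyperbolic"`.
#' @param options An [fit_options()] list.
#' @return A tibble of class `sd_fits`, one row per participant, with
#'   columns `participant_id`, `family`, `v0`, `k`, `logk`, `rss`, `n_obs`,
#'   `aic`, `converged`, `k_floored`, `degenerate`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 5, n_high = 5))
#' profiles <- build_profiles(cohort$choices)
#' fit_discounting(profiles)
#' @export
fit_discounting <- function(profiles, family = "hyperbolic",
                            options = fit_options()) {
  family <- match.arg(family, c("hyperbolic", "exponential", "linear"))
  out <- profiles |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ .fit_discount_one(.x$social_distance, .x$v,
                                            family, options)) |>
    dplyr::ungroup()
  class(out) <- c("sd_fits", class(out))
  out
}

#' Pooled discounting fit across all participants
#'
#' Fits one curve to all (N, v) observations pooled; used for family
#' selection across hyperbolic, exponential and linear candidates, not for
#' per-participant rates.
#'
#' @inheritParams fit_discounting
#' @return One-row tibble with the same columns as [fit_discounting()]
#'   minus `participant_id`.
#' @export
fit_pooled <- function(profiles, family = "hyperbolic",
                       options = fit_options()) {
  family <- match.arg(family, c("hyperbolic", "exponential", "linear"))
  .fit_discount_one(profiles$social_distance, profiles$v, family, options)
}

#' Compare discounting model families by AIC
#'
#' Computes per-family delta AIC relative to the minimum and Akaike weights
#' w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2), the relative
#' likelihood of each family within the compared set. A delta above 10 is
#' conventionally read as strong evidence for the lower-AIC family.
#'
#' @param aics Named numeric vector of AICs (>= 2 finite entries), or a data
#'   frame with columns `family` and `aic` (e.g. rows from [fit_pooled()]).
#' @return A tibble with columns `family`, `aic`, `delta_aic`,
#'   `akaike_weight`, sorted by AIC, with attribute `best_family`.
#' @examples
#' compare_models(c(hyperbolic = 46142.77, exponential = 49021.74,
#'                  linear = 48269.92))
#' @export
compare_models <- function(aics) {
  if (is.data.frame(aics)) {
    aics <- stats::setNames(aics$aic, aics$family)
  }
  if (length(aics) < 2) stop("need at least 2 AICs to compare", call. = FALSE)
  if (any(!is.finite(aics))) stop("non-finite AIC supplied", call. = FALSE)
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- tibble::tibble(
    family = names(aics),
    aic = unname(aics),
    delta_aic = unname(delta),
    akaike_weight = unname(w)
  ) |>
    dplyr::arrange(.data$aic)
  attr(out, "best_family") <- out$family[1L]
  out
}

#' Natural log of the discount rate
#'
#' logk summarises the rate of decay in generosity with social distance;
#' higher logk means steeper discounting. Rates are floored during fitting,
#' so anything below the floor here is a usage error.
#'
#' @param k Discount rate(s), each >= `k_floor`.
#' @param k_floor The fitting floor (default 1e-6).
#' @return ln(k).
#' @export
compute_logk <- function(k, k_floor = 1e-6) {
  if (any(k < k_floor)) {
    stop("k below the fitting floor (", k_floor,
         "); flooring is the fitter's job", call. = FALSE)
  }
  log(k)
}

#' Model-agnostic discounting AUC
#'
#' Trapezoidal area under the v-versus-N curve over the observed distances,
#' normalised to a proportion: area / ((max N - min N) * 80), where $80 is
#' the maximum possible amount willing to forgo. Anchored at the first
#' observed distance (N = 1); no synthetic N = 0 point is added. Higher AUC
#' means more overall generosity.
#'
#' @param profiles A profile tibble ([build_profiles()]); one AUC is
#'   computed per participant.
#' @param v_max Maximum possible v used for the y-axis normalisation
#'   (default 80, the task's largest forgone amount).
#' @return A tibble with `participant_id`, `auc` (in \[0, 1\]) and the
#'   normalisation constants `x_span`, `v_max`.
#' @examples
#' prof <- tibble::tibble(participant_id = 1, social_distance = social_distances(),
#'                        v = rep(80, 7))
#' compute_auc(prof)$auc # 1
#' @export
compute_auc <- function(profiles, v_max = 80) {
  one <- function(n, v) {
    if (length(n) < 2) stop("AUC needs at least 2 points", call. = FALSE)
    ord <- order(n)
    n <- n[ord]; v <- v[ord]
    span <- max(n) - min(n)
    tibble::tibble(
      auc = pracma::trapz(n, v) / (span * v_max),
      x_span = span,
      v_max = v_max
    )
  }
  profiles |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x$social_distance, .x$v)) |>
    dplyr::ungroup()
}
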