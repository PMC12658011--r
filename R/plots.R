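#' Plot mean social-discounting curves
#'
#' Mean amount willing to forgo (v, dollars) against social distance N, one
#' curve per group when a grouping column is supplied, with standard-error
#' ribbons. The fitted hyperbolic curve can be overlaid from a pooled fit.
#'
#' @param profiles A profile tibble ([build_profiles()]).
#' @param participants Optional participants table supplying a `group`
#'   column (joined on `participant_id`).
#' @param fit Optional one-row pooled fit ([fit_pooled()]) to overlay.
#' @return A ggplot object.
#' @export
plot_discount_curve <- function(profiles, participants = NULL, fit = NULL) {
  dat <- profiles
  if (!is.null(participants) && "group" %in% names(participants)) {
    dat <- dplyr::inner_join(
      dat, dplyr::select(participants, "participant_id", "group"),
      by = "participant_id")
  } else {
    dat$group <- "all"
  }
  summ <- dat |>
    dplyr::group_by(.data$group, .data$social_distance) |>
    dplyr::summarise(mean_v = mean(.data$v),
                     se_v = stats::sd(.data$v) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$social_distance,
                                          y = .data$mean_v,
                                          colour = .data$group,
                                          fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_v - .data$se_v,
                                      ymax = .data$mean_v + .data$se_v),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Social distance (N)",
                  y = "Amount willing to forgo, v ($)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(n = seq(1, 100, by = 1))
    grid$v <- model_value(fit$family[1], fit$v0[1], fit$k[1], grid$n)
    p <- p + ggplot2::geom_line(
      data = grid,
      ggplot2::aes(x = .data$n, y = .data$v),
      inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.sd_cohort <- function(object, ...) {
  plot_discount_curve(build_profiles(object$choices), object$participants)
}

#' Plot a mediation result
#'
#' Point estimates with 95% CIs for ACME, ADE and the total effect.
#'
#' @param object An `sd_mediation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sd_mediation <- function(object, ...) {
  eff <- object$effects[object$effects$effect != "prop_mediated", ]
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "Effect on outcome", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
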