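#' The canonical social-discounting trial schedule
#'
#' Builds the fixed task structure: seven social distances (the rank of a
#' person on an imagined list from 1, the closest other, to 100, a stranger)
#' crossed with nine dichotomous trials per distance. On each trial the
#' selfish option keeps an amount that decreases from $155 to $75 in $10
#' steps, while the generous option always splits the money so that both the
#' participant and the named other receive $75. Choosing generously on the
#' $155 trial therefore means sacrificing $80 to benefit that person.
#'
#' @return A tibble with one row per trial (`trial_index`, `selfish_amount`,
#'   `forgone_amount`) carrying attributes `social_distances` (the vector
#'   `c(1, 2, 5, 10, 20, 50, 100)`), `generous_self_amount` and
#'   `generous_other_amount` (both 75).
#' @examples
#' sched <- trial_schedule()
#' sched$selfish_amount # 155 145 ... 75
#' attr(sched, "social_distances")
#' @export
trial_schedule <- function() {
  amounts <- seq(155L, 75L, by = -10L)
  out <- tibble::tibble(
    trial_index = seq_along(amounts),
    selfish_amount = amounts,
    forgone_amount = amounts - 75L
  )
  attr(out, "social_distances") <- c(1L, 2L, 5L, 10L, 20L, 50L, 100L)
  attr(out, "generous_self_amount") <- 75L
  attr(out, "generous_other_amount") <- 75L
  out
}

#' Social distances probed by the task
#' @return Integer vector `c(1, 2, 5, 10, 20, 50, 100)`.
#' @export
social_distances <- function() c(1L, 2L, 5L, 10L, 20L, 50L, 100L)

#' Extract the indifference point from one block of nine choices
#'
#' The indifference point for a social distance is the selfish amount offered
#' on the trial at which the participant switched from keeping the money to
#' sharing it. An all-selfish block is censored at $75 and an all-generous
#' block at $155 (the generous choice on the very first, $155, trial). For
#' non-monotone blocks (a selfish choice occurring after the first generous
#' one) the first switch still defines the indifference point and the block
#' is flagged as a monotonicity violation; such participants are retained.
#'
#' @param choices Character vector of length 9 with entries `"selfish"` or
#'   `"generous"`, ordered by trial (amounts descending $155 to $75).
#' @return A list with `indifference_point` (dollars in \[75, 155\]) and
#'   `violation` (logical).
#' @examples
#' extract_indifference(rep("selfish", 9))$indifference_point # 75
#' extract_indifference(rep("generous", 9))$indifference_point # 155
#' extract_indifference(c(rep("selfish", 4), rep("generous", 5)))
#' @export
extract_indifference <- function(choices) {
  if (length(choices) != 9L) {
    stop("a choice block must contain exactly 9 trials, got ", length(choices),
         call. = FALSE)
  }
  if (!all(choices %in% c("selfish", "generous"))) {
    bad <- unique(setdiff(choices, c("selfish", "generous")))
    stop("unknown choice label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  amounts <- seq(155L, 75L, by = -10L)
  gen <- choices == "generous"
  if (!any(gen)) {
    return(list(indifference_point = 75, violation = FALSE))
  }
  first_gen <- which(gen)[1L]
  violation <- any(!gen[seq.int(first_gen, 9L)])
  list(indifference_point = as.numeric(amounts[first_gen]), violation = violation)
}

#' Amount willing to forgo from an indifference point
#'
#' v = indifference point - $75: the maximum sacrifice the participant
#' accepts so that the person at that social distance receives $75.
#'
#' @param indifference_point Dollars in \[75, 155\].
#' @return v in dollars, in \[0, 80\]. Vectorized.
#' @export
forgone_amount <- function(indifference_point) {
  if (any(indifference_point < 75 | indifference_point > 155)) {
    stop("indifference points must lie in [75, 155]", call. = FALSE)
  }
  indifference_point - 75
}

#' Build per-participant indifference profiles from long-format choices
#'
#' Collapses a long choice table (one row per trial) into one row per
#' participant x social distance: the indifference point, the amount willing
#' to forgo v, and a monotonicity-violation flag.
#'
#' @param choices A data frame with columns `participant_id`,
#'   `social_distance`, `trial_index`, `selfish_amount`, `choice`
#'   (`"selfish"`/`"generous"`), e.g. as produced by [generate_cohort()] or
#'   read by [read_choices()]. Every participant must contribute exactly one
#'   9-trial block per canonical distance.
#' @return A tibble with columns `participant_id`, `social_distance`,
#'   `indifference_point`, `v`, `violation`, 7 rows per participant.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 4, n_high = 4))
#' build_profiles(cohort$choices)
#' @export
build_profiles <- function(choices) {
  req <- c("participant_id", "social_distance", "trial_index", "choice")
  missing_cols <- setdiff(req, names(choices))
  if (length(missing_cols)) {
    stop("choices table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  canonical <- social_distances()
  bad_n <- setdiff(unique(choices$social_distance), canonical)
  if (length(bad_n)) {
    stop("non-canonical social distance(s): ", paste(bad_n, collapse = ", "),
         call. = FALSE)
  }

  out <- choices |>
    dplyr::arrange(.data$participant_id, .data$social_distance, .data$trial_index) |>
    dplyr::group_by(.data$participant_id, .data$social_distance) |>
    dplyr::summarise(
      indifference_point = extract_indifference(.data$choice)$indifference_point,
      violation = extract_indifference(.data$choice)$violation,
      .groups = "drop"
    ) |>
    dplyr::mutate(v = forgone_amount(.data$indifference_point)) |>
    dplyr::select("participant_id", "social_distance", "indifference_point",
                  "v", "violation")

  counts <- dplyr::count(out, .data$participant_id)
  bad <- counts$participant_id[counts$n != 7L]
  if (length(bad)) {
    stop("participant(s) without exactly one block per canonical distance: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}
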