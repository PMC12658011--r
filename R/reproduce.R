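#' Reproduce the headline full-sample statistics from deposited study data
#'
#' Runs the complete pipeline on a locally available copy of a study's
#' deposited data (participants + choices tables mapped to this package's
#' column conventions; see [read_choices()] and [read_participants()]) and
#' returns the two headline quantities: the mean TriPM total in the
#' high-psychopathy group and Cohen's d for the group difference in logk.
#' These depend on the deposit's fitting conventions (V0 mode), which can be
#' set through `fit`.
#'
#' The deposit itself is not shipped with the package and must be obtained
#' and converted separately; this function only needs the two CSVs.
#'
#' @param data_dir Directory containing `participants.csv` and
#'   `choices.csv`.
#' @param fit An [fit_options()] list matching the original fitting
#'   conventions.
#' @return A tibble with `high_group_tripm_mean` and `logk_cohens_d`.
#' @export
reproduce_full_study <- function(data_dir, fit = fit_options()) {
  p_path <- file.path(data_dir, "participants.csv")
  c_path <- file.path(data_dir, "choices.csv")
  if (!file.exists(p_path) || !file.exists(c_path)) {
    stop("deposited data not found under '", data_dir,
         "': expected participants.csv and choices.csv", call. = FALSE)
  }
  bundle <- run_pipeline(run_config(
    cohort = NULL, participants_csv = p_path, choices_csv = c_path,
    fit = fit))
  gt <- bundle$group_tests
  tibble::tibble(
    high_group_tripm_mean = mean(
      bundle$participants$tripm_total[bundle$participants$group == "high"]),
    logk_cohens_d = gt$cohens_d[gt$variable == "logk"]
  )
}
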