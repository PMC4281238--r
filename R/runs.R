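#' Summarise an ensemble of simulated escape runs
#'
#' Computes the mean collective asymmetry across runs with its standard
#' error. Runs that hit the step cap before every ant escaped are flagged
#' `truncated` by the simulators and are excluded by default, since their
#' escaped totals are censored; runs with no escaped ants are always
#' excluded (the statistic is undefined).
#'
#' @param runs A per-run data.frame from [simulate_pheromone()] or
#'   [simulate_vicsek()].
#' @param exclude_truncated Drop truncated runs (default TRUE).
#' @return A one-row data.frame: `runs_used`, `mean_delta`, `mean_delta_c`,
#'   `se` (standard error of the mean collective asymmetry), `mean_n`.
#' @export
summarise_runs <- function(runs, exclude_truncated = TRUE) {
  req <- c("n_left", "n_right", "truncated")
  if (!all(req %in% names(runs)))
    stop("`runs` must have columns n_left, n_right, truncated", call. = FALSE)
  keep <- runs$n_left + runs$n_right >= 1
  if (exclude_truncated) keep <- keep & !runs$truncated
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0L)
    stop("no usable runs to summarise", call. = FALSE)
  dc <- collective_asymmetry(runs$n_left, runs$n_right)
  d <- percentage_difference(runs$n_left, runs$n_right)
  data.frame(runs_used = nrow(runs),
             mean_delta = mean(d),
             mean_delta_c = mean(dc),
             se = if (nrow(runs) > 1) sd(dc) / sqrt(nrow(runs)) else NA_real_,
             mean_n = mean(runs$n_left + runs$n_right))
}

#' Convert simulated runs to a trial table
#'
#' @param runs A per-run data.frame from the simulators.
#' @param exclude_truncated Drop truncated runs (default TRUE).
#' @return A [trial_table()] with one trial per usable run.
#' @export
runs_to_trial_table <- function(runs, exclude_truncated = TRUE) {
  keep <- runs$n_left + runs$n_right >= 1
  if (exclude_truncated) keep <- keep & !runs$truncated
  runs <- runs[keep, , drop = FALSE]
  trial_table(n_left = runs$n_left, n_right = runs$n_right,
              trial_id = paste0("run", runs$run_id))
}
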