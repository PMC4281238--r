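#' Left/right majority counts across trials
#'
#' Counts the trials in which more ants escaped left than right, more right
#' than left, and exactly equal numbers. In an unbiased arena the left and
#' right majorities should be statistically indistinguishable; a lopsided
#' split indicates a hidden environmental bias.
#'
#' @param table A [trial_table()].
#' @return Named integer vector `c(left, right, tie)` summing to the number
#'   of trials.
#' @export
sign_counts <- function(table) {
  table <- as_trial_table(table)
  c(left = sum(table$n_left > table$n_right),
    right = sum(table$n_left < table$n_right),
    tie = sum(table$n_left == table$n_right))
}

per_trial_statistic <- function(table, statistic) {
  if (is.function(statistic)) return(statistic(table$n_left, table$n_right))
  statistic <- match.arg(statistic, c("delta_c", "delta"))
  switch(statistic,
         delta = percentage_difference(table$n_left, table$n_right),
         delta_c = collective_asymmetry(table$n_left, table$n_right))
}

sort_by_total <- function(table) {
  n <- table$n_left + table$n_right
  table[order(n, table$trial_id, method = "radix"), , drop = FALSE]
}

check_window <- function(window, n_trials) {
  if (length(window) != 1L || !is.finite(window) || window != round(window))
    stop("`window` must be a single integer", call. = FALSE)
  if (window < 2) stop("`window` must be at least 2", call. = FALSE)
  if (window > n_trials)
    stop("`window` (", window, ") exceeds the number of trials (",
         n_trials, ")", call. = FALSE)
  invisible(as.integer(window))
}

#' Moving-average curve of an escape statistic against group size
#'
#' Because the total number of escaped ants cannot be fixed in advance, the
#' dependence of an escape statistic on group size is estimated by sorting
#' trials by total escaped count N (ties broken by trial id) and sliding a
#' window of consecutive trials along the sorted sequence. Each full window
#' yields one curve point: the within-window mean of N on the x axis, the
#' within-window mean of the statistic on the y axis, and the standard error
#' of that mean as the spread. Only full windows are emitted, so a table of
#' `m` trials gives `m - window + 1` points.
#'
#' @param table A [trial_table()].
#' @param statistic `"delta_c"` (collective asymmetry, the default),
#'   `"delta"` (raw percentage difference), or a function of
#'   `(n_left, n_right)` returning one value per trial.
#' @param window Window length in trials (default 31); must be between 2 and
#'   the number of trials. Odd windows of 21--51 are typical.
#' @return An `escape_curve`: a data.frame with columns `x_mean_n`, `y`,
#'   `spread`, `window` and attribute `statistic`.
#' @examples
#' tt <- generate_trials(n_trials = 100, seed = 1)
#' head(moving_average_curve(tt, window = 21))
#' @export
moving_average_curve <- function(table, statistic = "delta_c", window = 31L) {
  table <- as_trial_table(table)
  window <- check_window(window, nrow(table))
  table <- sort_by_total(table)
  y <- per_trial_statistic(table, statistic)
  n <- table$n_left + table$n_right
  x_mean <- rolling_mean(n, window)
  y_mean <- rolling_mean(y, window)
  sem <- rolling_sd(y, window) / sqrt(window)
  new_escape_curve(x_mean, y_mean, sem, window,
                   statistic_label(statistic), "moving average")
}

#' Moving-window standard deviation of an escape statistic
#'
#' Same windowing as [moving_average_curve()], but each point reports the
#' sample standard deviation of the statistic within the window — the
#' fluctuation of collective asymmetry at a given group size. The `spread`
#' column is 0 for this curve.
#'
#' @inheritParams moving_average_curve
#' @return An `escape_curve` data.frame; `y` holds the windowed SD.
#' @export
sd_curve <- function(table, statistic = "delta_c", window = 31L) {
  table <- as_trial_table(table)
  window <- check_window(window, nrow(table))
  table <- sort_by_total(table)
  y <- per_trial_statistic(table, statistic)
  n <- table$n_left + table$n_right
  new_escape_curve(rolling_mean(n, window), rolling_sd(y, window),
                   0, window, statistic_label(statistic), "moving SD")
}

statistic_label <- function(statistic) {
  if (is.function(statistic)) "custom" else
    match.arg(statistic, c("delta_c", "delta"))
}

rolling_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  m <- length(x) - w + 1L
  (cs[(w + 1):(w + m)] - cs[1:m]) / w
}

rolling_sd <- function(x, w) {
  # sample SD over each full window, (w - 1) denominator
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  m <- length(x) - w + 1L
  s <- cs[(w + 1):(w + m)] - cs[1:m]
  s2 <- cs2[(w + 1):(w + m)] - cs2[1:m]
  sqrt(pmax(s2 - s^2 / w, 0) / (w - 1))
}

new_escape_curve <- function(x, y, spread, window, statistic, kind) {
  out <- data.frame(x_mean_n = x, y = y, spread = spread, window = window)
  attr(out, "statistic") <- statistic
  attr(out, "kind") <- kind
  class(out) <- c("escape_curve", "data.frame")
  out
}

#' @export
print.escape_curve <- function(x, ...) {
  cat(sprintf("Escape curve (%s of %s), window %d, %d points\n",
              attr(x, "kind"), attr(x, "statistic"), x$window[1], nrow(x)))
  NextMethod()
}

#' @export
plot.escape_curve <- function(x, ...) {
  args <- list(...)
  defaults <- list(x = x$x_mean_n, y = x$y, type = "l",
                   xlab = "mean total escaped N",
                   ylab = attr(x, "statistic"))
  do.call(graphics::plot, modifyList(defaults, args))
  if (any(x$spread > 0)) {
    graphics::lines(x$x_mean_n, x$y + x$spread, lty = 2)
    graphics::lines(x$x_mean_n, x$y - x$spread, lty = 2)
  }
  invisible(x)
}

#' Write a curve to CSV
#'
#' @param curve An `escape_curve` from [moving_average_curve()] or
#'   [sd_curve()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "escape_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
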