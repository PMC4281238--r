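#' Generate experiment-shaped synthetic trial tables
#'
#' Emits a trial table with the shape of a two-exit escape experiment: a
#' chosen number of trials whose total escaped counts N are drawn from a
#' range, and a left/right split that is fair-coin binomial under the null
#' (`rho = 0`) or over-dispersed under collective escape (`rho > 0`). The
#' defaults mirror a 291-repetition experiment with N between 6 and 269.
#'
#' Over-dispersion uses a beta-binomial construction: each trial draws a
#' left-escape probability `p` from a symmetric Beta whose intra-class
#' correlation is `rho`, then `n_left ~ Binomial(N, p)`. `rho` is not a
#' behavioural parameter; it is the statistical signature (correlated exit
#' choice within a trial) that the analysis layer consumes. Exchanging left
#' and right is distribution-preserving in every mode, so synthetic tables
#' carry no built-in side bias.
#'
#' @param n_trials Number of trials (default 291).
#' @param n_range Inclusive integer range for the total escaped count N
#'   (default `c(6, 269)`).
#' @param n_distribution `"uniform"` or `"log-uniform"` law for N over
#'   `n_range`.
#' @param rho Intra-trial escape correlation in `[0, 1)`; 0 is the fair-coin
#'   null.
#' @param rho_profile Optional function mapping N to a rho value, overriding
#'   `rho` per trial (used to build density-dependent tables).
#' @param seed Optional integer seed for reproducibility.
#' @return A [trial_table()].
#' @examples
#' null_tt <- generate_trials(seed = 42)
#' sign_counts(null_tt)
#' @export
generate_trials <- function(n_trials = 291L, n_range = c(6L, 269L),
                            n_distribution = c("uniform", "log-uniform"),
                            rho = 0, rho_profile = NULL, seed = NULL) {
  n_distribution <- match.arg(n_distribution)
  if (length(n_trials) != 1L || n_trials < 1 || n_trials != round(n_trials))
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (length(n_range) != 2L || any(n_range < 1) || n_range[2] < n_range[1] ||
      any(n_range != round(n_range)))
    stop("`n_range` must be an increasing pair of positive integers",
         call. = FALSE)
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1)
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (!is.null(rho_profile) && !is.function(rho_profile))
    stop("`rho_profile` must be a function of N", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_total <- draw_group_sizes(n_trials, n_range, n_distribution)
  rho_n <- if (is.null(rho_profile)) rep(rho, n_trials) else
    vapply(n_total, rho_profile, numeric(1))
  if (any(!is.finite(rho_n) | rho_n < 0 | rho_n >= 1))
    stop("`rho_profile` must return values in [0, 1)", call. = FALSE)

  p <- rep(0.5, n_trials)
  disp <- rho_n > 0
  if (any(disp)) {
    # symmetric Beta(a, a) has intra-class correlation 1 / (2a + 1)
    a <- (1 / rho_n[disp] - 1) / 2
    p[disp] <- rbeta(sum(disp), a, a)
  }
  n_left <- rbinom(n_trials, n_total, p)
  trial_table(n_left = n_left, n_right = n_total - n_left)
}

draw_group_sizes <- function(n_trials, n_range, n_distribution) {
  if (n_distribution == "uniform") {
    n_range[1] + floor(runif(n_trials) * (n_range[2] - n_range[1] + 1))
  } else {
    lo <- log(n_range[1]); hi <- log(n_range[2] + 1)
    pmin(floor(exp(lo + runif(n_trials) * (hi - lo))), n_range[2])
  }
}

#' Default density-dependent correlation profile
#'
#' A log-normal bump in the intra-trial escape correlation, peaking at an
#' intermediate group size. Feeding it to [generate_rise_fall_table()]
#' produces trial tables whose moving-average collective-asymmetry curve
#' rises and then falls with N — the qualitative shape seen in escape
#' experiments — which makes it a useful end-to-end pipeline fixture.
#'
#' @param peak_n Group size at which the correlation peaks (default 40).
#' @param max_rho Correlation at the peak (default 0.3).
#' @param log_width Width of the bump on the log-N scale (default 0.5).
#' @return A function of N returning a rho in `[0, 1)`.
#' @export
rho_peak_profile <- function(peak_n = 40, max_rho = 0.3, log_width = 0.5) {
  force(peak_n); force(max_rho); force(log_width)
  function(n) max_rho * exp(-(log(n / peak_n))^2 / (2 * log_width^2))
}

#' Generate a rise-then-fall synthetic trial table
#'
#' [generate_trials()] with a mandatory density-dependent correlation
#' profile; by construction the windowed collective-asymmetry curve of the
#' result is non-monotone in N when the profile is peaked.
#'
#' @inheritParams generate_trials
#' @param rho_profile Function mapping N to rho (default
#'   [rho_peak_profile()]).
#' @return A [trial_table()].
#' @export
generate_rise_fall_table <- function(n_trials = 291L, n_range = c(6L, 269L),
                                     n_distribution = c("uniform", "log-uniform"),
                                     rho_profile = rho_peak_profile(),
                                     seed = NULL) {
  if (is.null(rho_profile))
    stop("`rho_profile` is required", call. = FALSE)
  generate_trials(n_trials = n_trials, n_range = n_range,
                  n_distribution = n_distribution,
                  rho_profile = rho_profile, seed = seed)
}
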