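#' Percentage difference in door use
#'
#' For a single escape repetition in which `n_left` ants leave through the
#' left exit and `n_right` through the right, the percentage difference in
#' door use is `100 * |n_left - n_right| / (n_left + n_right)`. A value of 0
#' means both exits were used equally; 100 means every ant used the same
#' exit.
#'
#' @param n_left,n_right Non-negative integer counts of ants escaping through
#'   the left and right exits. Vectorised; recycled to a common length.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' percentage_difference(75, 25)  # 50
#' percentage_difference(1, 1)    # 0
#' @seealso [collective_asymmetry()] for the randomness-corrected statistic.
#' @export
percentage_difference <- function(n_left, n_right) {
  check_counts(n_left, n_right)
  n <- n_left + n_right
  100 * abs(n_left - n_right) / n
}

#' Exact null moments of the percentage difference
#'
#' Under the random self-propelled particle (SPP) null, each of `n` escaping
#' ants chooses the left exit independently with probability 1/2, so the
#' left count `X` is Binomial(n, 1/2) and the percentage difference is the
#' folded, scaled binomial `100 * |2X - n| / n`. `random_difference_mean()`
#' returns its exact expectation and `random_difference_sd()` its exact
#' standard deviation. Even a perfectly unbiased group therefore shows a
#' positive expected difference (50 for n = 2, 24.6 for n = 10, 8.0 for
#' n = 100), which is the motivation for the collective-asymmetry
#' correction.
#'
#' The expectation is evaluated as the exact sum over all left counts with
#' log-domain binomial coefficients, so it is numerically stable for group
#' sizes of at least several thousand. The second moment is available in
#' closed form: `E[(100|2X-n|/n)^2] = 10^4 / n` because
#' `E[(2X - n)^2] = 4 Var(X) = n`.
#'
#' @param n Positive integer group size(s); vectorised.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' random_difference_mean(2)          # 50
#' round(random_difference_mean(10), 1)   # 24.6
#' round(random_difference_mean(100), 1)  # 8.0
#' random_difference_sd(1)            # 0: the statistic is constant 100
#' @export
random_difference_mean <- function(n) {
  check_group_size(n)
  n <- as.integer(n)
  un <- unique(n)
  m <- vapply(un, function(ni) {
    k <- 0:ni
    sum(exp(lchoose(ni, k) - ni * log(2)) * 100 * abs(2 * k - ni) / ni)
  }, numeric(1))
  m[match(n, un)]
}

#' @rdname random_difference_mean
#' @export
random_difference_sd <- function(n) {
  check_group_size(n)
  m <- random_difference_mean(n)
  # second moment is exactly 10^4/n; guard tiny negative rounding at n = 1
  sqrt(pmax(1e4 / n - m^2, 0))
}

#' Collective asymmetry
#'
#' The percentage difference in door use minus its expectation under the
#' fair-coin null for the same total group size. Positive values indicate
#' more asymmetry than independent random escapers would produce; negative
#' values indicate a split more even than chance. Averaged over fair-coin
#' escapes the statistic is exactly zero at every group size, which is the
#' defining property of the correction.
#'
#' @inheritParams percentage_difference
#' @return Numeric vector of signed percentages.
#' @examples
#' collective_asymmetry(5, 5)    # -24.6: even split is "too symmetric"
#' collective_asymmetry(10, 0)   # 75.4
#' @export
collective_asymmetry <- function(n_left, n_right) {
  check_counts(n_left, n_right)
  percentage_difference(n_left, n_right) -
    random_difference_mean(n_left + n_right)
}

#' Exact null distribution of the percentage difference
#'
#' Enumerates the support of `100 * |2X - n| / n` for `X ~ Binomial(n, 1/2)`
#' with the exact probability of each distinct difference value (left counts
#' `k` and `n - k` fold onto the same difference).
#'
#' @param n Positive integer group size (scalar).
#' @return A data.frame with columns `difference` (ascending) and
#'   `probability`, summing to 1.
#' @examples
#' null_distribution(2)  # difference 0 w.p. 1/2, 100 w.p. 1/2
#' @export
null_distribution <- function(n) {
  check_group_size(n)
  if (length(n) != 1L) stop("`n` must be a single group size", call. = FALSE)
  n <- as.integer(n)
  k <- 0:n
  p <- exp(lchoose(n, k) - n * log(2))
  d <- 100 * abs(2 * k - n) / n
  agg <- tapply(p, d, sum)
  out <- data.frame(difference = as.numeric(names(agg)),
                    probability = as.numeric(agg))
  out[order(out$difference), , drop = FALSE]
}

#' Table of null moments over a range of group sizes
#'
#' @param n_min,n_max Inclusive positive integer bounds.
#' @return A data.frame with columns `n`, `mean_difference`,
#'   `sd_difference` (percent scale).
#' @export
null_table <- function(n_min = 1L, n_max = 300L) {
  check_group_size(n_min)
  check_group_size(n_max)
  if (n_max < n_min) stop("`n_max` must be >= `n_min`", call. = FALSE)
  n <- seq.int(as.integer(n_min), as.integer(n_max))
  data.frame(n = n,
             mean_difference = random_difference_mean(n),
             sd_difference = random_difference_sd(n))
}

check_counts <- function(n_left, n_right) {
  if (length(n_left) == 0L || length(n_right) == 0L)
    stop("counts must be non-empty", call. = FALSE)
  bad <- !is.finite(n_left) | !is.finite(n_right) |
    n_left < 0 | n_right < 0 |
    n_left != round(n_left) | n_right != round(n_right)
  if (any(bad))
    stop("escape counts must be non-negative integers", call. = FALSE)
  if (any(n_left + n_right < 1))
    stop("total escaped count must be at least 1", call. = FALSE)
  invisible(NULL)
}

check_group_size <- function(n) {
  if (length(n) == 0L || any(!is.finite(n) | n < 1 | n != round(n)))
    stop("group size `n` must be a positive integer", call. = FALSE)
  invisible(NULL)
}
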