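# Independent oracles used across tests.

# Brute-force fair-coin null: enumerate all 2^n equiprobable left/right
# assignments by bit pattern, no binomial formula involved.
brute_force_null <- function(n) {
  outcomes <- 0:(2^n - 1)
  k <- integer(length(outcomes))
  for (b in 0:(n - 1)) {
    bit <- bitwShiftL(1L, b)
    k <- k + bitwAnd(outcomes, bit) %/% bit
  }
  d <- 100 * abs(2 * k - n) / n
  c(mean = mean(d), sd = sqrt(mean(d^2) - mean(d)^2))
}

# Exact expected percentage difference under the beta-binomial split:
# p ~ Beta(a, a) with intra-class correlation rho = 1 / (2a + 1), then
# n_left ~ Binomial(N, p). Marginal P(X = k) = C(N,k) B(k+a, N-k+a) / B(a,a).
beta_binomial_mean_delta <- function(N, rho) {
  if (rho == 0) {
    k <- 0:N
    return(sum(choose(N, k) / 2^N * 100 * abs(2 * k - N) / N))
  }
  a <- (1 / rho - 1) / 2
  k <- 0:N
  logp <- lchoose(N, k) + lbeta(k + a, N - k + a) - lbeta(a, a)
  sum(exp(logp) * 100 * abs(2 * k - N) / N)
}

# Standard error of a sample mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
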