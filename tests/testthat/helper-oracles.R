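# Brute-force density oracles, written from the closed forms so they stay
# independent of the package's own stats:: calls.

norm_lpdf <- function(x, mu, s) -0.5 * log(2 * pi) - log(s) - (x - mu)^2 / (2 * s^2)

lnorm_lpdf <- function(x, mu = 0, s = 1) {
  ifelse(x > 0, -log(x) + norm_lpdf(log(x), mu, s), -Inf)
}

beta_lpdf <- function(x, a, b) {
  ifelse(x > 0 & x < 1,
    (a - 1) * log(x) + (b - 1) * log(1 - x) -
      (lgamma(a) + lgamma(b) - lgamma(a + b)),
    -Inf
  )
}

unif_lpdf <- function(x, lo, hi) ifelse(x >= lo & x <= hi, -log(hi - lo), -Inf)

# one-sample K-S statistic against U(0,1) by direct ECDF max-gap enumeration
ks_stat_oracle <- function(u) {
  u <- sort(u)
  n <- length(u)
  max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
}

# naive Hill / combination means, computed exactly as written, for tiny inputs
hill_oracle <- function(x, E0, E1, C, H) {
  if (x == 0) E0 else E0 + (E1 - E0) / (1 + (C / x)^H)
}

combo_oracle <- function(x1, x2, E0, E1, E2, E3, C1, C2, H1, H2, alpha) {
  num <- C1^H1 * C2^H2 * E0 + x1^H1 * C2^H2 * E1 +
    C1^H1 * x2^H2 * E2 + alpha * x1^H1 * x2^H2 * E3
  den <- C1^H1 * C2^H2 + x1^H1 * C2^H2 + C1^H1 * x2^H2 + alpha * x1^H1 * x2^H2
  num / den
}
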