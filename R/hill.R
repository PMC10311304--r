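#' Hill dose-response mean function
#'
#' Expected response of a monotherapy at dose `x` under the four-parameter
#' Hill model
#' \deqn{E(x) = E_0 + \frac{E_1 - E_0}{1 + (C/x)^H},}
#' where `E0` is the base level at dose zero, `E1` (Einf) the maximal-effect
#' level at infinite dose, `C` the IC50 and `H` the Hill slope. The dose-zero
#' value is the limit convention `E(0) = E0`; no division by zero occurs
#' because the curve is evaluated as `E0 + (E1 - E0) * plogis(H * (log x - log C))`.
#'
#' @param x Dose(s), non-negative; vectorised.
#' @param E0,E1 Base and maximal-effect response levels.
#' @param C IC50 (> 0). @param H Hill slope (> 0).
#' @return Expected response(s), always between `min(E0, E1)` and `max(E0, E1)`.
#' @examples
#' hill_mean(c(0, 1, 1e6), E0 = 100, E1 = 0, C = 1, H = 2)
#' @export
hill_mean <- function(x, E0, E1, C, H) {
  if (any(!is.finite(x)) || any(x < 0)) abort("doses must be finite and non-negative.")
  stopifnot(C > 0, H > 0)
  frac <- ifelse(x > 0, plogis(H * (log(x) - log(C))), 0)
  E0 + (E1 - E0) * frac
}

#' Two-drug combination dose-response surface
#'
#' Expected response at doses `(x1, x2)` under the detailed-balance
#' combination surface
#' \deqn{E(x_1,x_2) = \frac{C_1^{H_1}C_2^{H_2}E_0 + x_1^{H_1}C_2^{H_2}E_1 +
#'   C_1^{H_1}x_2^{H_2}E_2 + \alpha x_1^{H_1}x_2^{H_2}E_3}
#'   {C_1^{H_1}C_2^{H_2} + x_1^{H_1}C_2^{H_2} + C_1^{H_1}x_2^{H_2} +
#'   \alpha x_1^{H_1}x_2^{H_2}},}
#' a weighted average of the four asymptotic levels `E0 = E(0,0)`,
#' `E1 = E(Inf,0)`, `E2 = E(0,Inf)`, `E3 = E(Inf,Inf)`. The association
#' parameter `alpha` rescales the joint-dose weight: `alpha > 1` means each
#' drug potentiates the other (synergistic potency), `alpha = 1` no potency
#' interaction. Each monotherapy slice (`x2 = 0` or `x1 = 0`) reduces exactly
#' to [hill_mean()] with the corresponding single-drug parameters, and the
#' surface there is independent of `alpha`.
#'
#' Weights are computed on the log scale and normalised by their maximum, so
#' the surface stays finite for extreme slopes or dose/IC50 ratios.
#'
#' @param x1,x2 Doses of the two drugs, non-negative; vectorised in parallel.
#' @param E0,E1,E2,E3 Asymptotic response levels.
#' @param C1,C2 IC50s (> 0). @param H1,H2 Hill slopes (> 0).
#' @param alpha Association parameter (> 0).
#' @return Expected response(s).
#' @examples
#' combo_mean(1, 1, E0 = 100, E1 = 0, E2 = 0, E3 = 0,
#'            C1 = 1, C2 = 1, H1 = 1, H2 = 1, alpha = 1) # 25
#' @export
combo_mean <- function(x1, x2, E0, E1, E2, E3, C1, C2, H1, H2, alpha) {
  if (any(!is.finite(x1)) || any(!is.finite(x2)) || any(x1 < 0) || any(x2 < 0)) {
    abort("doses must be finite and non-negative.")
  }
  stopifnot(C1 > 0, C2 > 0, H1 > 0, H2 > 0, alpha > 0)
  lw1 <- ifelse(x1 > 0, H1 * (log(x1) - log(C1)), -Inf)
  lw2 <- ifelse(x2 > 0, H2 * (log(x2) - log(C2)), -Inf)
  lw3 <- log(alpha) + lw1 + lw2
  mx <- pmax(0, lw1, lw2, lw3)
  w0 <- exp(-mx)
  w1 <- exp(lw1 - mx)
  w2 <- exp(lw2 - mx)
  w3 <- exp(lw3 - mx)
  (w0 * E0 + w1 * E1 + w2 * E2 + w3 * E3) / (w0 + w1 + w2 + w3)
}

#' Excess maximal effect over the highest single agent
#'
#' The efficacy synergy score `delta_hsa = min(E1, E2) - E3`: the gain in
#' maximal effect of the combination over the more effective of the two
#' single drugs. On the decreasing-response scale the more effective single
#' agent has the *lower* maximal level, so `min` selects it; a positive value
#' means the combination pushes the maximal effect beyond either drug alone
#' (synergistic efficacy). Applied per posterior draw so that the minimum is
#' taken inside the joint posterior, never on marginal summaries.
#'
#' @param E1,E2 Maximal-effect levels of drugs 1 and 2 alone; vectorised.
#' @param E3 Maximal-effect level of the combination.
#' @return `min(E1, E2) - E3`, in response units.
#' @examples
#' delta_hsa(E1 = 40, E2 = 30, E3 = 10) # 20
#' @export
delta_hsa <- function(E1, E2, E3) {
  pmin(E1, E2) - E3
}
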