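#' Prior configuration for the dose-response model
#'
#' Collects the constants of the prior:
#' * `E0 ~ Normal(B, variance 0.03 * B)` — the dose-zero base level is
#'   probabilistic because the normalisation measurement is itself noisy;
#'   for `B = 100` the standard deviation is `sqrt(3) ~ 1.73`.
#' * `Ei / E0 ~ Uniform(0, 1)` or `Beta(beta_a, beta_b)` — the normalised
#'   maximal-effect levels. The default Beta(0.46, 0.58) shape is an
#'   empirical prior fitted to single-agent screening data, bimodal at the
#'   extremes: a drug at saturating dose tends to be either highly effective
#'   or essentially inactive.
#' * `log C ~ Uniform(log delta, log upper)` — uninformative over potency;
#'   `delta` must be below every non-zero dose and `upper` above every dose
#'   so that an IC50 outside the tested range stays a-priori possible.
#' * `H, sigma, alpha ~ lognormal(0, 1)` — positive, moderately small;
#'   `P(H < 5) ~ 0.95` a priori, and the alpha prior has median 1 (no
#'   potency interaction).
#'
#' @param B Normalised inhibition at dose zero (100 under the DREAM
#'   convention).
#' @param delta,upper Bounds of the uniform prior on `log C`, on the raw dose
#'   scale. Defaults `1e-10` and `1e6` suit micromolar screening doses; use
#'   [prior_from_data()] to adapt them to a dataset.
#' @param efficacy_prior `"uniform"` or `"beta"` prior for `Ei / E0`.
#' @param beta_a,beta_b Beta shape constants (defaults 0.46, 0.58).
#' @return A `prior_config` list.
#' @export
prior_config <- function(B = 100, delta = 1e-10, upper = 1e6,
                         efficacy_prior = c("uniform", "beta"),
                         beta_a = 0.46, beta_b = 0.58) {
  efficacy_prior <- match.arg(efficacy_prior)
  if (!(is.numeric(delta) && is.numeric(upper) && delta > 0 && delta < upper)) {
    abort("need 0 < delta < upper.")
  }
  if (!(B > 0 && beta_a > 0 && beta_b > 0)) abort("B and Beta shapes must be positive.")
  structure(
    list(
      B = B, delta = delta, upper = upper,
      efficacy_prior = efficacy_prior, beta_a = beta_a, beta_b = beta_b
    ),
    class = "prior_config"
  )
}

#' @export
print.prior_config <- function(x, ...) {
  cat(sprintf(
    "<prior_config: B = %g, log C ~ U(log %g, log %g), Ei/E0 ~ %s>\n",
    x$B, x$delta, x$upper,
    if (x$efficacy_prior == "beta") {
      sprintf("Beta(%g, %g)", x$beta_a, x$beta_b)
    } else {
      "U(0, 1)"
    }
  ))
  invisible(x)
}

#' @describeIn prior_config Derive the `log C` bounds from a dataset:
#'   `delta` is half the smallest non-zero dose and `upper` ten times the
#'   largest dose, so the uniform support brackets the tested range; `B` is
#'   taken from the dataset metadata.
#' @param data A [dose_response()] object.
#' @param ... Passed on to `prior_config()`.
#' @export
prior_from_data <- function(data, ...) {
  doses <- as.matrix(as_tibble(data)[grep("^dose", names(data))])
  pos <- doses[doses > 0]
  if (!length(pos)) abort("cannot derive log C bounds without a positive dose.")
  prior_config(B = dr_base(data), delta = min(pos) / 2, upper = 10 * max(doses), ...)
}

# log-density of one normalised efficacy ratio, with the 1/E0 Jacobian that
# maps the ratio density to the Ei scale
ratio_log_density <- function(Ei, E0, prior) {
  r <- Ei / E0
  if (r < 0 || r > 1) {
    return(-Inf)
  }
  lp <- if (prior$efficacy_prior == "beta") {
    dbeta(r, prior$beta_a, prior$beta_b, log = TRUE)
  } else {
    dunif(r, 0, 1, log = TRUE)
  }
  lp - log(abs(E0))
}

#' Log prior density
#'
#' Joint log prior of the model parameters in the model's native
#' parameterisation: Normal density for `E0`; the ratio prior for each
#' `Ei / E0` (including the change-of-variable Jacobian `1/E0`, so the value
#' is a density in `Ei` given `E0`); a Uniform density for `log C`; and
#' lognormal densities for `H`, `sigma` (and `alpha` in the combination
#' setting). Returns `-Inf` outside the support instead of raising an error.
#'
#' @param params Named list. Monotherapy: `E0, E1, C, H, sigma`.
#'   Combination: `E0, E1, E2, E3, C1, C2, H1, H2, alpha, sigma`.
#' @param prior A [prior_config()].
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_prior_mono <- function(params, prior = prior_config()) {
  p <- params
  if (p$E0 <= 0 || p$C <= 0 || p$H <= 0 || p$sigma <= 0) {
    return(-Inf)
  }
  lC <- log(p$C)
  if (lC < log(prior$delta) || lC > log(prior$upper)) {
    return(-Inf)
  }
  dnorm(p$E0, prior$B, sqrt(0.03 * prior$B), log = TRUE) +
    ratio_log_density(p$E1, p$E0, prior) +
    dunif(lC, log(prior$delta), log(prior$upper), log = TRUE) +
    dlnorm(p$H, 0, 1, log = TRUE) +
    dlnorm(p$sigma, 0, 1, log = TRUE)
}

#' @rdname log_prior_mono
#' @export
log_prior_combo <- function(params, prior = prior_config()) {
  p <- params
  if (p$E0 <= 0 || p$C1 <= 0 || p$C2 <= 0 || p$H1 <= 0 || p$H2 <= 0 ||
    p$alpha <= 0 || p$sigma <= 0) {
    return(-Inf)
  }
  lC <- c(log(p$C1), log(p$C2))
  if (any(lC < log(prior$delta)) || any(lC > log(prior$upper))) {
    return(-Inf)
  }
  dnorm(p$E0, prior$B, sqrt(0.03 * prior$B), log = TRUE) +
    ratio_log_density(p$E1, p$E0, prior) +
    ratio_log_density(p$E2, p$E0, prior) +
    ratio_log_density(p$E3, p$E0, prior) +
    sum(dunif(lC, log(prior$delta), log(prior$upper), log = TRUE)) +
    dlnorm(p$H1, 0, 1, log = TRUE) +
    dlnorm(p$H2, 0, 1, log = TRUE) +
    dlnorm(p$alpha, 0, 1, log = TRUE) +
    dlnorm(p$sigma, 0, 1, log = TRUE)
}

#' Log likelihood
#'
#' Sum of Gaussian log densities of the observed responses around the Hill
#' mean ([hill_mean()] or [combo_mean()]) with standard deviation `sigma`.
#' Measurements are conditionally independent given the doses (screening
#' wells are run on separate plates). In the combination setting,
#' monotherapy slice points (one dose equal to zero) contribute through the
#' reduced single-drug Hill curve automatically.
#'
#' @inheritParams log_prior_mono
#' @param data A [dose_response()] dataset (or data frame with the same
#'   columns) in the matching setting.
#' @return Scalar log likelihood.
#' @export
log_lik_mono <- function(params, data) {
  if (nrow(data) == 0) abort("empty dataset.")
  if ("dose2" %in% names(data)) abort("monotherapy likelihood needs single-dose data.")
  p <- params
  mu <- hill_mean(data$dose1, p$E0, p$E1, p$C, p$H)
  sum(dnorm(data$response, mu, p$sigma, log = TRUE))
}

#' @rdname log_lik_mono
#' @export
log_lik_combo <- function(params, data) {
  if (nrow(data) == 0) abort("empty dataset.")
  if (!"dose2" %in% names(data)) abort("combination likelihood needs two-dose data.")
  p <- params
  mu <- combo_mean(
    data$dose1, data$dose2, p$E0, p$E1, p$E2, p$E3,
    p$C1, p$C2, p$H1, p$H2, p$alpha
  )
  sum(dnorm(data$response, mu, p$sigma, log = TRUE))
}

#' Sample parameters from the prior
#'
#' Independent draws from the joint prior of [prior_config()], following the
#' hierarchical scheme: `E0` first, then each efficacy ratio, then
#' `Ei = ratio * E0`; `C` is drawn as `exp(Uniform(log delta, log upper))`.
#' Every draw satisfies the parameter-type invariants and has finite log
#' prior.
#'
#' @param n Number of draws.
#' @param prior A [prior_config()].
#' @param setting `"mono"` or `"combo"`.
#' @param seed Optional integer; when supplied, draws are reproducible.
#' @return A tibble with one row per draw, columns `.draw` plus the
#'   parameters of the chosen setting.
#' @examples
#' sample_prior(3, prior_config(), "combo", seed = 1)
#' @export
sample_prior <- function(n, prior = prior_config(), setting = c("mono", "combo"),
                         seed = NULL) {
  setting <- match.arg(setting)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rratio <- function(n) {
    if (prior$efficacy_prior == "beta") rbeta(n, prior$beta_a, prior$beta_b) else runif(n)
  }
  E0 <- rnorm(n, prior$B, sqrt(0.03 * prior$B))
  rC <- function(n) exp(runif(n, log(prior$delta), log(prior$upper)))
  if (setting == "mono") {
    tibble(
      .draw = seq_len(n), E0 = E0, E1 = rratio(n) * E0,
      C = rC(n), H = rlnorm(n), sigma = rlnorm(n)
    )
  } else {
    tibble(
      .draw = seq_len(n), E0 = E0,
      E1 = rratio(n) * E0, E2 = rratio(n) * E0, E3 = rratio(n) * E0,
      C1 = rC(n), C2 = rC(n), H1 = rlnorm(n), H2 = rlnorm(n),
      alpha = rlnorm(n), sigma = rlnorm(n)
    )
  }
}
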