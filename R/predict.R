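# M x N matrix of model means: one row per posterior draw, one column per
# dose point in `newdata`
draw_mean_matrix <- function(fit, newdata) {
  d <- fit$draws
  if (fit$setting == "mono") {
    x <- newdata$dose1
    lx <- ifelse(x > 0, log(x), 0)
    lw <- d$H %o% lx - d$H * log(d$C) # H_m * (lx_n - lC_m)
    frac <- plogis(lw)
    frac[, x == 0] <- 0
    d$E0 + (d$E1 - d$E0) * frac
  } else {
    if (!"dose2" %in% names(newdata)) {
      abort("combination posterior needs dose1 and dose2 in `newdata`.")
    }
    x1 <- newdata$dose1
    x2 <- newdata$dose2
    lw1 <- d$H1 %o% ifelse(x1 > 0, log(x1), 0) - d$H1 * log(d$C1)
    lw2 <- d$H2 %o% ifelse(x2 > 0, log(x2), 0) - d$H2 * log(d$C2)
    lw1[, x1 == 0] <- -Inf
    lw2[, x2 == 0] <- -Inf
    lw3 <- log(d$alpha) + lw1 + lw2
    mx <- pmax(0, lw1, lw2, lw3)
    w0 <- exp(-mx)
    w1 <- exp(lw1 - mx)
    w2 <- exp(lw2 - mx)
    w3 <- exp(lw3 - mx)
    (w0 * d$E0 + w1 * d$E1 + w2 * d$E2 + w3 * d$E3) / (w0 + w1 + w2 + w3)
  }
}

#' Posterior predictive quantities at new doses
#'
#' The posterior predictive distribution of an untested response is the
#' Monte-Carlo mixture over the `M` retained draws:
#' `p(y | D, x) ~ (1/M) * sum_m Normal(y; mean(theta_m, x), sigma_m)` —
#' a mixture of Gaussians, one component per draw, *not* a single Gaussian
#' at the posterior-mean parameters.
#'
#' * `predict()` returns the predictive mean `(1/M) * sum_m mean(theta_m, x)`
#'   (equal to the mixture mean because the noise is zero-mean) as a `.pred`
#'   column.
#' * `predictive_density()` evaluates the mixture density at observed
#'   responses.
#' * `pit_values()` evaluates the mixture CDF at observed responses — the
#'   probability integral transform, uniform on `[0, 1]` when the predictive
#'   distribution is calibrated.
#'
#' @param object,fit A `dr_fit`.
#' @param newdata Data frame of dose points in the fit's setting (`dose1`
#'   [+ `dose2`]); for `predictive_density()` and `pit_values()` it must
#'   also hold the observed `response`.
#' @param ... Unused.
#' @return `predict()`: `newdata` as a tibble with `.pred` appended.
#'   `predictive_density()`: the same with `.density` and `.log_density`.
#'   `pit_values()`: numeric vector of PIT values in `[0, 1]`.
#' @export
predict.dr_fit <- function(object, newdata, ...) {
  mu <- draw_mean_matrix(object, newdata)
  dplyr::mutate(as_tibble(newdata), .pred = colMeans(mu))
}

#' @rdname predict.dr_fit
#' @export
predictive_density <- function(fit, newdata) {
  stopifnot(inherits(fit, "dr_fit"), "response" %in% names(newdata))
  mu <- draw_mean_matrix(fit, newdata)
  dens <- vapply(seq_len(nrow(newdata)), function(j) {
    mean(dnorm(newdata$response[j], mu[, j], fit$draws$sigma))
  }, 0)
  dplyr::mutate(as_tibble(newdata), .density = dens, .log_density = log(dens))
}

#' @rdname predict.dr_fit
#' @export
pit_values <- function(fit, newdata) {
  stopifnot(inherits(fit, "dr_fit"), "response" %in% names(newdata))
  mu <- draw_mean_matrix(fit, newdata)
  vapply(seq_len(nrow(newdata)), function(j) {
    mean(pnorm(newdata$response[j], mu[, j], fit$draws$sigma))
  }, 0)
}

#' Kolmogorov-Smirnov uniformity test for PIT values
#'
#' One-sample K-S test of a vector of probability-integral-transform values
#' against the Uniform(0, 1) distribution, the standard check that a
#' predictive distribution is calibrated. The reference protocol applies the
#' test per combination (one PIT value per held-out point); the function
#' accepts PIT values pooled across combinations as well, which is a more
#' powerful but aggregate check.
#'
#' @param pit Numeric vector of values in `[0, 1]`.
#' @param level Significance level for the `calibrated` flag.
#' @return List with `statistic` (the maximal ECDF gap), `p_value` and
#'   `calibrated` (`p_value >= level`).
#' @examples
#' ks_uniformity(runif(100))
#' @export
ks_uniformity <- function(pit, level = 0.05) {
  if (length(pit) < 1 || any(!is.finite(pit)) || any(pit < 0 | pit > 1)) {
    abort("PIT values must lie in [0, 1].")
  }
  kt <- suppressWarnings(ks.test(pit, "punif"))
  list(
    statistic = unname(kt$statistic),
    p_value = unname(kt$p.value),
    calibrated = unname(kt$p.value) >= level
  )
}

#' Evaluate posterior predictions on held-out points
#'
#' Computes the held-out metrics for a fit and the split it was trained on:
#' the root-mean-square error of the posterior predictive means
#' `rmse = sqrt(sum_i (y_i - yhat_i)^2 / N)`, the per-point log predictive
#' densities (Monte-Carlo mixture, see [predictive_density()]) with their
#' mean as the summary test log-likelihood, and the PIT values with their
#' K-S uniformity p-value.
#'
#' The fit must have been trained on `split$train`: a fingerprint comparison
#' guards against train/test contamination.
#'
#' @param fit A `dr_fit` trained on `split$train`.
#' @param split A `dr_split` from [split_dream()], [split_almanac()] or
#'   [split_fraction()].
#' @return A `dr_eval`: list with `metrics` (tibble: `rmse`,
#'   `mean_log_density`, `n_test`, `ks_p`, `calibrated`) and `per_point`
#'   (tibble with doses, `response`, `.pred`, `.log_density`, `.pit`).
#' @export
evaluate_predictions <- function(fit, split) {
  stopifnot(inherits(fit, "dr_fit"), inherits(split, "dr_split"))
  if (!identical(fit$data_hash, dr_hash(split$train))) {
    abort("contamination guard: the fit was not trained on `split$train`.")
  }
  test <- split$test
  per <- predictive_density(fit, test)
  per$.pred <- predict(fit, test)$.pred
  per$.pit <- pit_values(fit, test)
  ks <- ks_uniformity(per$.pit)
  structure(
    list(
      metrics = tibble(
        rmse = sqrt(mean((per$response - per$.pred)^2)),
        mean_log_density = mean(per$.log_density),
        n_test = nrow(test),
        ks_p = ks$p_value,
        calibrated = ks$calibrated
      ),
      per_point = per
    ),
    class = "dr_eval"
  )
}

#' @export
print.dr_eval <- function(x, ...) {
  cat("<dr_eval>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x,object A `dr_eval`.
#' @param ... Unused.
#' @method glance dr_eval
#' @export
glance.dr_eval <- function(x, ...) x$metrics

#' Write an evaluation report as JSON
#'
#' Per-combination evaluation record: `{rmse, mean_log_density, n_test,
#' ks_p, pit[]}` plus the test-row indices of the split when supplied, so
#' the exact split can be reproduced.
#'
#' @param x A `dr_eval`.
#' @param path Output JSON path.
#' @param split Optional `dr_split` whose `test_idx` is recorded.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(x, path, split = NULL) {
  out <- c(
    as.list(x$metrics[c("rmse", "mean_log_density", "n_test", "ks_p")]),
    list(pit = x$per_point$.pit)
  )
  if (!is.null(split)) {
    out$strategy <- split$strategy
    out$seed <- split$seed
    out$test_idx <- split$test_idx
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
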