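#' Posterior synergy report for a drug combination
#'
#' Transforms the posterior draws of a combination fit into the two decoupled
#' synergy summaries:
#' * **efficacy** — `delta_hsa = min(E1, E2) - E3` computed per draw (the
#'   minimum is taken inside the joint posterior), with
#'   `p_synergistic_efficacy = P(delta_hsa > 0 | D)`;
#' * **potency** — the association parameter `alpha`, with
#'   `p_synergistic_potency = P(alpha > 1 | D)`.
#'
#' Both probabilities are exact empirical fractions over the retained draws
#' with a strict inequality (a draw with `delta_hsa` exactly 0 counts as
#' non-synergistic); no smoothing is applied. A probability near 0.5 with a
#' wide sample spread signals that the data cannot yet resolve the synergy
#' and more (or larger-dose) measurements are needed.
#'
#' @param fit A `dr_fit` in the combination setting.
#' @return A `synergy_report`: list with `samples` (tibble: `.draw`,
#'   `delta_hsa`, `log_alpha`), `p_synergistic_efficacy`,
#'   `p_synergistic_potency`, `summaries` (the [tidy.dr_fit()] table) and
#'   `n_draws`.
#' @examples
#' \donttest{
#' sim <- simulate_dose_matrix("dream_6x6",
#'   truth = list(
#'     E0 = 100, E1 = 40, E2 = 50, E3 = 5, C1 = 1, C2 = 1,
#'     H1 = 1, H2 = 1, alpha = 5, sigma = 3
#'   ), seed = 1
#' )
#' synergy(fit_dose_response(sim$data, seed = 1))
#' }
#' @export
synergy <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  if (fit$setting != "combo") {
    abort("synergy summaries require a combination fit; this posterior is monotherapy.")
  }
  d <- fit$draws
  samples <- tibble(
    .draw = d$.draw,
    delta_hsa = delta_hsa(d$E1, d$E2, d$E3),
    log_alpha = log(d$alpha)
  )
  structure(
    list(
      samples = samples,
      p_synergistic_efficacy = mean(samples$delta_hsa > 0),
      p_synergistic_potency = mean(d$alpha > 1),
      summaries = tidy(fit),
      n_draws = nrow(d)
    ),
    class = "synergy_report"
  )
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<synergy_report: %d draws>\n",
      "  P(synergistic efficacy)  P(delta_hsa > 0 | D) = %.3f\n",
      "  P(synergistic potency)   P(alpha > 1 | D)     = %.3f\n"
    ),
    x$n_draws, x$p_synergistic_efficacy, x$p_synergistic_potency
  ))
  invisible(x)
}

#' @rdname synergy
#' @param x,object A `synergy_report`.
#' @param ... Unused.
#' @method tidy synergy_report
#' @export
tidy.synergy_report <- function(x, ...) {
  purrr::map_dfr(
    list(delta_hsa = x$samples$delta_hsa, log_alpha = x$samples$log_alpha),
    function(v) {
      tibble(
        estimate = median(v),
        conf.low = quantile(v, 0.025, names = FALSE),
        conf.high = quantile(v, 0.975, names = FALSE)
      )
    },
    .id = "term"
  )
}

#' @rdname synergy
#' @method glance synergy_report
#' @export
glance.synergy_report <- function(x, ...) {
  tibble(
    p_synergistic_efficacy = x$p_synergistic_efficacy,
    p_synergistic_potency = x$p_synergistic_potency,
    n_draws = x$n_draws
  )
}

#' Write a synergy report as JSON
#'
#' @param x A `synergy_report`.
#' @param path Output JSON path.
#' @param samples_csv Optional path for a CSV of the raw per-draw
#'   `delta_hsa` / `log_alpha` samples.
#' @return `path`, invisibly.
#' @export
write_synergy_json <- function(x, path, samples_csv = NULL) {
  jsonlite::write_json(
    list(
      p_synergistic_efficacy = x$p_synergistic_efficacy,
      p_synergistic_potency = x$p_synergistic_potency,
      summaries = x$summaries,
      n_draws = x$n_draws
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(samples_csv)) {
    write.csv(as.data.frame(x$samples), samples_csv, row.names = FALSE)
  }
  invisible(path)
}
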