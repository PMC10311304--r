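#' Prior predictive curve fan
#'
#' Draws monotherapy parameter sets from the prior and plots the expected
#' dose-response curve of each, the standard visual check that the prior
#' covers a wide but Hill-shaped family of curves.
#'
#' @param prior A [prior_config()].
#' @param n Number of prior curves.
#' @param dose_range Length-2 positive dose range (log-spaced grid).
#' @param seed Optional seed.
#' @return A ggplot object.
#' @export
plot_prior_curves <- function(prior = prior_config(), n = 300,
                              dose_range = c(1e-3, 1e3), seed = NULL) {
  draws <- sample_prior(n, prior, "mono", seed = seed)
  x <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = 80)
  curves <- purrr::pmap_dfr(
    draws[c(".draw", "E0", "E1", "C", "H")],
    function(.draw, E0, E1, C, H) {
      tibble(.draw = .draw, dose = x, response = hill_mean(x, E0, E1, C, H))
    }
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$dose, .data$response, group = .data$.draw)) +
    ggplot2::geom_line(alpha = 0.1, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dose", y = "expected response",
      title = sprintf("%d prior expected dose-response curves", n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response model
#'
#' Monotherapy fits show a fan of posterior expected curves over the data;
#' combination fits show the posterior-mean response surface on the
#' measured dose grid.
#'
#' @param object A `dr_fit`.
#' @param n_curves Curves to draw for monotherapy fans.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dr_fit
#' @export
autoplot.dr_fit <- function(object, n_curves = 100, ...) {
  data <- as_tibble(object$data)
  if (object$setting == "mono") {
    pos <- data$dose1[data$dose1 > 0]
    x <- 10^seq(log10(min(pos)) - 1, log10(max(pos)) + 1, length.out = 80)
    idx <- object$draws$.draw[seq(1, nrow(object$draws),
      length.out = min(n_curves, nrow(object$draws))
    )]
    sub <- object$draws[object$draws$.draw %in% idx, ]
    curves <- purrr::pmap_dfr(
      sub[c(".draw", "E0", "E1", "C", "H")],
      function(.draw, E0, E1, C, H) {
        tibble(.draw = .draw, dose1 = x, response = hill_mean(x, E0, E1, C, H))
      }
    )
    ggplot2::ggplot(curves, ggplot2::aes(.data$dose1, .data$response)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$.draw),
        alpha = 0.07, colour = "steelblue"
      ) +
      ggplot2::geom_point(data = data[data$dose1 > 0, ], colour = "firebrick") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "dose", y = "response", title = "posterior expected curves") +
      ggplot2::theme_minimal()
  } else {
    grid <- predict(object, data)
    ggplot2::ggplot(grid, ggplot2::aes(
      factor(signif(.data$dose1, 3)), factor(signif(.data$dose2, 3)),
      fill = .data$.pred
    )) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(
        x = "dose, drug 1", y = "dose, drug 2", fill = "posterior\nmean",
        title = "posterior mean response surface"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a synergy report
#'
#' Histograms of the posterior `delta_hsa` (efficacy) and `log(alpha)`
#' (potency) samples with the zero reference line; the mass to the right of
#' the line is the corresponding synergy probability.
#'
#' @param object A `synergy_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synergy_report
#' @export
autoplot.synergy_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, -".draw",
    names_to = "quantity", values_to = "value"
  )
  labs <- c(
    delta_hsa = sprintf(
      "delta HSA  (P > 0: %.1f%%)", 100 * object$p_synergistic_efficacy
    ),
    log_alpha = sprintf(
      "log alpha  (P > 0: %.1f%%)", 100 * object$p_synergistic_potency
    )
  )
  long$quantity <- labs[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior draws") +
    ggplot2::theme_minimal()
}
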