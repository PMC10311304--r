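default_dose_grid <- function(shape, truth = NULL) {
  if (shape == "dream_6x6") {
    if (is.null(truth)) {
      list(d1 = 10^seq(-2, 2), d2 = 10^seq(-2, 2))
    } else {
      list(d1 = truth$C1 * 10^seq(-2, 2), d2 = truth$C2 * 10^seq(-2, 2))
    }
  } else {
    if (is.null(truth)) {
      list(d1 = 10^(-1:1), d2 = 10^(-1:1))
    } else {
      list(d1 = truth$C1 * 10^(-1:1), d2 = truth$C2 * 10^(-1:1))
    }
  }
}

#' Simulate a dose-response matrix from the generative model
#'
#' Draws one synthetic combination screen from the model's own generative
#' process: a ground-truth parameter point (either supplied or sampled from
#' the [prior_config()] prior), the [combo_mean()] surface evaluated on the
#' dose grid, and i.i.d. Gaussian noise with the truth's `sigma` added to
#' *every* cell — including the base cell and the monotherapy slices.
#' Negative simulated responses are kept: the noise model allows them, and
#' the negative-response rejection rule applies to real screening data at
#' load time only.
#'
#' Shapes mirror the two public screening layouts: `"dream_6x6"` is 36
#' points (1 base + two 5-point monotherapy slices + a 5x5 grid) on 5-point
#' log-spaced dose grids; `"almanac_15"` is 16 points (1 base + two 3-point
#' slices + a 3x3 grid) on 3-point grids. When `truth` is supplied the
#' default grids are centred on its IC50s (doses from `C/100` to `100 C`),
#' which makes identifiability controllable: pass doses well below `C` to
#' reproduce the unsaturating, efficacy-uncertain regime. When the truth is
#' drawn from the prior the fixed default grids are used (the prior IC50
#' range spans many decades, so no grid can track it — that is the point of
#' prior-calibration studies).
#'
#' @param shape `"dream_6x6"` or `"almanac_15"`.
#' @param truth Optional named list of generating parameters
#'   (`E0, E1, E2, E3, C1, C2, H1, H2, alpha, sigma`); if `NULL`, sampled
#'   from `prior`.
#' @param prior A [prior_config()] used to sample the truth and as the `B`
#'   metadata of the dataset.
#' @param doses1,doses2 Optional strictly positive, sorted dose vectors
#'   overriding the default grids.
#' @param sigma Optional noise s.d. overriding the truth's `sigma`
#'   (e.g. `0` for a noiseless fixture).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A list with `data` (a [dose_response()] matrix) and `truth` (the
#'   generating parameters, with any `sigma` override applied).
#' @examples
#' sim <- simulate_dose_matrix("dream_6x6", seed = 42)
#' nrow(sim$data) # 36
#' @export
simulate_dose_matrix <- function(shape = c("dream_6x6", "almanac_15"),
                                 truth = NULL, prior = prior_config(),
                                 doses1 = NULL, doses2 = NULL, sigma = NULL,
                                 seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  explicit <- !is.null(truth)
  if (!explicit) {
    truth <- as.list(sample_prior(1, prior, "combo"))[-1]
  }
  grids <- default_dose_grid(shape, if (explicit) truth)
  d1 <- sort(doses1 %||% grids$d1)
  d2 <- sort(doses2 %||% grids$d2)
  if (any(d1 <= 0) || any(d2 <= 0)) abort("dose grids must be strictly positive.")
  if (!is.null(sigma)) truth$sigma <- sigma
  g <- tidyr::expand_grid(dose1 = c(0, d1), dose2 = c(0, d2))
  mu <- combo_mean(
    g$dose1, g$dose2, truth$E0, truth$E1, truth$E2, truth$E3,
    truth$C1, truth$C2, truth$H1, truth$H2, truth$alpha
  )
  g$response <- mu + rnorm(nrow(g), 0, truth$sigma)
  list(
    data = suppressWarnings(dose_response(g, B = prior$B)),
    truth = truth
  )
}

#' Simulate a suite of matrices
#'
#' `n_matrices` independent draws from [simulate_dose_matrix()], each with
#' its own recorded seed derived from `seed`, so any single matrix can be
#' regenerated exactly.
#'
#' @inheritParams simulate_dose_matrix
#' @param n_matrices Number of matrices.
#' @param seed Integer master seed; matrix `i` uses `seed + i`.
#' @param ... Passed to [simulate_dose_matrix()] (`truth`, `doses1`, ...).
#' @return A tibble manifest with columns `id`, `seed`, and list-columns
#'   `data` and `truth`.
#' @export
simulate_suite <- function(n_matrices, shape = c("dream_6x6", "almanac_15"),
                           prior = prior_config(), seed = 1L, ...) {
  shape <- match.arg(shape)
  stopifnot(n_matrices >= 1)
  purrr::map_dfr(seq_len(n_matrices), function(i) {
    s <- as.integer(seed) + i
    sim <- simulate_dose_matrix(shape, prior = prior, seed = s, ...)
    tibble(id = i, seed = s, data = list(sim$data), truth = list(sim$truth))
  })
}

#' Simulate a monotherapy dose-response curve
#'
#' Single-drug analogue of [simulate_dose_matrix()]: responses are
#' [hill_mean()] at the given doses (plus a dose-zero base point) with
#' Gaussian noise.
#'
#' @param doses Strictly positive dose vector.
#' @param truth Named list `E0, E1, C, H, sigma`; if `NULL`, sampled from
#'   `prior`.
#' @inheritParams simulate_dose_matrix
#' @return A list with `data` (a monotherapy [dose_response()]) and `truth`.
#' @export
simulate_dose_curve <- function(doses, truth = NULL, prior = prior_config(),
                                sigma = NULL, seed = NULL) {
  if (any(doses <= 0)) abort("doses must be strictly positive.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- as.list(sample_prior(1, prior, "mono"))[-1]
  if (!is.null(sigma)) truth$sigma <- sigma
  x <- c(0, sort(doses))
  mu <- hill_mean(x, truth$E0, truth$E1, truth$C, truth$H)
  out <- tibble(dose1 = x, response = mu + rnorm(length(x), 0, truth$sigma))
  list(data = suppressWarnings(dose_response(out, B = prior$B)), truth = truth)
}
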