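# Build a dr_fit by hand from a data frame of parameter draws, for oracle
# tests of the posterior-predictive machinery.
make_fit <- function(draws, setting, data, prior = dosebayes::prior_config()) {
  draws <- tibble::as_tibble(draws)
  n <- nrow(draws)
  full <- dplyr::bind_cols(
    tibble::tibble(.chain = 1L, .iteration = seq_len(n), .draw = seq_len(n)),
    draws
  )
  fit <- structure(
    list(
      draws = full, setting = setting, prior = prior,
      control = dosebayes::mcmc_control(iterations = n + 1, warmup = 1, chains = 1),
      data = data, data_hash = dosebayes:::dr_hash(data), diagnostics = NULL
    ),
    class = "dr_fit"
  )
  fit
}

combo_truth_example <- function() {
  list(
    E0 = 100, E1 = 40, E2 = 50, E3 = 5, C1 = 1, C2 = 2,
    H1 = 1.2, H2 = 0.8, alpha = 3, sigma = 3
  )
}

fast_control <- function() dosebayes::mcmc_control(iterations = 600, warmup = 300, chains = 2)
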