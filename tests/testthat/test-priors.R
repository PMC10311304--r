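test_that("prior_config validates its constants", {
  expect_error(prior_config(delta = 1, upper = 0.5), "delta")
  expect_error(prior_config(delta = 0), "delta")
  expect_error(prior_config(B = -1), "positive")
  cfg <- prior_config(efficacy_prior = "beta")
  expect_equal(cfg$beta_a, 0.46)
  expect_equal(cfg$beta_b, 0.58)
})

test_that("prior_from_data brackets the dose range", {
  sim <- simulate_dose_matrix("dream_6x6", truth = combo_truth_example(), seed = 1)
  cfg <- prior_from_data(sim$data)
  pos <- with(sim$data, c(dose1[dose1 > 0], dose2[dose2 > 0]))
  expect_equal(cfg$delta, min(pos) / 2)
  expect_equal(cfg$upper, 10 * max(pos))
  expect_lt(cfg$delta, min(pos))
  expect_gt(cfg$upper, max(pos))
})

test_that("log priors match independently coded densities", {
  for (eff in c("uniform", "beta")) {
    cfg <- prior_config(efficacy_prior = eff)
    ratio_oracle <- function(r) {
      if (eff == "beta") beta_lpdf(r, 0.46, 0.58) else unif_lpdf(r, 0, 1)
    }
    pm <- list(E0 = 98.5, E1 = 30, C = 2.5, H = 1.4, sigma = 2.2)
    oracle_m <- norm_lpdf(pm$E0, 100, sqrt(3)) +
      ratio_oracle(pm$E1 / pm$E0) - log(pm$E0) +
      unif_lpdf(log(pm$C), log(1e-10), log(1e6)) +
      lnorm_lpdf(pm$H) + lnorm_lpdf(pm$sigma)
    expect_equal(log_prior_mono(pm, cfg), oracle_m, tolerance = 1e-10)

    pc <- list(
      E0 = 101, E1 = 30, E2 = 55, E3 = 8, C1 = 2.5, C2 = 0.3,
      H1 = 1.4, H2 = 0.7, alpha = 2.8, sigma = 2.2
    )
    oracle_c <- norm_lpdf(pc$E0, 100, sqrt(3)) +
      sum(sapply(c(pc$E1, pc$E2, pc$E3) / pc$E0, ratio_oracle)) - 3 * log(pc$E0) +
      unif_lpdf(log(pc$C1), log(1e-10), log(1e6)) +
      unif_lpdf(log(pc$C2), log(1e-10), log(1e6)) +
      lnorm_lpdf(pc$H1) + lnorm_lpdf(pc$H2) +
      lnorm_lpdf(pc$alpha) + lnorm_lpdf(pc$sigma)
    expect_equal(log_prior_combo(pc, cfg), oracle_c, tolerance = 1e-10)
  }
})

test_that("log priors return -Inf outside the support, not an error", {
  cfg <- prior_config(delta = 1e-3, upper = 1e3)
  base <- list(E0 = 100, E1 = 50, C = 1, H = 1, sigma = 1)
  expect_identical(log_prior_mono(modifyList(base, list(C = 2e3)), cfg), -Inf)
  expect_identical(log_prior_mono(modifyList(base, list(C = 1e-4)), cfg), -Inf)
  expect_identical(log_prior_mono(modifyList(base, list(E1 = 120)), cfg), -Inf)
  expect_identical(log_prior_mono(modifyList(base, list(E1 = -5)), cfg), -Inf)
  expect_identical(log_prior_mono(modifyList(base, list(H = -1)), cfg), -Inf)
  cb <- modifyList(combo_truth_example(), list(E3 = 150))
  expect_identical(log_prior_combo(cb, cfg), -Inf)
  expect_identical(
    log_prior_combo(modifyList(combo_truth_example(), list(alpha = 0)), cfg),
    -Inf
  )
})

test_that("known single-factor contributions appear in the log prior", {
  # a uniform efficacy ratio of 0.5 contributes only its Jacobian;
  # doubling E1 to 1.0 keeps the U(0,1) density at log 1 = 0
  cfg <- prior_config()
  a <- list(E0 = 100, E1 = 50, C = 1, H = 1, sigma = 1)
  b <- modifyList(a, list(E1 = 100))
  expect_equal(log_prior_mono(a, cfg), log_prior_mono(b, cfg))
  # H at its prior median contributes the lognormal log-density -log(sqrt(2*pi))
  h1 <- modifyList(a, list(H = 1))
  h2 <- modifyList(a, list(H = exp(1)))
  expect_equal(
    log_prior_mono(h1, cfg) - log_prior_mono(h2, cfg),
    -log(sqrt(2 * pi)) - lnorm_lpdf(exp(1))
  )
  # alpha at 1 is the lognormal median: same contribution in the combo prior
  c1 <- modifyList(combo_truth_example(), list(alpha = 1))
  c2 <- modifyList(combo_truth_example(), list(alpha = exp(1)))
  expect_equal(
    log_prior_combo(c1, cfg) - log_prior_combo(c2, cfg),
    -log(sqrt(2 * pi)) - lnorm_lpdf(exp(1))
  )
})

test_that("prior draws are reproducible and respect the type invariants", {
  cfg <- prior_config(efficacy_prior = "beta")
  d1 <- sample_prior(500, cfg, "combo", seed = 42)
  d2 <- sample_prior(500, cfg, "combo", seed = 42)
  expect_identical(d1, d2)
  expect_true(all(d1$C1 > 0 & d1$C2 > 0 & d1$H1 > 0 & d1$H2 > 0 &
    d1$alpha > 0 & d1$sigma > 0))
  ratios <- cbind(d1$E1 / d1$E0, d1$E2 / d1$E0, d1$E3 / d1$E0)
  expect_true(all(ratios >= 0 & ratios <= 1))
  lp <- apply(d1, 1, function(row) {
    log_prior_combo(as.list(row[-1]), cfg)
  })
  expect_true(all(is.finite(lp)))
})

test_that("prior draws reproduce the stated marginal probabilities", {
  n <- 20000
  dm <- sample_prior(n, prior_config(efficacy_prior = "beta"), "mono", seed = 7)
  # lognormal(0,1) slope prior puts ~95% of its mass below 5
  expect_equal(mean(dm$H < 5), plnorm(5), tolerance = 0.01)
  expect_equal(round(mean(dm$H < 5), 1), 0.9)
  expect_equal(mean(dm$sigma < 5), plnorm(5), tolerance = 0.01)
  # empirical Beta prior mass near total ineffectiveness
  expect_equal(mean(dm$E1 / dm$E0 < 0.05), pbeta(0.05, 0.46, 0.58), tolerance = 0.015)
  # alpha prior median 1
  dc <- sample_prior(n, prior_config(), "combo", seed = 8)
  expect_equal(median(dc$alpha), 1, tolerance = 0.03)
})

test_that("prior draws pass goodness-of-fit against each marginal", {
  n <- 10000
  cfg <- prior_config()
  d <- sample_prior(n, cfg, "combo", seed = 123)
  ks_p <- function(x, cdf) suppressWarnings(ks.test(x, cdf)$p.value)
  expect_gt(ks_p(d$E0, function(q) pnorm(q, 100, sqrt(3))), 0.001)
  expect_gt(ks_p(d$E1 / d$E0, "punif"), 0.001)
  expect_gt(ks_p(log(d$C1), function(q) punif(q, log(1e-10), log(1e6))), 0.001)
  expect_gt(ks_p(log(d$C2), function(q) punif(q, log(1e-10), log(1e6))), 0.001)
  expect_gt(ks_p(d$H1, "plnorm"), 0.001)
  expect_gt(ks_p(d$alpha, "plnorm"), 0.001)
  expect_gt(ks_p(d$sigma, "plnorm"), 0.001)
  db <- sample_prior(n, prior_config(efficacy_prior = "beta"), "mono", seed = 124)
  expect_gt(ks_p(db$E1 / db$E0, function(q) pbeta(q, 0.46, 0.58)), 0.001)
})
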