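mono_fixture <- function() {
  dose_response(data.frame(dose = c(0, 1, 10), response = c(100, 60, 20)))
}

single_draw <- function() {
  tibble::tibble(E0 = 100, E1 = 10, C = 1, H = 1.5, sigma = 2)
}

test_that("predictive density with one draw is a single Gaussian", {
  fit <- make_fit(single_draw(), "mono", mono_fixture())
  nd <- tibble::tibble(dose1 = c(0, 1, 5), response = c(99, 57, 30))
  mu <- hill_mean(nd$dose1, 100, 10, 1, 1.5)
  got <- predictive_density(fit, nd)
  expect_equal(got$.density, dnorm(nd$response, mu, 2), tolerance = 1e-14)
  # two identical draws collapse to the same mixture
  fit2 <- make_fit(dplyr::bind_rows(single_draw(), single_draw()), "mono", mono_fixture())
  expect_equal(predictive_density(fit2, nd)$.density, got$.density, tolerance = 1e-14)
})

test_that("mixture density and PIT match hand-computed averages over draws", {
  draws <- tibble::tibble(
    E0 = c(100, 98, 102, 101), E1 = c(10, 0, 25, 15),
    C = c(1, 2, 0.5, 1.5), H = c(1, 2, 0.8, 1.2), sigma = c(2, 3, 1.5, 2.5)
  )
  fit <- make_fit(draws, "mono", mono_fixture())
  x <- 2.5
  y <- 55
  mus <- mapply(hill_oracle, x, draws$E0, draws$E1, draws$C, draws$H)
  expect_equal(
    predictive_density(fit, tibble::tibble(dose1 = x, response = y))$.density,
    mean(exp(norm_lpdf(y, mus, draws$sigma))),
    tolerance = 1e-10
  )
  expect_equal(
    pit_values(fit, tibble::tibble(dose1 = x, response = y)),
    mean(pnorm(y, mus, draws$sigma)),
    tolerance = 1e-12
  )
  # predictive mean is the arithmetic average of per-draw means
  expect_equal(
    predict(fit, tibble::tibble(dose1 = x))$.pred,
    mean(mus),
    tolerance = 1e-12
  )
  # at dose zero the predictive mean is the posterior mean of E0
  expect_equal(predict(fit, tibble::tibble(dose1 = 0))$.pred, mean(draws$E0))
})

test_that("the mixture predictive density integrates to one", {
  draws <- tibble::tibble(
    E0 = c(100, 99), E1 = c(20, 5), C = c(1, 3), H = c(1, 2), sigma = c(2, 4)
  )
  fit <- make_fit(draws, "mono", mono_fixture())
  ygrid <- seq(-60, 180, length.out = 4001)
  dens <- predictive_density(
    fit, tibble::tibble(dose1 = rep(2, length(ygrid)), response = ygrid)
  )$.density
  expect_equal(sum(dens) * diff(ygrid[1:2]), 1, tolerance = 1e-6)
})

test_that("PIT hits its analytic extremes and centre", {
  fit <- make_fit(single_draw(), "mono", mono_fixture())
  mu1 <- hill_mean(1, 100, 10, 1, 1.5)
  expect_equal(pit_values(fit, tibble::tibble(dose1 = 1, response = mu1)), 0.5)
  expect_lt(pit_values(fit, tibble::tibble(dose1 = 1, response = mu1 - 50)), 1e-6)
  expect_gt(pit_values(fit, tibble::tibble(dose1 = 1, response = mu1 + 50)), 1 - 1e-6)
})

test_that("K-S uniformity test matches the ECDF max-gap oracle", {
  set.seed(9)
  u <- runif(40)
  ks <- ks_uniformity(u)
  expect_equal(ks$statistic, ks_stat_oracle(u), tolerance = 1e-12)
  expect_equal(ks$p_value, suppressWarnings(ks.test(u, "punif")$p.value))
  # grossly non-uniform PIT values are flagged
  expect_lt(ks_uniformity(rep(0.999, 30))$p_value, 1e-10)
  expect_false(ks_uniformity(rep(0.999, 30))$calibrated)
  expect_error(ks_uniformity(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(ks_uniformity(numeric()), "\\[0, 1\\]")
})

test_that("K-S rejection rate on truly uniform PIT sits at the nominal level", {
  set.seed(31)
  rej <- mean(replicate(400, ks_uniformity(runif(35))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("evaluation computes RMSE and mean log density on the held-out points", {
  mono <- dose_response(data.frame(
    dose = c(0, 0.1, 0.5, 1, 5, 10),
    response = c(100, 95, 80, 60, 30, 20)
  ))
  sp <- split_fraction(mono, fraction = 0.4, seed = 2)
  fit <- make_fit(single_draw(), "mono", sp$train)
  ev <- evaluate_predictions(fit, sp)
  pred <- predict(fit, sp$test)$.pred
  expect_equal(ev$metrics$rmse, sqrt(mean((sp$test$response - pred)^2)))
  expect_equal(ev$metrics$n_test, 2)
  expect_equal(
    ev$metrics$mean_log_density,
    mean(predictive_density(fit, sp$test)$.log_density)
  )
  # rmse is invariant to test-point order; log-density sums are additive
  rev_test <- sp$test[2:1, ]
  expect_equal(
    sqrt(mean((rev_test$response - predict(fit, rev_test)$.pred)^2)),
    ev$metrics$rmse
  )
  ld <- predictive_density(fit, sp$test)$.log_density
  expect_equal(sum(ld), sum(ld[1]) + sum(ld[2]))
  # single-point splits give |residual| as RMSE
  sp1 <- split_fraction(mono, fraction = 0.2, seed = 5)
  fit1 <- make_fit(single_draw(), "mono", sp1$train)
  ev1 <- evaluate_predictions(fit1, sp1)
  expect_equal(
    ev1$metrics$rmse,
    abs(sp1$test$response - predict(fit1, sp1$test)$.pred)
  )
})

test_that("the contamination guard rejects a fit trained on other data", {
  mono <- mono_fixture()
  sp <- split_fraction(
    dose_response(data.frame(dose = c(0, 1, 2, 5, 10), response = c(100, 80, 60, 40, 20))),
    fraction = 0.25, seed = 1
  )
  fit <- make_fit(single_draw(), "mono", mono) # trained elsewhere
  expect_error(evaluate_predictions(fit, sp), "contamination")
})
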