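#' MCMC sampler settings
#'
#' Defaults follow the reference configuration for screening-sized matrices:
#' 4 chains of 1000 iterations each, the first 500 of which are warm-up
#' (used for sampler adaptation and discarded), leaving
#' `chains * (iterations - warmup) = 2000` retained draws.
#'
#' @param iterations Iterations per chain (warm-up included).
#' @param warmup Warm-up iterations per chain (`< iterations`).
#' @param chains Number of chains.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(iterations = 1000, warmup = 500, chains = 4) {
  if (!(warmup >= 1 && warmup < iterations && chains >= 1)) {
    abort("need 1 <= warmup < iterations and chains >= 1.")
  }
  structure(list(iterations = iterations, warmup = warmup, chains = chains),
    class = "mcmc_control"
  )
}

# BUGS model code. Means are computed through logistic / log-sum weights so
# the surface stays finite for extreme slopes; zero doses enter via the pos
# indicator (the lx dummy value is multiplied away).
jags_model_mono <- function(prior) {
  ratio <- if (prior$efficacy_prior == "beta") "dbeta(a, b)" else "dunif(0, 1)"
  sprintf("model {
  for (i in 1:n) {
    mu[i] <- E0 + (E1 - E0) * pos[i] * ilogit(H * (lx[i] - logC))
    y[i] ~ dnorm(mu[i], tau)
  }
  E0 ~ dnorm(B, prec0)
  r1 ~ %s
  E1 <- r1 * E0
  logC ~ dunif(ld, lM)
  C <- exp(logC)
  H ~ dlnorm(0, 1)
  sigma ~ dlnorm(0, 1)
  tau <- 1 / (sigma * sigma)
}", ratio)
}

jags_model_combo <- function(prior) {
  ratio <- if (prior$efficacy_prior == "beta") "dbeta(a, b)" else "dunif(0, 1)"
  sprintf("model {
  for (i in 1:n) {
    lw1[i] <- pos1[i] * H1 * (lx1[i] - logC1) + (1 - pos1[i]) * (-1.0E6)
    lw2[i] <- pos2[i] * H2 * (lx2[i] - logC2) + (1 - pos2[i]) * (-1.0E6)
    lw3[i] <- logalpha + lw1[i] + lw2[i]
    mx[i] <- max(0, max(lw1[i], max(lw2[i], lw3[i])))
    w0[i] <- exp(-mx[i])
    w1[i] <- exp(lw1[i] - mx[i])
    w2[i] <- exp(lw2[i] - mx[i])
    w3[i] <- exp(lw3[i] - mx[i])
    mu[i] <- (w0[i] * E0 + w1[i] * E1 + w2[i] * E2 + w3[i] * E3) /
             (w0[i] + w1[i] + w2[i] + w3[i])
    y[i] ~ dnorm(mu[i], tau)
  }
  E0 ~ dnorm(B, prec0)
  r1 ~ %s
  r2 ~ %s
  r3 ~ %s
  E1 <- r1 * E0
  E2 <- r2 * E0
  E3 <- r3 * E0
  logC1 ~ dunif(ld, lM)
  logC2 ~ dunif(ld, lM)
  C1 <- exp(logC1)
  C2 <- exp(logC2)
  H1 ~ dlnorm(0, 1)
  H2 ~ dlnorm(0, 1)
  alpha ~ dlnorm(0, 1)
  logalpha <- log(alpha)
  sigma ~ dlnorm(0, 1)
  tau <- 1 / (sigma * sigma)
}", ratio, ratio, ratio)
}

#' Fit the Bayesian dose-response model
#'
#' Draws from the posterior of the Hill model ([hill_mean()] for monotherapy,
#' [combo_mean()] for two-drug combinations) under the [prior_config()]
#' prior, by Markov chain Monte Carlo (JAGS backend via \pkg{rjags}). The
#' posterior is asymptotically exact: draws target
#' `exp(log_prior + log_likelihood)`. Warm-up iterations are used for
#' sampler adaptation and discarded; each chain's RNG is seeded from `seed`,
#' so a repeated call with the same seed reproduces every draw.
#'
#' @param data A [dose_response()] dataset. Datasets with fewer than two
#'   strictly positive-dose points are accepted with a warning (the posterior
#'   then largely reflects the prior).
#' @param prior A [prior_config()]; by default derived from the data via
#'   [prior_from_data()].
#' @param control An [mcmc_control()].
#' @param seed Integer seed for the sampler RNGs.
#' @return A `dr_fit` object: a list with `draws` (tibble with `.chain`,
#'   `.iteration`, `.draw` and one column per parameter), `setting`, `prior`,
#'   `control`, `data`, `data_hash`, and `diagnostics` (see
#'   [diagnostics_report()]). Non-convergence (split-R-hat above 1.05 or low
#'   effective sample size) is flagged in the diagnostics and as a warning,
#'   never an error: the draws are returned and the caller decides.
#' @examples
#' \donttest{
#' sim <- simulate_dose_matrix("almanac_15", seed = 1)
#' fit <- fit_dose_response(sim$data, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_dose_response <- function(data, prior = NULL, control = mcmc_control(),
                              seed = 1L) {
  stopifnot(inherits(data, "dose_response"))
  prior <- prior %||% prior_from_data(data)
  setting <- dr_setting(data)
  doses <- as.matrix(as_tibble(data)[grep("^dose", names(data))])
  if (sum(rowSums(doses) > 0) < 2) {
    warn("fewer than 2 positive-dose points; the posterior will be close to the prior.")
  }
  base <- list(
    n = nrow(data), y = data$response, B = prior$B,
    prec0 = 1 / (0.03 * prior$B), ld = log(prior$delta), lM = log(prior$upper)
  )
  if (prior$efficacy_prior == "beta") {
    base$a <- prior$beta_a
    base$b <- prior$beta_b
  }
  if (setting == "mono") {
    jd <- c(base, list(
      lx = ifelse(data$dose1 > 0, log(data$dose1), 0),
      pos = as.numeric(data$dose1 > 0)
    ))
    code <- jags_model_mono(prior)
    pars <- c("E0", "E1", "C", "H", "sigma")
  } else {
    jd <- c(base, list(
      lx1 = ifelse(data$dose1 > 0, log(data$dose1), 0),
      pos1 = as.numeric(data$dose1 > 0),
      lx2 = ifelse(data$dose2 > 0, log(data$dose2), 0),
      pos2 = as.numeric(data$dose2 > 0)
    ))
    code <- jags_model_combo(prior)
    pars <- c("E0", "E1", "E2", "E3", "C1", "C2", "H1", "H2", "alpha", "sigma")
  }
  # overdispersed starting points drawn from the prior, one set per chain,
  # plus per-chain RNG seeds so the whole run is reproducible from `seed`
  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    lapply(seq_len(control$chains), function(k) {
      init <- list(
        E0 = rnorm(1, prior$B, sqrt(0.03 * prior$B)),
        r1 = runif(1, 0.05, 0.95),
        H = rlnorm(1), sigma = rlnorm(1),
        logC = runif(1, log(prior$delta), log(prior$upper))
      )
      if (setting == "combo") {
        init <- c(init[c("E0", "r1")], list(
          r2 = runif(1, 0.05, 0.95), r3 = runif(1, 0.05, 0.95),
          logC1 = runif(1, log(prior$delta), log(prior$upper)),
          logC2 = runif(1, log(prior$delta), log(prior$upper)),
          H1 = rlnorm(1), H2 = rlnorm(1),
          alpha = rlnorm(1), sigma = rlnorm(1)
        ))
      }
      c(init, list(
        .RNG.name = "base::Mersenne-Twister",
        .RNG.seed = (as.integer(seed) * 1009L + k) %% .Machine$integer.max
      ))
    })
  })
  inits <- rng
  model <- rjags::jags.model(textConnection(code),
    data = jd, inits = inits,
    n.chains = control$chains, n.adapt = control$warmup, quiet = TRUE
  )
  samples <- rjags::coda.samples(model, pars,
    n.iter = control$iterations - control$warmup, progress.bar = "none"
  )
  draws <- purrr::imap_dfr(samples, function(ch, k) {
    out <- as_tibble(as.matrix(ch))
    dplyr::mutate(out, .chain = as.integer(k), .iteration = dplyr::row_number(), .before = 1)
  })
  draws <- dplyr::mutate(draws, .draw = dplyr::row_number(), .after = ".iteration")
  fit <- structure(
    list(
      draws = draws[c(".chain", ".iteration", ".draw", pars)],
      setting = setting, prior = prior, control = control,
      data = data, data_hash = dr_hash(data), diagnostics = NULL
    ),
    class = "dr_fit"
  )
  fit$diagnostics <- diagnostics_report(fit)
  if (!fit$diagnostics$converged) {
    warn(paste0(
      "MCMC convergence not established (", fit$diagnostics$note,
      "); inspect diagnostics_report()."
    ))
  }
  fit
}

#' @export
print.dr_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<dr_fit: %s model, %d draws (%d chains), %s>\n",
    x$setting, nrow(x$draws), x$control$chains,
    if (isTRUE(d$converged)) "converged" else paste0("NOT converged: ", d$note)
  ))
  print(tidy(x))
  invisible(x)
}

# split-R-hat: each chain halved, then the usual between/within variance ratio
split_rhat <- function(x, chain) {
  parts <- unlist(lapply(split(x, chain), function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(parts)
  n <- length(parts[[1]])
  if (m < 2 || n < 2) {
    return(NA_real_)
  }
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) {
    return(1)
  }
  sqrt((n - 1) / n + B / (n * W))
}

#' Convergence diagnostics for a fitted model
#'
#' Per-parameter split-R-hat (each chain halved before computing the
#' between/within variance ratio) and effective sample size
#' (\code{coda::effectiveSize}). The fit is flagged `converged` when every
#' parameter has split-R-hat below 1.05 and effective sample size of at
#' least 100 — conventional screening thresholds, reported rather than
#' enforced. With a single chain split-R-hat is still defined (two half
#' chains), but a `note` records the reduced sensitivity; the Gibbs backend
#' has no divergent-transition concept, so `divergences` is always 0.
#'
#' @param fit A `dr_fit` object (draws may have been modified, e.g. thinned;
#'   diagnostics are recomputed from `fit$draws`).
#' @return A list with `parameters` (tibble: `term`, `rhat`, `ess`),
#'   `divergences`, `converged` and `note`.
#' @export
diagnostics_report <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"), nrow(fit$draws) > 0)
  pars <- setdiff(names(fit$draws), c(".chain", ".iteration", ".draw"))
  chains <- split(fit$draws[pars], fit$draws$.chain)
  mcl <- coda::as.mcmc.list(lapply(chains, function(d) coda::mcmc(as.matrix(d))))
  ess <- coda::effectiveSize(mcl)
  tab <- tibble(
    term = pars,
    rhat = vapply(pars, function(p) split_rhat(fit$draws[[p]], fit$draws$.chain), 0),
    ess = as.numeric(ess[pars])
  )
  single <- length(chains) < 2
  ok <- all(!is.na(tab$rhat)) && all(tab$rhat < 1.05) && all(tab$ess >= 100)
  note <- if (single) {
    "single chain: between-chain R-hat unavailable, split halves only"
  } else if (!ok) {
    bad <- tab$term[is.na(tab$rhat) | tab$rhat >= 1.05 | tab$ess < 100]
    paste0("R-hat >= 1.05 or ESS < 100 for: ", paste(bad, collapse = ", "))
  } else {
    "ok"
  }
  list(
    parameters = tab, divergences = 0L,
    converged = ok && !single, note = note
  )
}

#' Posterior parameter summaries
#'
#' `tidy()` returns per-parameter posterior medians and central 95% credible
#' intervals. IC50 parameters are summarised on the log scale and
#' exponentiated (quantiles are equivariant under monotone maps, so this
#' equals the raw-scale quantiles while making the log-scale summary
#' explicit). `glance()` returns one-row fit-level information including the
#' worst split-R-hat and smallest effective sample size.
#'
#' @param x,object A `dr_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dr_fit
#' @export
tidy.dr_fit <- function(x, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration", ".draw"))
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    log_scale <- p %in% c("C", "C1", "C2")
    if (log_scale) v <- log(v)
    q <- quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    if (log_scale) q <- exp(q)
    tibble(term = p, estimate = q[1], conf.low = q[2], conf.high = q[3])
  })
}

#' @rdname tidy.dr_fit
#' @method glance dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  d <- x$diagnostics$parameters
  tibble(
    setting = x$setting, n_obs = nrow(x$data), n_draws = nrow(x$draws),
    n_chains = x$control$chains, max_rhat = max(d$rhat), min_ess = min(d$ess),
    converged = x$diagnostics$converged
  )
}

#' Serialise posterior draws
#'
#' Writes the draws as a columnar CSV (`.chain`, `.iteration`, `.draw`, one
#' column per parameter) plus a JSON diagnostics sidecar
#' (`<path>.diagnostics.json`).
#'
#' @param fit A `dr_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  side <- list(
    setting = fit$setting,
    data_hash = fit$data_hash,
    control = unclass(fit$control),
    prior = unclass(fit$prior),
    diagnostics = list(
      parameters = fit$diagnostics$parameters,
      divergences = fit$diagnostics$divergences,
      converged = fit$diagnostics$converged,
      note = fit$diagnostics$note
    )
  )
  jsonlite::write_json(side, paste0(path, ".diagnostics.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
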