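test_that("prior draws have the configured moments and load law", {
  set.seed(61)
  prior <- prior_config(m_max = 4, lambda_ref_ex = 5000,
                        lambda_ref_fret = 200, lambda_ref_sys = 10,
                        alpha = 2, alpha_ex = 100, gamma = 2)
  draws <- replicate(4000, sample_prior(prior), simplify = FALSE)
  ex <- vapply(draws, `[[`, numeric(1), "lambda_ex")
  expect_lt(abs(mean(ex) - 5000), 3 * 5000 / sqrt(100) / sqrt(4000))
  fr <- unlist(lapply(draws, `[[`, "lambda_fret"))
  expect_lt(abs(mean(fr) - 200), 3 * 200 / sqrt(2) / sqrt(length(fr)))
  sys <- unlist(lapply(draws, function(d) d$lambda_sys[d$lambda_sys > 0]))
  expect_lt(abs(mean(sys) - 10), 3 * 10 / sqrt(2) / sqrt(length(sys)))
  # no draw is ever empty
  expect_true(all(vapply(draws, function(d) sum(d$loads), integer(1)) >= 1))
  # stated load prior probability identities
  expect_equal(prior_config(5, 1e4, gamma = 4)$load_prob, 0.5)
  expect_gt(prior_config(5, 1e4, gamma = 5)$load_prob, 0.5)
})

test_that("MH rate updates target a known conjugate posterior", {
  set.seed(62)
  # one bright state, near-instant relaxation, lossless detection:
  # detected photons are Poisson(lambda_ex) and the Gamma prior is
  # conjugate, so the chain must match Gamma(alpha + K, alpha/ref + T)
  ld <- 1e12
  phys <- photophysics_config(lambda_ex = 2000, lambda_d = ld)
  kin <- system_kinetics(matrix(0, 1, 1), lambda_fret = 0)
  det <- detection_model(c(0, 1), c(1, 0))
  Tobs <- 0.1
  tr <- simulate_trace(phys, kin, det, duration = Tobs)
  K <- nrow(tr)
  alpha <- 2; lref <- 1500
  prior <- prior_config(m_max = 1, lambda_ref_ex = lref, alpha_ex = alpha,
                        gamma = 1)
  state <- list(loads = 1L, lambda_ex = 1800, lambda_fret = 1,
                lambda_sys = matrix(0, 1, 1))
  fixed <- fixed_phys_rates(lambda_d = ld)
  ll <- NULL
  draws <- numeric(2500)
  for (it in seq_along(draws)) {
    st <- mh_update_rate(state, "excitation", trace = tr, det = det,
                         prior = prior, sigma2 = 0.01, fixed = fixed,
                         cur_loglik = ll)
    state <- st$state; ll <- st$loglik
    draws[it] <- state$lambda_ex
  }
  draws <- draws[-(1:500)]
  shape <- alpha + K; rate <- alpha / lref + Tobs
  n_eff <- length(draws) / 20    # conservative autocorrelation allowance
  expect_lt(abs(mean(draws) - shape / rate),
            4 * sqrt(shape) / rate / sqrt(n_eff))
  expect_lt(abs(stats::sd(draws) / (sqrt(shape) / rate) - 1), 0.2)
  qs <- stats::quantile(draws, c(0.1, 0.5, 0.9), names = FALSE)
  expect_equal(qs, stats::qgamma(c(0.1, 0.5, 0.9), shape, rate),
               tolerance = 0.03)
})

test_that("with a flat likelihood the sampler reproduces its priors", {
  set.seed(63)
  # empty trace, zero detection flux: the likelihood is constant
  tr0 <- photon_trace(numeric(0), integer(0), 0, 1)
  det0 <- detection_model(c(0, 0), c(0, 0), c(0, 0))
  prior <- prior_config(m_max = 3, lambda_ref_ex = 100,
                        lambda_ref_fret = 50, lambda_ref_sys = 10,
                        alpha = 1.5, alpha_ex = 4, gamma = 2)
  wide <- c(excitation = 0.5, fret = 0.5, system = 0.5)
  cfg <- sampler_config(n_sweeps = 3000, burn_in = 0, var_a = wide,
                        var_b = wide, seed = 64)
  ch <- run_sampler(tr0, det0, prior, cfg,
                    fixed = fixed_phys_rates(lambda_d = 100))
  n_eff <- nrow(ch) / 20
  expect_lt(abs(mean(ch$lambda_ex) - 100), 4 * (100 / 2) / sqrt(n_eff))
  fr <- unlist(lapply(1:3, function(i) {
    ch[[paste0("lambda_fret_", i)]][ch[[paste0("b_", i)]] == 1]
  }))
  expect_lt(abs(mean(fr) - 50), 4 * (50 / sqrt(1.5)) / sqrt(n_eff))
  # state counts follow the >=1-truncated binomial load prior
  p <- prior$load_prob
  pk <- stats::dbinom(1:3, 3, p); pk <- pk / sum(pk)
  obs <- as.numeric(table(factor(ch$n_states, 1:3))) / nrow(ch)
  expect_lt(max(abs(obs - pk)), 0.06)
  # chain invariants: no empty model, no nonpositive stored rates
  expect_true(all(ch$n_states >= 1))
  expect_true(all(ch$lambda_ex > 0))
})

test_that("load updates use the prior-weighted likelihood ratio", {
  set.seed(65)
  mod <- toy_two_state()
  det <- calibration_preset("eg36")
  tr <- simulate_trace(mod$phys, mod$kin, det, photons = 80)
  prior <- prior_config(m_max = 2, lambda_ref_ex = 1e4, gamma = 1)
  state <- list(loads = c(1L, 1L), lambda_ex = 1e4,
                lambda_fret = mod$kin$lambda_fret,
                lambda_sys = mod$kin$lambda_sys)
  # the only active load can never be deactivated
  state1 <- state; state1$loads <- c(1L, 0L)
  res <- update_load(state1, 1L, tr, det, prior)
  expect_identical(res$state$loads, c(1L, 0L))
  expect_false(res$flipped)
  # a full update returns a valid configuration with consistent loglik
  res2 <- update_load(state, 2L, tr, det, prior)
  expect_gte(sum(res2$state$loads), 1L)
  ll_direct <- fretjump:::state_loglik(res2$state, tr, det,
                                       fixed_phys_rates())
  expect_equal(res2$loglik, ll_direct, tolerance = 1e-9)
})

test_that("joint draws pass a successive-conditional (Geweke) check", {
  set.seed(66)
  # marginal draws: theta ~ prior; successive-conditional: resimulate the
  # trace from theta, then one MCMC sweep. Both must leave the prior
  # marginal over theta invariant.
  ld <- 2e4
  fixed <- fixed_phys_rates(lambda_d = ld)
  prior <- prior_config(m_max = 2, lambda_ref_ex = 2000,
                        lambda_ref_fret = ld, lambda_ref_sys = 10,
                        alpha = 1, alpha_ex = 100, gamma = 1)
  det <- calibration_preset("eg36")
  Tobs <- 0.1
  sim_from <- function(state) {
    phys <- photophysics_config(state$lambda_ex, lambda_d = ld)
    kin <- system_kinetics(state$lambda_sys, state$lambda_fret,
                           state$loads)
    simulate_trace(phys, kin, det, duration = Tobs)
  }
  # wide proposals so the successive-conditional chain mixes enough for
  # batch-means error estimates to be meaningful
  wide <- c(excitation = 0.3, fret = 0.5, system = 0.5)
  cfg1 <- sampler_config(n_sweeps = 1, burn_in = 0, var_a = wide,
                         var_b = wide)
  n_cycle <- 400
  g_sc <- matrix(NA_real_, n_cycle, 3)
  state <- sample_prior(prior)
  for (cyc in seq_len(n_cycle)) {
    tr <- sim_from(state)
    ch <- run_sampler(tr, det, prior, cfg1, fixed = fixed, init = state)
    state <- attr(ch, "final_state")
    g_sc[cyc, ] <- c(sum(state$loads), log(state$lambda_ex),
                     log(state$lambda_sys[1, 2]))
  }
  g_pr <- t(replicate(3000, {
    st <- sample_prior(prior)
    c(sum(st$loads), log(st$lambda_ex), log(st$lambda_sys[1, 2]))
  }))
  # batch-means standard errors for the autocorrelated chain
  bm_se <- function(x, b = 20) {
    m <- matrix(x[seq_len(b * (length(x) %/% b))], nrow = b)
    stats::sd(colMeans(m)) / sqrt(ncol(m))
  }
  for (k in 1:3) {
    se <- sqrt(bm_se(g_sc[, k])^2 + stats::var(g_pr[, k]) / nrow(g_pr))
    z <- (mean(g_sc[, k]) - mean(g_pr[, k])) / se
    expect_lt(abs(z), 4)
  }
})

test_that("chains expose tidy, glance and plotting interfaces", {
  set.seed(67)
  mod <- toy_two_state()
  det <- calibration_preset("eg36")
  tr <- simulate_trace(mod$phys, mod$kin, det, photons = 150)
  prior <- prior_config(m_max = 2, lambda_ref_ex = 1e4, gamma = 1)
  ch <- run_sampler(tr, det, prior,
                    sampler_config(n_sweeps = 30, burn_in = 5, seed = 68))
  expect_s3_class(ch, "fret_chain")
  expect_identical(nrow(ch), 30L)
  td <- tidy(ch)
  expect_true(all(c("sweep", "parameter", "value") %in% names(td)))
  gl <- glance(ch)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$map_states >= 1)
  expect_s3_class(autoplot(ch), "ggplot")
  expect_s3_class(plot_state_count(ch), "ggplot")
})
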