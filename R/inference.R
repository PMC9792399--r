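#' Prior configuration for rates and loads
#'
#' All transition rates carry independent Gamma priors parameterized by a
#' shared shape `alpha` and a per-class prior mean `lambda_ref`
#' (shape `alpha`, scale `lambda_ref / alpha`), one reference value per
#' parameter class: excitation, FRET transfer, and system transitions.
#' Candidate-state loads carry Bernoulli priors with success probability
#' `1 / (1 + (m_max - 1) / gamma)`, so `gamma` is the expected number of
#' active system states a priori.
#'
#' @param m_max Maximum number of candidate system states.
#' @param lambda_ref_ex Prior mean of the excitation rate (1/s); use the
#'   calibrated instrument value.
#' @param lambda_ref_fret Prior mean of the FRET transfer rates (1/s);
#'   default `1 / 3.5e-9` (prior FRET efficiency centered near 0.5 for a
#'   3.5 ns donor).
#' @param lambda_ref_sys Prior mean of system transition rates (1/s),
#'   default 10.
#' @param alpha Gamma shape for FRET and system rates, default 1.
#' @param alpha_ex Gamma shape for the excitation rate; default 100,
#'   a tight prior around the precalibrated excitation rate.
#' @param gamma Expected number of system states, in `[1, m_max]`;
#'   default 2.
#'
#' @return List of class `"prior_config"`.
#' @export
prior_config <- function(m_max,
                         lambda_ref_ex,
                         lambda_ref_fret = 1 / 3.5e-9,
                         lambda_ref_sys = 10,
                         alpha = 1,
                         alpha_ex = 100,
                         gamma = 2) {
  stopifnot(m_max >= 1, alpha > 0, alpha_ex > 0,
            lambda_ref_ex > 0, lambda_ref_fret > 0, lambda_ref_sys > 0,
            gamma >= 1, gamma <= m_max)
  structure(
    list(m_max = as.integer(m_max),
         lambda_ref = c(excitation = lambda_ref_ex, fret = lambda_ref_fret,
                        system = lambda_ref_sys),
         alpha = c(excitation = alpha_ex, fret = alpha, system = alpha),
         gamma = gamma,
         load_prob = 1 / (1 + (m_max - 1) / gamma)),
    class = "prior_config"
  )
}

#' Sampler configuration
#'
#' The Metropolis proposals are normal random walks in log space whose
#' variances alternate every sweep between two fixed sets (one narrow,
#' one wide) so the chain explores rates across orders of magnitude:
#' set A `{sigma2_ex = 1e-5, sigma2_fret = 0.01, sigma2_sys = 0.1}` on
#' even sweeps and set B `{1e-5, 0.5, 5.0}` on odd sweeps.
#'
#' @param n_sweeps Total sweeps to run.
#' @param burn_in Sweeps discarded by the summary stage (stored anyway).
#' @param var_a,var_b Named proposal-variance sets (log-space, unitless),
#'   names `excitation`, `fret`, `system`.
#' @param kappa Rate unit making the log argument dimensionless; 1 s^-1.
#' @param fixed_loads If `TRUE`, loads stay at their initial values and
#'   only rates are sampled (the parametric sampler).
#' @param seed Optional integer seed applied at the start of the run.
#' @param verbose Print progress every 100 sweeps.
#'
#' @return List of class `"sampler_config"`.
#' @export
sampler_config <- function(n_sweeps = 1000, burn_in = 200,
                           var_a = c(excitation = 1e-5, fret = 0.01,
                                     system = 0.1),
                           var_b = c(excitation = 1e-5, fret = 0.5,
                                     system = 5.0),
                           kappa = 1,
                           fixed_loads = FALSE,
                           seed = NULL,
                           verbose = FALSE) {
  stopifnot(n_sweeps > burn_in, burn_in >= 0,
            all(var_a > 0), all(var_b > 0), kappa > 0)
  cls <- c("excitation", "fret", "system")
  stopifnot(all(cls %in% names(var_a)), all(cls %in% names(var_b)))
  structure(
    list(n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
         var_a = var_a[cls], var_b = var_b[cls], kappa = kappa,
         fixed_loads = isTRUE(fixed_loads), seed = seed,
         verbose = isTRUE(verbose)),
    class = "sampler_config"
  )
}

#' Draw an initial model state from the priors
#'
#' Rates are Gamma draws per class (prior mean `lambda_ref`); loads are
#' Bernoulli draws, redrawn until at least one is active.
#'
#' @param prior A [prior_config()].
#' @return A model state: list with `loads`, `lambda_ex`, `lambda_fret`
#'   (length `m_max`), `lambda_sys` (`m_max` x `m_max`, zero diagonal).
#' @export
sample_prior <- function(prior) {
  m <- prior$m_max
  repeat {
    loads <- stats::rbinom(m, 1L, prior$load_prob)
    if (sum(loads) >= 1L) break
  }
  a <- prior$alpha; lr <- prior$lambda_ref
  lambda_sys <- matrix(
    stats::rgamma(m * m, shape = a["system"],
                  scale = lr["system"] / a["system"]), m, m)
  diag(lambda_sys) <- 0
  list(
    loads = as.integer(loads),
    lambda_ex = stats::rgamma(1, shape = a["excitation"],
                              scale = lr["excitation"] / a["excitation"]),
    lambda_fret = stats::rgamma(m, shape = a["fret"],
                                scale = lr["fret"] / a["fret"]),
    lambda_sys = lambda_sys
  )
}

#' Fixed (non-sampled) photophysical rates of a run
#'
#' The sampler treats donor/acceptor relaxation, direct excitation and
#' back transfer as precalibrated constants; only excitation, FRET and
#' system rates are sampled.
#'
#' @param lambda_d,lambda_a Relaxation rates (1/s); default 1/3.5 ns.
#' @param lambda_direct,lambda_back Direct excitation and back-transfer
#'   rates (1/s), default 0.
#' @return Named list consumed by [run_sampler()].
#' @export
fixed_phys_rates <- function(lambda_d = 1 / 3.5e-9, lambda_a = lambda_d,
                             lambda_direct = 0, lambda_back = 0) {
  list(lambda_d = lambda_d, lambda_a = lambda_a,
       lambda_direct = lambda_direct, lambda_back = lambda_back)
}

state_generator <- function(state, fixed) {
  phys <- photophysics_config(
    lambda_ex = state$lambda_ex, lambda_d = fixed$lambda_d,
    lambda_a = fixed$lambda_a, lambda_direct = fixed$lambda_direct,
    lambda_back = fixed$lambda_back)
  kin <- system_kinetics(state$lambda_sys, state$lambda_fret, state$loads)
  build_generator(phys, kin)
}

state_loglik <- function(state, trace, det, fixed) {
  log_likelihood(trace, state_generator(state, fixed), det)
}

# log Gamma prior density for one rate of a given class
lprior_rate <- function(x, class, prior) {
  stats::dgamma(x, shape = prior$alpha[class],
                scale = prior$lambda_ref[class] / prior$alpha[class],
                log = TRUE)
}

get_rate <- function(state, class, i = NULL, j = NULL) {
  switch(class,
    excitation = state$lambda_ex,
    fret = state$lambda_fret[i],
    system = state$lambda_sys[i, j])
}

set_rate <- function(state, class, value, i = NULL, j = NULL) {
  switch(class,
    excitation = state$lambda_ex <- value,
    fret = state$lambda_fret[i] <- value,
    system = state$lambda_sys[i, j] <- value)
  state
}

#' One Metropolis-Hastings update of a single transition rate
#'
#' Proposes `log(lambda* / kappa) ~ Normal(log(lambda / kappa), sigma2)`
#' and accepts with probability
#' `min(1, [L* p(lambda*) lambda*] / [L p(lambda) lambda])` — the ratio of
#' conditional posteriors times the log-normal proposal Jacobian
#' `lambda* / lambda`. A non-finite acceptance ratio rejects the proposal.
#'
#' @param state Model state (see [sample_prior()]).
#' @param class `"excitation"`, `"fret"`, or `"system"`.
#' @param i,j State indices addressing FRET (`i`) or system (`i -> j`)
#'   rates; ignored for the excitation class.
#' @param trace A [photon_trace()].
#' @param det A [detection_model()].
#' @param prior A [prior_config()].
#' @param sigma2 Log-space proposal variance.
#' @param fixed Fixed photophysical rates (`lambda_d`, `lambda_a`, ...).
#' @param cur_loglik Cached log-likelihood of `state` (recomputed if
#'   `NULL`).
#' @param kappa Rate unit in the log transform (default 1).
#'
#' @return List `state`, `loglik`, `accepted`, `warned` (non-finite
#'   ratio encountered).
#' @export
mh_update_rate <- function(state, class, i = NULL, j = NULL,
                           trace, det, prior, sigma2,
                           fixed = fixed_phys_rates(),
                           cur_loglik = NULL, kappa = 1) {
  stopifnot(sigma2 > 0)
  if (is.null(cur_loglik)) {
    cur_loglik <- state_loglik(state, trace, det, fixed)
  }
  cur <- get_rate(state, class, i, j)
  prop <- kappa * exp(stats::rnorm(1, log(cur / kappa), sqrt(sigma2)))
  cand <- set_rate(state, class, prop, i, j)
  new_loglik <- tryCatch(state_loglik(cand, trace, det, fixed),
                         error = function(e) -Inf)
  log_acc <- (new_loglik - cur_loglik) +
    (lprior_rate(prop, class, prior) - lprior_rate(cur, class, prior)) +
    (log(prop) - log(cur))
  if (!is.finite(log_acc) && !identical(log_acc, -Inf)) {
    return(list(state = state, loglik = cur_loglik, accepted = FALSE,
                warned = TRUE))
  }
  if (log(stats::runif(1)) < log_acc) {
    list(state = cand, loglik = new_loglik, accepted = TRUE, warned = FALSE)
  } else {
    list(state = state, loglik = cur_loglik, accepted = FALSE, warned = FALSE)
  }
}

#' Gibbs update of one Bernoulli load
#'
#' Draws load `i` from its conditional posterior
#' `Bernoulli(q_i)`, `q_i = p L(b_i = 1) / (p L(b_i = 1) + (1 - p) L(b_i = 0))`
#' with prior success probability `p` from the prior configuration. The
#' steady state is recomputed inside each likelihood for its own load
#' configuration. Deactivations that would empty the model are skipped.
#'
#' @inheritParams mh_update_rate
#' @param i Candidate-state index to update.
#'
#' @return List `state`, `loglik` (of the returned configuration),
#'   `flipped`.
#' @export
update_load <- function(state, i, trace, det, prior,
                        fixed = fixed_phys_rates(), cur_loglik = NULL) {
  if (state$loads[i] == 1L && sum(state$loads) == 1L) {
    if (is.null(cur_loglik)) {
      cur_loglik <- state_loglik(state, trace, det, fixed)
    }
    return(list(state = state, loglik = cur_loglik, flipped = FALSE))
  }
  if (is.null(cur_loglik)) {
    cur_loglik <- state_loglik(state, trace, det, fixed)
  }
  flipped <- state
  flipped$loads[i] <- 1L - state$loads[i]
  flip_loglik <- state_loglik(flipped, trace, det, fixed)
  if (state$loads[i] == 1L) {
    l1 <- cur_loglik; l0 <- flip_loglik
  } else {
    l1 <- flip_loglik; l0 <- cur_loglik
  }
  q <- load_prob_from_loglik(l1, l0, prior$load_prob)
  new_on <- stats::runif(1) < q
  if (new_on == (state$loads[i] == 1L)) {
    list(state = state, loglik = cur_loglik, flipped = FALSE)
  } else {
    list(state = flipped, loglik = flip_loglik, flipped = TRUE)
  }
}

# refresh parameters of inactive candidate states from the prior
# (required for a correct trans-dimensional activation move)
refresh_inactive <- function(state, prior) {
  m <- prior$m_max
  inactive <- which(state$loads == 0L)
  if (!length(inactive)) return(state)
  a <- prior$alpha; lr <- prior$lambda_ref
  state$lambda_fret[inactive] <- stats::rgamma(
    length(inactive), shape = a["fret"], scale = lr["fret"] / a["fret"])
  for (i in inactive) {
    state$lambda_sys[i, -i] <- stats::rgamma(
      m - 1, shape = a["system"], scale = lr["system"] / a["system"])
    others <- setdiff(seq_len(m), i)
    state$lambda_sys[others, i] <- stats::rgamma(
      m - 1, shape = a["system"], scale = lr["system"] / a["system"])
  }
  state
}

state_logpost <- function(state, loglik, prior) {
  act <- which(state$loads == 1L)
  lp <- loglik +
    lprior_rate(state$lambda_ex, "excitation", prior) +
    sum(vapply(act, function(i) lprior_rate(state$lambda_fret[i], "fret",
                                            prior), numeric(1)))
  for (i in act) for (j in setdiff(act, i)) {
    lp <- lp + lprior_rate(state$lambda_sys[i, j], "system", prior)
  }
  p <- prior$load_prob
  lp + sum(state$loads) * log(p) +
    (prior$m_max - sum(state$loads)) * log(1 - p)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Each sweep updates, in order: the excitation rate, every active
#' state's FRET rate, every ordered pair of active system rates (all via
#' [mh_update_rate()], alternating the two proposal-variance sets every
#' sweep), then — unless `config$fixed_loads` — refreshes inactive
#' states' parameters from the prior and Gibbs-updates every load via
#' [update_load()]. One record per sweep is stored.
#'
#' @param trace A [photon_trace()].
#' @param det A [detection_model()].
#' @param prior A [prior_config()].
#' @param config A [sampler_config()].
#' @param fixed Fixed photophysical rates, see [fixed_phys_rates()].
#' @param init Optional initial model state (default: drawn from the
#'   prior).
#'
#' @return A `"fret_chain"`: tibble with one row per sweep (columns
#'   `sweep`, `n_states`, `loglik`, `logpost`, `lambda_ex`, `b_*`,
#'   `lambda_fret_*`, `lambda_sys_i_j`) carrying the run configuration,
#'   acceptance counters and final state as attributes.
#' @export
run_sampler <- function(trace, det, prior, config = sampler_config(),
                        fixed = fixed_phys_rates(), init = NULL) {
  det <- validate_detection(det)
  validate_trace(trace)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- if (is.null(init)) sample_prior(prior) else init
  m <- prior$m_max
  stopifnot(length(state$loads) == m)
  loglik <- state_loglik(state, trace, det, fixed)

  n <- config$n_sweeps
  acc <- c(excitation = 0, fret = 0, system = 0)
  tries <- c(excitation = 0, fret = 0, system = 0)
  warned <- 0L

  rec_ex <- numeric(n); rec_ll <- numeric(n); rec_lp <- numeric(n)
  rec_loads <- matrix(0L, n, m)
  rec_fret <- matrix(0, n, m)
  rec_sys <- matrix(0, n, m * m)

  for (sweep in seq_len(n)) {
    vars <- if (sweep %% 2L == 0L) config$var_a else config$var_b
    act <- which(state$loads == 1L)

    step <- mh_update_rate(state, "excitation", trace = trace, det = det,
                           prior = prior, sigma2 = vars[["excitation"]],
                           fixed = fixed, cur_loglik = loglik,
                           kappa = config$kappa)
    state <- step$state; loglik <- step$loglik
    acc["excitation"] <- acc["excitation"] + step$accepted
    tries["excitation"] <- tries["excitation"] + 1
    warned <- warned + step$warned

    for (i in act) {
      step <- mh_update_rate(state, "fret", i = i, trace = trace, det = det,
                             prior = prior, sigma2 = vars[["fret"]],
                             fixed = fixed, cur_loglik = loglik,
                             kappa = config$kappa)
      state <- step$state; loglik <- step$loglik
      acc["fret"] <- acc["fret"] + step$accepted
      tries["fret"] <- tries["fret"] + 1
      warned <- warned + step$warned
    }

    for (i in act) for (j in setdiff(act, i)) {
      step <- mh_update_rate(state, "system", i = i, j = j, trace = trace,
                             det = det, prior = prior,
                             sigma2 = vars[["system"]],
                             fixed = fixed, cur_loglik = loglik,
                             kappa = config$kappa)
      state <- step$state; loglik <- step$loglik
      acc["system"] <- acc["system"] + step$accepted
      tries["system"] <- tries["system"] + 1
      warned <- warned + step$warned
    }

    if (!config$fixed_loads) {
      state <- refresh_inactive(state, prior)
      for (i in seq_len(m)) {
        step <- update_load(state, i, trace = trace, det = det,
                            prior = prior, fixed = fixed,
                            cur_loglik = loglik)
        state <- step$state; loglik <- step$loglik
      }
    }

    rec_ex[sweep] <- state$lambda_ex
    rec_ll[sweep] <- loglik
    rec_lp[sweep] <- state_logpost(state, loglik, prior)
    rec_loads[sweep, ] <- state$loads
    rec_fret[sweep, ] <- state$lambda_fret
    rec_sys[sweep, ] <- as.vector(state$lambda_sys)

    if (config$verbose && sweep %% 100L == 0L) {
      message(sprintf(
        "sweep %d/%d | states %d | logL %.1f | acc ex/fret/sys %.2f/%.2f/%.2f",
        sweep, n, sum(state$loads), loglik,
        acc["excitation"] / max(tries["excitation"], 1),
        acc["fret"] / max(tries["fret"], 1),
        acc["system"] / max(tries["system"], 1)))
    }
  }

  chain <- tibble::tibble(
    sweep = seq_len(n),
    n_states = as.integer(rowSums(rec_loads)),
    loglik = rec_ll,
    logpost = rec_lp,
    lambda_ex = rec_ex
  )
  colnames(rec_loads) <- paste0("b_", seq_len(m))
  colnames(rec_fret) <- paste0("lambda_fret_", seq_len(m))
  sys_names <- outer(seq_len(m), seq_len(m),
                     function(i, j) paste0("lambda_sys_", i, "_", j))
  colnames(rec_sys) <- as.vector(sys_names)
  keep_sys <- as.vector(outer(seq_len(m), seq_len(m), `!=`))
  chain <- dplyr::bind_cols(
    chain,
    tibble::as_tibble(rec_loads),
    tibble::as_tibble(rec_fret),
    tibble::as_tibble(rec_sys[, keep_sys, drop = FALSE])
  )
  structure(chain,
            class = c("fret_chain", class(chain)),
            prior = prior, config = config, fixed = fixed,
            acceptance = list(accepted = acc, attempted = tries,
                              nonfinite = warned),
            final_state = state)
}

#' @export
print.fret_chain <- function(x, ...) {
  accz <- attr(x, "acceptance")
  rate <- accz$accepted / pmax(accz$attempted, 1)
  cat(sprintf(
    "<fret_chain> %d sweeps, m_max %d | acceptance ex %.2f, fret %.2f, sys %.2f\n",
    nrow(x), attr(x, "prior")$m_max,
    rate["excitation"], rate["fret"], rate["system"]))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior chain into long format
#'
#' @param x A `"fret_chain"`.
#' @param ... Unused.
#' @return Tibble with columns `sweep`, `parameter`, `value`.
#' @method tidy fret_chain
#' @export
tidy.fret_chain <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = -c("sweep"),
                      names_to = "parameter", values_to = "value")
}

#' One-row summary of a sampler run
#'
#' @param x A `"fret_chain"`.
#' @param ... Unused.
#' @return Tibble with sweep counts, the MAP state count, and per-class
#'   acceptance rates.
#' @method glance fret_chain
#' @export
glance.fret_chain <- function(x, ...) {
  accz <- attr(x, "acceptance")
  rate <- accz$accepted / pmax(accz$attempted, 1)
  scp <- state_count_posterior(x)
  tibble::tibble(
    n_sweeps = nrow(x),
    burn_in = attr(x, "config")$burn_in,
    map_states = attr(scp, "map"),
    mean_loglik = mean(x$loglik),
    accept_excitation = unname(rate["excitation"]),
    accept_fret = unname(rate["fret"]),
    accept_system = unname(rate["system"])
  )
}
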