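# shared fixture builders (everything generated in code)

# moderate-rate 2-system-state model; non-stiff so both likelihood paths
# and the Gillespie dwell statistics are easy to probe
toy_two_state <- function(lambda_ex = 1e4, lambda_d = 1 / 3.5e-9,
                          esc = c(20, 10), eff = c(0.1, 0.8)) {
  m <- length(esc)
  ls <- matrix(0, m, m)
  for (i in seq_len(m)) ls[i, -i] <- esc[i] / (m - 1)
  list(
    phys = photophysics_config(lambda_ex = lambda_ex, lambda_d = lambda_d),
    kin = system_kinetics(ls, fret_rate(eff, lambda_d))
  )
}

# random valid model inputs for property-style loops
random_model <- function(m_max = 3, all_active = FALSE) {
  loads <- if (all_active) rep(1L, m_max) else {
    repeat {
      l <- stats::rbinom(m_max, 1, 0.6)
      if (sum(l) >= 1) break
    }
    l
  }
  ls <- matrix(stats::runif(m_max^2, 0.5, 30), m_max, m_max)
  diag(ls) <- 0
  list(
    phys = photophysics_config(
      lambda_ex = stats::runif(1, 1e3, 1e4),
      lambda_d = stats::runif(1, 1e7, 1e9),
      lambda_a = stats::runif(1, 1e7, 1e9)),
    kin = system_kinetics(ls, stats::runif(m_max, 1e6, 1e9), loads)
  )
}

# independent nested-loop construction of the composite generator,
# written directly from the block rules (oracle for build_generator)
oracle_generator <- function(phys, kin) {
  m <- kin$m_max
  b <- kin$loads
  n <- 3 * m
  G <- matrix(0, n, n)
  idx <- function(i, l) (i - 1) * 3 + l
  for (i in seq_len(m)) {
    rates <- matrix(0, 3, 3)
    rates[1, 2] <- phys$lambda_ex
    rates[1, 3] <- phys$lambda_direct
    rates[2, 1] <- phys$lambda_d
    rates[2, 3] <- kin$lambda_fret[i]
    rates[3, 1] <- phys$lambda_a
    rates[3, 2] <- phys$lambda_back
    for (l in 1:3) for (k in 1:3) {
      if (l != k) G[idx(i, l), idx(i, k)] <- b[i] * b[i] * rates[l, k]
    }
    for (j in seq_len(m)) {
      if (j == i) next
      for (l in 1:3) {
        G[idx(i, l), idx(j, l)] <- b[i] * b[j] * kin$lambda_sys[i, j]
      }
    }
  }
  for (r in seq_len(n)) G[r, r] <- -sum(G[r, -r])
  G
}

# active submatrix of a composite generator, attributes stripped
active_sub <- function(G) {
  a <- attr(G, "active")
  m <- unclass(G)[a, a, drop = FALSE]
  attributes(m) <- list(dim = dim(m))
  m
}

# five-state system rate matrix of posterior medians (buffer dataset)
published_five_state <- function() {
  matrix(c(
    -4.31, 3.44, 0.70, 0.15, 0.02,
    18.0, -24.97, 3.48, 0.99, 2.5,
    0.21, 3.98, -5.10, 0.91, 0.003,
    1.85, 0.013, 7.0, -8.87, 0.007,
    0.08, 6.23, 0.12, 0.71, -6.6), 5, 5, byrow = TRUE)
}

# build a minimal fret_chain-shaped tibble for summary-stage tests
fake_chain <- function(n_states_vec, m_max = max(n_states_vec),
                       lambda_fret = NULL, lambda_sys = NULL,
                       lambda_d = 100) {
  n <- length(n_states_vec)
  out <- tibble::tibble(
    sweep = seq_len(n), n_states = as.integer(n_states_vec),
    loglik = 0, logpost = 0, lambda_ex = 1e4)
  for (i in seq_len(m_max)) {
    out[[paste0("b_", i)]] <- as.integer(i <= n_states_vec)
    out[[paste0("lambda_fret_", i)]] <-
      if (is.null(lambda_fret)) lambda_d * i else lambda_fret[i]
  }
  for (i in seq_len(m_max)) for (j in seq_len(m_max)) {
    if (i == j) next
    out[[paste0("lambda_sys_", i, "_", j)]] <-
      if (is.null(lambda_sys)) 1 else lambda_sys[i, j]
  }
  structure(out, class = c("fret_chain", class(out)),
            fixed = fixed_phys_rates(lambda_d = lambda_d),
            config = sampler_config(n_sweeps = n + 1, burn_in = 0))
}
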