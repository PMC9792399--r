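#' Split the composite generator into nonradiative and detection parts
#'
#' Factorizes the dynamics between photon detections from the dynamics at
#' detections. For channel `j`, the radiative matrix `R_j` carries the
#' detected flux: `lambda_d * phi_d[j]` on each within-block donor
#' relaxation (psi2 -> psi1) and `lambda_a * phi_a[j]` on each acceptor
#' relaxation (psi3 -> psi1). The detection matrix is
#' `D_j = R_j + bg[j] * I` (molecular detection superposed with channel
#' background), and the nonradiative generator is
#' `H = G_active - R_1 - R_2 - (bg[1] + bg[2]) * I`: undetected relaxations
#' stay in `H`, and its diagonal keeps the full escape rate plus the total
#' background deficit.
#'
#' @param G A `"fret_generator"` from [build_generator()].
#' @param det A validated [detection_model()].
#'
#' @return List of class `"propagator_set"` with `H`, `D` (list of the two
#'   channel matrices), `active` (global superstate indices) and `psi`.
#' @export
decompose_generator <- function(G, det) {
  det <- validate_detection(det)
  Ga <- active_generator(G)
  act <- attr(Ga, "active")
  psi <- attr(Ga, "psi")
  n <- nrow(Ga)
  Ga <- unclass(Ga); attributes(Ga) <- list(dim = c(n, n))
  # detected fraction of each radiative relaxation, per channel
  R <- list(matrix(0, n, n), matrix(0, n, n))
  sys_id <- sys_of_phi(act)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (sys_id[a] != sys_id[b]) next
      if (psi[a] == 2L && psi[b] == 1L) {
        R[[1]][a, b] <- Ga[a, b] * det$phi_d[1]
        R[[2]][a, b] <- Ga[a, b] * det$phi_d[2]
      } else if (psi[a] == 3L && psi[b] == 1L) {
        R[[1]][a, b] <- Ga[a, b] * det$phi_a[1]
        R[[2]][a, b] <- Ga[a, b] * det$phi_a[2]
      }
    }
  }
  H <- Ga - R[[1]] - R[[2]] - sum(det$bg) * diag(n)
  D <- list(R[[1]] + det$bg[1] * diag(n),
            R[[2]] + det$bg[2] * diag(n))
  structure(list(H = H, D = D, active = act, psi = psi),
            class = "propagator_set")
}

# Eigendecomposition of H with conditioning/reconstruction guard.
# Returns NULL when the eigenvector basis is unfit (caller falls back to
# scaling-and-squaring). The explicit reconstruction check against a
# scaling-and-squaring exponential only runs for suspect conditioning
# (kappa above `kappa_check`); comfortably conditioned bases are trusted.
eigen_cache <- function(H, tau_bar, kappa_max = 1e8, kappa_check = 1e4,
                        recon_tol = 1e-8) {
  e <- tryCatch(eigen(H), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  V <- e$vectors
  Vinv <- tryCatch(solve(V), error = function(err) NULL)
  if (is.null(Vinv)) return(NULL)
  kappa <- norm(as.matrix(Mod(V)), "1") * norm(as.matrix(Mod(Vinv)), "1")
  if (!is.finite(kappa) || kappa > kappa_max) return(NULL)
  if (kappa > kappa_check && is.finite(tau_bar) && tau_bar > 0) {
    E_eig <- Re(V %*% (exp(e$values * tau_bar) * Vinv))
    E_ref <- as.matrix(Matrix::expm(H * tau_bar))
    denom <- max(abs(E_ref), 1e-300)
    if (max(abs(E_eig - E_ref)) / denom > recon_tol) return(NULL)
  }
  list(values = e$values, V = V, Vinv = Vinv)
}

#' Log-likelihood from an explicit propagator set
#'
#' Lower-level evaluation of the alternating propagator product for a
#' caller-supplied nonradiative generator `H`, detection matrices `D`
#' and initial distribution `rho0` — useful for degenerate models (e.g.
#' a one-superstate pure-background process) that do not arise from a
#' composite generator. Same recursion and renormalization as
#' [log_likelihood()], on the scaling-and-squaring path.
#'
#' @param trace A [photon_trace()].
#' @param H Square nonradiative generator (1/s).
#' @param D List of per-channel detection matrices (1/s).
#' @param rho0 Initial probability row vector.
#' @return Log-likelihood.
#' @export
loglik_propagators <- function(trace, H, D, rho0) {
  validate_trace(trace)
  H <- as.matrix(H)
  win <- trace_window(trace)
  taus <- c(trace$time_s, win["t_end"]) - c(win["t_start"], trace$time_s)
  rho <- matrix(rho0, nrow = 1)
  logscale <- 0
  K <- nrow(trace)
  for (k in seq_len(K)) {
    rho <- rho %*% as.matrix(Matrix::expm(H * taus[k])) %*%
      as.matrix(D[[trace$channel[k]]])
    s <- sum(abs(rho))
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("non-finite likelihood propagation at photon %d", k),
           call. = FALSE)
    }
    rho <- rho / s
    logscale <- logscale + log(s)
  }
  rho <- rho %*% as.matrix(Matrix::expm(H * taus[K + 1]))
  val <- sum(rho)
  if (!is.finite(val)) stop("non-finite terminal likelihood value",
                            call. = FALSE)
  if (val <= 0) return(-Inf)
  logscale + log(val)
}

#' Photon-by-photon log-likelihood of a trace
#'
#' Evaluates the natural log of
#' `rho_start exp(H tau_1) D_c1 exp(H tau_2) D_c2 ... D_cK exp(H tau_end) 1`,
#' the probability density of the observed photon arrival times and
#' channels under the composite model. `rho_start` is the steady state of
#' the full active generator (the molecule equilibrated before
#' observation). Interphoton propagation uses one eigendecomposition of
#' `H` per call, with per-step renormalization so traces of millions of
#' photons do not underflow; an automatic fallback to per-interval
#' scaling-and-squaring matrix exponentials covers ill-conditioned
#' eigenvector bases.
#'
#' @param trace A [photon_trace()].
#' @param G A `"fret_generator"`.
#' @param det A [detection_model()].
#' @param method `"auto"` (eigen with fallback), `"eigen"`, or `"expm"`
#'   (force scaling-and-squaring; slow, used for cross-validation).
#'
#' @return Log-likelihood (natural log of a density; additive constants
#'   consistent across models of equal data).
#' @export
log_likelihood <- function(trace, G, det,
                           method = c("auto", "eigen", "expm")) {
  method <- match.arg(method)
  validate_trace(trace)
  ps <- decompose_generator(G, det)
  rho0 <- steady_state(G)
  win <- trace_window(trace)
  taus <- c(trace$time_s, win["t_end"]) - c(win["t_start"], trace$time_s)
  channels <- trace$channel
  K <- length(channels)

  if (method != "expm") {
    ec <- eigen_cache(ps$H, tau_bar = mean(taus))
    if (!is.null(ec)) {
      u0 <- as.vector(rho0 %*% ec$V)
      B1 <- ec$Vinv %*% ps$D[[1]] %*% ec$V
      B2 <- ec$Vinv %*% ps$D[[2]] %*% ec$V
      vinv_one <- ec$Vinv %*% rep(1, nrow(ps$H))
      return(loglik_eigen_core(
        matrix(as.complex(u0), nrow = 1), as.complex(ec$values),
        B1 + 0i, B2 + 0i,
        as.integer(channels), as.numeric(taus),
        as.complex(vinv_one)))
    }
    if (method == "eigen") {
      stop("eigenvector basis of H is too ill-conditioned for the eigen path",
           call. = FALSE)
    }
  }

  # scaling-and-squaring path: one matrix exponential per interval
  rho <- rho0
  logscale <- 0
  for (k in seq_len(K)) {
    rho <- rho %*% as.matrix(Matrix::expm(ps$H * taus[k])) %*%
      ps$D[[channels[k]]]
    s <- sum(abs(rho))
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("non-finite likelihood propagation at photon %d", k),
           call. = FALSE)
    }
    rho <- rho / s
    logscale <- logscale + log(s)
  }
  rho <- rho %*% as.matrix(Matrix::expm(ps$H * taus[K + 1]))
  val <- sum(rho)
  if (!is.finite(val)) stop("non-finite terminal likelihood value",
                            call. = FALSE)
  if (val <= 0) return(-Inf)
  logscale + log(val)
}

#' Load inclusion probability from two likelihood evaluations
#'
#' The Gibbs update for a Bernoulli load compares the trace likelihood
#' with the candidate state active versus inactive:
#' `q = p L1 / (p L1 + (1 - p) L0)` with prior success probability `p`.
#' Computed in log space; the steady state is recomputed inside each
#' likelihood for its own load configuration.
#'
#' @param trace A [photon_trace()].
#' @param G_on Generator with the candidate load active.
#' @param G_off Generator with it inactive.
#' @param det A [detection_model()].
#' @param prior_prob Bernoulli prior success probability `p` (default 0.5,
#'   reducing to the bare likelihood ratio).
#'
#' @return Probability in `[0, 1]` that the load is active.
#' @export
likelihood_ratio_for_loads <- function(trace, G_on, G_off, det,
                                       prior_prob = 0.5) {
  stopifnot(prior_prob > 0, prior_prob < 1)
  l1 <- log_likelihood(trace, G_on, det)
  l0 <- log_likelihood(trace, G_off, det)
  load_prob_from_loglik(l1, l0, prior_prob)
}

# stable q = p e^{l1} / (p e^{l1} + (1-p) e^{l0})
load_prob_from_loglik <- function(l1, l0, prior_prob) {
  if (!is.finite(l1) && !is.finite(l0)) {
    stop("both load configurations have vanishing likelihood", call. = FALSE)
  }
  if (l1 == -Inf) return(0)
  if (l0 == -Inf) return(1)
  delta <- (log(1 - prior_prob) + l0) - (log(prior_prob) + l1)
  1 / (1 + exp(delta))
}
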