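#' Photophysical rate configuration
#'
#' Collects the dye-level rates of the composite model: excitation of the
#' donor, radiative relaxation of donor and acceptor, and the (usually
#' negligible) direct acceptor excitation and acceptor-to-donor back-transfer
#' rates. All rates are in 1/s.
#'
#' @param lambda_ex Donor excitation rate (1/s), set by laser power.
#' @param lambda_d Donor relaxation rate (1/s); default `1 / 3.5e-9`,
#'   a typical 3.5 ns donor lifetime.
#' @param lambda_a Acceptor relaxation rate (1/s); defaults to `lambda_d`.
#' @param lambda_direct Direct acceptor excitation rate (1/s), default 0.
#' @param lambda_back Acceptor-to-donor back-transfer rate (1/s), default 0.
#'
#' @return A validated list of class `"photophysics_config"`.
#' @export
#' @examples
#' photophysics_config(lambda_ex = 1e4)
photophysics_config <- function(lambda_ex,
                                lambda_d = 1 / 3.5e-9,
                                lambda_a = lambda_d,
                                lambda_direct = 0,
                                lambda_back = 0) {
  rates <- c(
    lambda_ex = lambda_ex, lambda_d = lambda_d, lambda_a = lambda_a,
    lambda_direct = lambda_direct, lambda_back = lambda_back
  )
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("photophysical rates must be finite and >= 0", call. = FALSE)
  }
  if (lambda_d <= 0 || lambda_a <= 0) {
    stop("lambda_d and lambda_a must be > 0", call. = FALSE)
  }
  structure(as.list(rates), class = "photophysics_config")
}

#' System-level kinetic scheme
#'
#' Describes the candidate conformational (system) states: which of the
#' `m_max` candidates are active (binary loads), the matrix of system
#' transition rates between candidates, and the per-state FRET transfer
#' rate that sets each state's FRET efficiency.
#'
#' @param lambda_sys `m_max` x `m_max` matrix of system transition rates
#'   (1/s); the diagonal is ignored.
#' @param lambda_fret Length-`m_max` vector of donor-to-acceptor transfer
#'   rates (1/s), one per candidate state.
#' @param loads Binary vector of length `m_max`; 1 marks an active state.
#'   Defaults to all active.
#'
#' @return A validated list of class `"system_kinetics"` with elements
#'   `m_max`, `loads`, `lambda_sys`, `lambda_fret`.
#' @export
system_kinetics <- function(lambda_sys, lambda_fret, loads = NULL) {
  lambda_sys <- as.matrix(lambda_sys)
  m_max <- nrow(lambda_sys)
  if (ncol(lambda_sys) != m_max) {
    stop("lambda_sys must be square", call. = FALSE)
  }
  if (length(lambda_fret) != m_max) {
    stop("lambda_fret must have one entry per candidate state", call. = FALSE)
  }
  if (is.null(loads)) loads <- rep(1L, m_max)
  loads <- as.integer(loads)
  if (length(loads) != m_max || !all(loads %in% c(0L, 1L))) {
    stop("loads must be a binary vector of length m_max", call. = FALSE)
  }
  if (sum(loads) < 1L) {
    stop("at least one load must be active", call. = FALSE)
  }
  off <- lambda_sys; diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0) ||
      any(!is.finite(lambda_fret)) || any(lambda_fret < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  diag(lambda_sys) <- 0
  structure(
    list(m_max = m_max, loads = loads,
         lambda_sys = lambda_sys, lambda_fret = as.numeric(lambda_fret)),
    class = "system_kinetics"
  )
}

# number of photophysical states per system state:
# psi1 both dyes ground, psi2 donor excited, psi3 acceptor excited
N_PSI <- 3L

#' Superstate bookkeeping
#'
#' Superstate `phi` for system state `i` and photophysical state `l` has
#' index `(i - 1) * 3 + l`. Helpers mapping between the two conventions.
#'
#' @param i System state index.
#' @param l Photophysical state index in 1:3.
#' @name superstate-index
#' @keywords internal
phi_index <- function(i, l) (i - 1L) * N_PSI + l

psi_of_phi <- function(phi) (phi - 1L) %% N_PSI + 1L

sys_of_phi <- function(phi) (phi - 1L) %/% N_PSI + 1L

#' Build the composite system-photophysics generator
#'
#' Assembles the full `3 * m_max` square generator matrix of the composite
#' jump process. Within the block of active system state `i`, photophysical
#' transitions carry the rates of `phys` plus state `i`'s FRET rate;
#' between active blocks `i != j`, system transitions `lambda_sys[i, j]`
#' connect equal photophysical states. Rows and columns of inactive states
#' (load 0) are identically zero; diagonals are negative row sums so every
#' row sums to zero.
#'
#' @param phys A [photophysics_config()].
#' @param kin A [system_kinetics()].
#'
#' @return A matrix of class `"fret_generator"` with attributes `loads`,
#'   `active` (indices of active superstates) and `psi` (photophysical
#'   index of every superstate).
#' @export
#' @examples
#' phys <- photophysics_config(lambda_ex = 1e4)
#' kin <- system_kinetics(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE),
#'                        lambda_fret = c(0, 2.857e8))
#' G <- build_generator(phys, kin)
#' rowSums(G)  # all zero
build_generator <- function(phys, kin) {
  stopifnot(inherits(phys, "photophysics_config"),
            inherits(kin, "system_kinetics"))
  m <- kin$m_max
  b <- kin$loads
  n <- m * N_PSI
  G <- matrix(0, n, n)
  for (i in seq_len(m)) {
    if (b[i] == 0L) next
    p <- phi_index(i, 1L:3L)
    G[p[1L], p[2L]] <- phys$lambda_ex
    G[p[1L], p[3L]] <- phys$lambda_direct
    G[p[2L], p[1L]] <- phys$lambda_d
    G[p[2L], p[3L]] <- kin$lambda_fret[i]
    G[p[3L], p[1L]] <- phys$lambda_a
    G[p[3L], p[2L]] <- phys$lambda_back
    for (j in seq_len(m)) {
      if (j == i || b[j] == 0L) next
      for (l in 1L:3L) {
        G[phi_index(i, l), phi_index(j, l)] <- kin$lambda_sys[i, j]
      }
    }
  }
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  active <- which(rep(b, each = N_PSI) == 1L)
  structure(G,
            class = c("fret_generator", "matrix", "array"),
            loads = b, active = active,
            psi = psi_of_phi(seq_len(n)))
}

#' Restrict a composite generator to its active superstates
#' @param G A `"fret_generator"`.
#' @return Plain matrix over active superstates, with attributes `active`
#'   (global indices) and `psi`.
#' @keywords internal
active_generator <- function(G) {
  act <- attr(G, "active")
  if (is.null(act)) act <- seq_len(nrow(G))
  Ga <- unclass(G)[act, act, drop = FALSE]
  attr(Ga, "active") <- act
  attr(Ga, "psi") <- psi_of_phi(act)
  Ga
}

#' Steady-state distribution of a generator matrix
#'
#' Solves `rho %*% G = 0` with `sum(rho) = 1` for the stationary
#' distribution of a continuous-time Markov generator (zero row sums).
#' For a composite `"fret_generator"` the computation runs on the active
#' submatrix and the result is reported over active superstates.
#'
#' @param G A generator matrix: either a `"fret_generator"` from
#'   [build_generator()] or any square matrix with zero row sums, such as
#'   a system-level rate matrix whose diagonal holds negative escape rates.
#' @param tol Relative singular-value tolerance used to identify the null
#'   space (default 1e-9).
#'
#' @return Numeric probability vector (sums to 1). For a
#'   `"fret_generator"`, it has one entry per active superstate and carries
#'   the global indices as names.
#' @export
#' @examples
#' Gs <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
#' steady_state(Gs)  # c(2/3, 1/3)
steady_state <- function(G, tol = 1e-9) {
  if (inherits(G, "fret_generator")) {
    Ga <- active_generator(G)
    act <- attr(Ga, "active")
    rho <- steady_state_core(unclass(Ga), tol)
    names(rho) <- act
    return(rho)
  }
  steady_state_core(as.matrix(G), tol)
}

steady_state_core <- function(Ga, tol = 1e-9) {
  n <- nrow(Ga)
  if (n == 1L) return(1)
  if (max(abs(rowSums(Ga))) > 1e-8 * max(abs(Ga))) {
    stop("not a generator: rows do not sum to zero", call. = FALSE)
  }
  # constrained solve: one balance equation replaced by normalization;
  # two rounds of iterative refinement keep accuracy when rate scales
  # span many orders of magnitude
  B <- t(Ga); B[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  rho <- tryCatch(solve(B, b), error = function(e) NULL)
  if (is.null(rho)) {
    # singular system: diagnose the null-space multiplicity for the error
    sv <- svd(Ga)
    null_dim <- sum(sv$d < tol * max(sv$d))
    stop(sprintf(
      "generator has a null space of dimension %d (reducible or defective); steady state is not unique",
      max(null_dim, 2L)), call. = FALSE)
  }
  for (it in 1:2) {
    r <- b - as.vector(B %*% rho)
    dl <- tryCatch(solve(B, r), error = function(e) NULL)
    if (is.null(dl)) break
    rho <- rho + dl
  }
  rho <- rho / sum(rho)
  if (any(rho < -1e-6)) {
    stop("steady-state solve produced negative probabilities (near-reducible generator)",
         call. = FALSE)
  }
  pmax(rho, 0) / sum(pmax(rho, 0))
}

#' Coerce a rate matrix to a proper generator
#'
#' Takes a square matrix of nonnegative transition rates (the diagonal is
#' ignored) and sets each diagonal entry to the negative sum of its row's
#' off-diagonal entries. Useful for reported rate tables whose printed
#' diagonals are independent summaries (e.g. posterior medians) and so do
#' not close the rows exactly.
#'
#' @param m Square numeric matrix of rates (1/s).
#' @return Generator matrix with zero row sums.
#' @export
#' @examples
#' as_generator(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE))
as_generator <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  diag(m) <- 0
  if (any(m < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  diag(m) <- -rowSums(m)
  m
}

#' Escape rates of the active system states
#'
#' The escape rate of a system state is the sum of all system transition
#' rates out of it (to other active states); equivalently the negative
#' diagonal of the system-level generator.
#'
#' @param kin A [system_kinetics()].
#' @return Named numeric vector, one entry per active state (1/s).
#' @export
escape_rates <- function(kin) {
  stopifnot(inherits(kin, "system_kinetics"))
  act <- which(kin$loads == 1L)
  out <- vapply(act, function(i) {
    sum(kin$lambda_sys[i, setdiff(act, i)])
  }, numeric(1))
  names(out) <- act
  out
}

#' System-level generator from a kinetic scheme
#'
#' Off-diagonals are the active-to-active system rates; diagonal entries
#' are negative escape rates.
#'
#' @param kin A [system_kinetics()].
#' @return Square matrix over active system states.
#' @export
system_generator <- function(kin) {
  act <- which(kin$loads == 1L)
  Gs <- kin$lambda_sys[act, act, drop = FALSE]
  diag(Gs) <- 0
  diag(Gs) <- -rowSums(Gs)
  dimnames(Gs) <- list(act, act)
  Gs
}

#' FRET efficiency and its inverse map
#'
#' FRET efficiency is the probability that a donor excitation relaxes by
#' energy transfer rather than donor emission:
#' `eps = lambda_fret / (lambda_fret + lambda_d)`.
#'
#' @param lambda_fret Transfer rate (1/s), >= 0.
#' @param lambda_d Donor relaxation rate (1/s), > 0.
#' @return `fret_efficiency()`: efficiency in `[0, 1)`.
#' @export
#' @examples
#' fret_efficiency(2.857e8, 2.857e8)  # 0.5
#' fret_rate(0.9, 1)                  # 9
fret_efficiency <- function(lambda_fret, lambda_d) {
  stopifnot(all(lambda_d > 0), all(lambda_fret >= 0))
  lambda_fret / (lambda_fret + lambda_d)
}

#' @rdname fret_efficiency
#' @param efficiency Target efficiency in `[0, 1)`.
#' @return `fret_rate()`: the transfer rate achieving `efficiency`.
#' @export
fret_rate <- function(efficiency, lambda_d) {
  stopifnot(all(lambda_d > 0))
  if (any(efficiency < 0) || any(efficiency >= 1)) {
    stop("efficiency must lie in [0, 1); 1 needs an infinite rate",
         call. = FALSE)
  }
  lambda_d * efficiency / (1 - efficiency)
}
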