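#' Photon budget index
#'
#' Dimensionless adequacy measure for probing a rate `lambda_probe` from a
#' trace of `K` photons at excitation rate `lambda_ex` shared among
#' `m_sigma` system states: `s = K * lambda_ex / (lambda_probe * m_sigma)`.
#' Inference of the probed rate is typically reliable when `s` exceeds
#' the empirical threshold 1e6.
#'
#' @param photons Photon count `K`.
#' @param lambda_ex Excitation rate (1/s).
#' @param lambda_probe Escape rate(s) to be probed (1/s); vectorized.
#' @param m_sigma Number of system states.
#' @param threshold Adequacy threshold, default 1e6.
#'
#' @return Tibble with columns `lambda_probe`, `s`, `adequate`.
#' @export
#' @examples
#' photon_budget_index(2e6, 1e4, c(1e4, 2e4, 3e4), 3)
photon_budget_index <- function(photons, lambda_ex, lambda_probe, m_sigma,
                                threshold = 1e6) {
  stopifnot(photons > 0, lambda_ex > 0, all(lambda_probe > 0), m_sigma > 0)
  s <- photons * lambda_ex / (lambda_probe * m_sigma)
  tibble::tibble(lambda_probe = lambda_probe, s = s,
                 adequate = s >= threshold)
}

#' Posterior over the number of system states
#'
#' Histogram of the active-load count across post-burn-in sweeps, and its
#' mode (the MAP state count; ties broken toward fewer states).
#'
#' @param chain A `"fret_chain"`.
#' @param burn_in Sweeps to drop; defaults to the run configuration's
#'   value.
#'
#' @return Tibble with columns `n_states`, `prob`; the MAP count is
#'   attached as attribute `"map"`.
#' @export
state_count_posterior <- function(chain, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- attr(chain, "config")$burn_in
  if (is.null(burn_in)) burn_in <- 0L
  kept <- chain$n_states[chain$sweep > burn_in]
  if (!length(kept)) stop("no sweeps after burn-in", call. = FALSE)
  tab <- table(kept)
  hist <- tibble::tibble(
    n_states = as.integer(names(tab)),
    prob = as.numeric(tab) / length(kept)
  )
  map <- hist$n_states[hist$prob == max(hist$prob)]
  structure(hist, map = min(map))
}

# within-sweep relabeling by increasing FRET efficiency; returns a long
# tibble (sweep, label, efficiency, escape, original state index)
relabeled_states <- function(chain, lambda_d, burn_in, dimension) {
  prior <- attr(chain, "prior")
  m <- if (!is.null(prior)) prior$m_max else {
    sum(startsWith(names(chain), "b_"))
  }
  kept <- chain[chain$sweep > burn_in & chain$n_states == dimension, ,
                drop = FALSE]
  if (!nrow(kept)) {
    stop(sprintf("no post-burn-in sweeps with %d active states", dimension),
         call. = FALSE)
  }
  loads <- as.matrix(kept[paste0("b_", seq_len(m))])
  fret <- as.matrix(kept[paste0("lambda_fret_", seq_len(m))])
  rows <- lapply(seq_len(nrow(kept)), function(r) {
    act <- which(loads[r, ] == 1L)
    eff <- fret_efficiency(fret[r, act], lambda_d)
    esc <- vapply(act, function(i) {
      sum(vapply(setdiff(act, i), function(j) {
        kept[[paste0("lambda_sys_", i, "_", j)]][r]
      }, numeric(1)))
    }, numeric(1))
    ord <- order(eff)
    tibble::tibble(sweep = kept$sweep[r],
                   label = seq_along(act),
                   state = act[ord],
                   efficiency = eff[ord],
                   escape = esc[ord])
  })
  dplyr::bind_rows(rows)
}

#' Posterior summary of states, rates and populations
#'
#' Conditions on one model dimension (default: the MAP state count),
#' relabels the active states of every sweep by increasing FRET
#' efficiency to resolve label switching, and reports per-label medians
#' with 95% equal-tailed credible intervals for efficiency and escape
#' rate, the median system-rate matrix in the relabeled order, and the
#' steady-state populations of that median matrix.
#'
#' @param chain A `"fret_chain"`.
#' @param lambda_d Donor relaxation rate used in the efficiency map;
#'   defaults to the run's fixed value.
#' @param dimension Model dimension to condition on (default MAP).
#' @param burn_in Sweeps to drop; default from the run configuration.
#'
#' @return List of class `"fret_summary"`: `state_count` (tibble),
#'   `map_states`, `per_state` (tibble of medians and intervals),
#'   `median_matrix`, `steady_state`, `n_sweeps_used`.
#' @export
summarize_states <- function(chain, lambda_d = NULL, dimension = NULL,
                             burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- attr(chain, "config")$burn_in
  if (is.null(burn_in)) burn_in <- 0L
  if (is.null(lambda_d)) {
    fixed <- attr(chain, "fixed")
    lambda_d <- if (!is.null(fixed)) fixed$lambda_d else 1 / 3.5e-9
  }
  hist <- state_count_posterior(chain, burn_in)
  if (is.null(dimension)) dimension <- attr(hist, "map")

  long <- relabeled_states(chain, lambda_d, burn_in, dimension)
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  # summary columns reusing input names come last in each group so the
  # quantile expressions all see the raw per-sweep values
  per_state <- dplyr::summarise(
    dplyr::group_by(long, .data$label),
    efficiency_lo = qs(.data$efficiency)[1],
    efficiency_hi = qs(.data$efficiency)[3],
    efficiency = qs(.data$efficiency)[2],
    escape_lo = qs(.data$escape)[1],
    escape_hi = qs(.data$escape)[3],
    escape = qs(.data$escape)[2],
    .groups = "drop"
  )
  per_state <- dplyr::select(
    per_state, "label", "efficiency_lo", "efficiency", "efficiency_hi",
    "escape_lo", "escape", "escape_hi")

  # median system-rate matrix in the relabeled order
  kept <- chain[chain$sweep > burn_in & chain$n_states == dimension, ,
                drop = FALSE]
  wide <- tidyr::pivot_wider(long[c("sweep", "label", "state")],
                             names_from = "label", values_from = "state")
  med <- matrix(0, dimension, dimension)
  for (k in seq_len(dimension)) for (l in seq_len(dimension)) {
    if (k == l) next
    vals <- vapply(seq_len(nrow(wide)), function(r) {
      i <- wide[[as.character(k)]][r]
      j <- wide[[as.character(l)]][r]
      kept[[paste0("lambda_sys_", i, "_", j)]][kept$sweep == wide$sweep[r]]
    }, numeric(1))
    med[k, l] <- stats::median(vals)
  }
  diag(med) <- -rowSums(med)
  rho <- steady_state(med)

  structure(
    list(state_count = tibble::as_tibble(hist),
         map_states = attr(hist, "map"),
         dimension = dimension,
         per_state = per_state,
         median_matrix = med,
         steady_state = rho,
         n_sweeps_used = nrow(wide),
         lambda_d = lambda_d),
    class = "fret_summary"
  )
}

#' @export
print.fret_summary <- function(x, ...) {
  cat(sprintf("<fret_summary> MAP %d system states (conditioned on %d; %d sweeps)\n",
              x$map_states, x$dimension, x$n_sweeps_used))
  cat("\nState-count posterior:\n")
  print(x$state_count)
  cat("\nPer-state posterior medians [95% CI], states ordered by efficiency:\n")
  print(x$per_state)
  cat("\nMedian system-rate matrix (1/s):\n")
  print(round(x$median_matrix, 3))
  cat("\nSteady-state populations:", paste(round(x$steady_state, 2),
                                           collapse = " "), "\n")
  invisible(x)
}

#' Tidy a posterior summary
#' @param x A `"fret_summary"`.
#' @param ... Unused.
#' @return The per-state tibble with one row per relabeled state.
#' @method tidy fret_summary
#' @export
tidy.fret_summary <- function(x, ...) x$per_state

#' One-row overview of a posterior summary
#' @param x A `"fret_summary"`.
#' @param ... Unused.
#' @return Tibble with the MAP dimension and sweep usage.
#' @method glance fret_summary
#' @export
glance.fret_summary <- function(x, ...) {
  tibble::tibble(map_states = x$map_states, dimension = x$dimension,
                 n_sweeps_used = x$n_sweeps_used)
}
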