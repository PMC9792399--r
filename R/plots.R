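#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic trace plots for a sampler run
#'
#' Shows the sampled number of system states and the log-likelihood
#' across sweeps.
#'
#' @param object A `"fret_chain"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fret_chain
#' @export
autoplot.fret_chain <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("sweep", "n_states", "loglik")],
    cols = c("n_states", "loglik"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "MCMC sweep", y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior over the number of system states
#'
#' @param chain A `"fret_chain"`.
#' @param burn_in Sweeps to drop (default: run configuration).
#' @return A ggplot bar chart of the state-count posterior.
#' @export
plot_state_count <- function(chain, burn_in = NULL) {
  hist <- state_count_posterior(chain, burn_in)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$n_states),
                                     y = .data$prob)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "number of system states", y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Joint posterior of escape rates and FRET efficiencies
#'
#' Scatter of per-sweep (efficiency, escape) pairs after relabeling,
#' optionally smoothed with a 2D kernel density estimate. The KDE layer
#' is for visualization only; numerical summaries come from
#' [summarize_states()].
#'
#' @param chain A `"fret_chain"`.
#' @param lambda_d Donor relaxation rate; default from the run.
#' @param dimension Model dimension to condition on (default MAP).
#' @param burn_in Sweeps to drop (default: run configuration).
#' @param kde Add a density contour layer.
#' @return A ggplot object.
#' @export
plot_joint_posterior <- function(chain, lambda_d = NULL, dimension = NULL,
                                 burn_in = NULL, kde = FALSE) {
  if (is.null(burn_in)) burn_in <- attr(chain, "config")$burn_in
  if (is.null(burn_in)) burn_in <- 0L
  if (is.null(lambda_d)) {
    fixed <- attr(chain, "fixed")
    lambda_d <- if (!is.null(fixed)) fixed$lambda_d else 1 / 3.5e-9
  }
  if (is.null(dimension)) {
    dimension <- attr(state_count_posterior(chain, burn_in), "map")
  }
  long <- relabeled_states(chain, lambda_d, burn_in, dimension)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$efficiency,
                                          y = .data$escape,
                                          colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::labs(x = "FRET efficiency", y = "escape rate (1/s)",
                  colour = "state") +
    ggplot2::theme_minimal()
  if (kde) {
    p <- p + ggplot2::stat_density_2d(linewidth = 0.3)
  }
  p
}
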