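#' Photon trace container
#'
#' A photon trace is a tibble with one row per detected photon, columns
#' `time_s` (strictly increasing arrival times, seconds) and `channel`
#' (integer detection channel, 1 = acceptor-targeted, 2 = donor-targeted),
#' plus the observation window carried as attributes `t_start` and
#' `t_end`. The empty trace (zero photons over a window) is valid.
#'
#' @param time_s Numeric vector of arrival times (s).
#' @param channel Integer vector of channel labels, same length.
#' @param t_start,t_end Observation window (s); `t_start < time_s[1]` and
#'   `time_s[K] < t_end`.
#'
#' @return A tibble of class `"photon_trace"`.
#' @export
#' @examples
#' photon_trace(c(0.1, 0.25, 0.3), c(1L, 2L, 2L), t_start = 0, t_end = 1)
photon_trace <- function(time_s, channel, t_start, t_end) {
  validate_trace(structure(
    tibble::tibble(time_s = as.numeric(time_s),
                   channel = as.integer(channel)),
    t_start = as.numeric(t_start), t_end = as.numeric(t_end),
    class = c("photon_trace", "tbl_df", "tbl", "data.frame")
  ))
}

#' Validate a photon trace
#' @param trace A `"photon_trace"`.
#' @return The trace, invisibly checked.
#' @export
validate_trace <- function(trace) {
  t0 <- attr(trace, "t_start"); t1 <- attr(trace, "t_end")
  if (is.null(t0) || is.null(t1) || !is.finite(t0) || !is.finite(t1) ||
      t0 >= t1) {
    stop("trace needs a finite observation window with t_start < t_end",
         call. = FALSE)
  }
  k <- nrow(trace)
  if (k > 0L) {
    if (any(!is.finite(trace$time_s))) {
      stop("photon times must be finite", call. = FALSE)
    }
    dt <- diff(trace$time_s)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop(sprintf("photon times must be strictly increasing; violation at photon %d (t = %.12g)",
                   bad, trace$time_s[bad]), call. = FALSE)
    }
    if (trace$time_s[1] <= t0 || trace$time_s[k] >= t1) {
      stop("photon times must lie strictly inside (t_start, t_end)",
           call. = FALSE)
    }
    if (any(!trace$channel %in% c(1L, 2L))) {
      stop("channels must be 1 (acceptor) or 2 (donor)", call. = FALSE)
    }
  }
  trace
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %d photons on [%g, %g] s (%.3g s span)\n",
              nrow(x), attr(x, "t_start"), attr(x, "t_end"),
              attr(x, "t_end") - attr(x, "t_start")))
  NextMethod()
}

#' Observation window of a trace
#' @param trace A `"photon_trace"`.
#' @return Named numeric `c(t_start, t_end)`.
#' @export
trace_window <- function(trace) {
  c(t_start = attr(trace, "t_start"), t_end = attr(trace, "t_end"))
}
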