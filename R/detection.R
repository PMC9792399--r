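#' Detection model: channel routing probabilities and background
#'
#' `phi_d[j]` (`phi_a[j]`) is the probability that an emitted donor
#' (acceptor) photon is registered in detection channel `j`. Channel 1 is
#' the acceptor-targeted detector and channel 2 the donor-targeted one, so
#' `phi_d[1]` is donor-to-acceptor cross talk and `1 - sum(phi_d)` is the
#' donor detection loss. `bg[j]` is the channel's Poisson background rate.
#'
#' @param phi_d Length-2 donor routing probabilities `(channel 1, channel 2)`.
#' @param phi_a Length-2 acceptor routing probabilities.
#' @param bg Length-2 background rates (photons/s), default `c(0, 0)`.
#'
#' @return Validated list of class `"detection_model"` with an extra
#'   element `loss` giving per-dye loss fractions.
#' @export
#' @examples
#' detection_model(phi_d = c(0.18, 0.82), phi_a = c(0.84, 0), bg = c(0.467, 0.283))
detection_model <- function(phi_d, phi_a, bg = c(0, 0)) {
  validate_detection(structure(
    list(phi_d = as.numeric(phi_d), phi_a = as.numeric(phi_a),
         bg = as.numeric(bg)),
    class = "detection_model"
  ))
}

#' Validate a detection model
#'
#' Enforces that all routing probabilities lie in `[0, 1]`, that each dye's
#' probabilities sum to at most 1, and that background rates are
#' nonnegative; recomputes the per-dye loss fractions `1 - sum(phi)`.
#'
#' @param det A `"detection_model"` (or a bare list with `phi_d`, `phi_a`,
#'   `bg`).
#' @return The checked model with `loss` filled in.
#' @export
validate_detection <- function(det) {
  for (nm in c("phi_d", "phi_a")) {
    phi <- det[[nm]]
    if (length(phi) != 2L || any(!is.finite(phi))) {
      stop(sprintf("%s must be two finite probabilities", nm), call. = FALSE)
    }
    bad <- which(phi < 0 | phi > 1)
    if (length(bad)) {
      stop(sprintf("%s[%d] = %g is outside [0, 1]", nm, bad[1], phi[bad[1]]),
           call. = FALSE)
    }
    if (sum(phi) > 1 + 1e-12) {
      stop(sprintf("%s sums to %.4f > 1: a photon cannot be detected in more than one channel",
                   nm, sum(phi)), call. = FALSE)
    }
  }
  if (length(det$bg) != 2L || any(!is.finite(det$bg)) || any(det$bg < 0)) {
    stop("bg must be two nonnegative rates (photons/s)", call. = FALSE)
  }
  det$loss <- c(donor = 1 - sum(det$phi_d), acceptor = 1 - sum(det$phi_a))
  class(det) <- "detection_model"
  det
}

#' Normalize a route correction matrix into routing probabilities
#'
#' A calibrated route correction matrix (RCM) combines spectral cross talk
#' and relative detection efficiencies and is only defined up to a positive
#' scale. By convention its rows are (donor, acceptor) and columns follow
#' `[[phi_d2, -phi_d1], [-phi_a2, phi_a1]]`. The normalization anchors the
#' donor routing probabilities to sum to one,
#' `c = 1 / (RCM[1, 1] + |RCM[1, 2]|)`, then
#' `phi_d2 = c * RCM[1, 1]`, `phi_d1 = c * |RCM[1, 2]|`,
#' `phi_a2 = c * |RCM[2, 1]|`, `phi_a1 = c * RCM[2, 2]`.
#'
#' @param rcm 2x2 numeric matrix; diagonal > 0, off-diagonal <= 0.
#' @param bg Optional background rates passed through to the result.
#'
#' @return A `"detection_model"` (background zero unless given).
#' @export
#' @examples
#' normalize_rcm(matrix(c(1.0, -0.22, 0.0, 1.02), 2, 2, byrow = TRUE))
normalize_rcm <- function(rcm, bg = c(0, 0)) {
  rcm <- as.matrix(rcm)
  if (!all(dim(rcm) == c(2L, 2L)) || any(!is.finite(rcm))) {
    stop("rcm must be a finite 2x2 matrix", call. = FALSE)
  }
  if (any(diag(rcm) <= 0)) {
    stop("rcm diagonal entries must be positive", call. = FALSE)
  }
  if (rcm[1, 2] > 0 || rcm[2, 1] > 0) {
    stop("rcm off-diagonal entries must be <= 0 as stored", call. = FALSE)
  }
  denom <- rcm[1, 1] + abs(rcm[1, 2])
  if (denom <= 0) stop("zero donor row: cannot normalize", call. = FALSE)
  cc <- 1 / denom
  detection_model(
    phi_d = c(cc * abs(rcm[1, 2]), cc * rcm[1, 1]),
    phi_a = c(cc * rcm[2, 2], cc * abs(rcm[2, 1])),
    bg = bg
  )
}

#' Built-in calibration presets
#'
#' Routing factors and background rates for the two published confocal
#' calibrations used throughout the examples: `"eg36"` (immobilized sample
#' in 36% ethylene glycol) and `"buffer"` (aqueous buffer, faster
#' kinetics). Backgrounds are photons/s in channels (acceptor, donor).
#'
#' @param name `"eg36"` or `"buffer"`.
#' @return A `"detection_model"`.
#' @export
#' @examples
#' calibration_preset("buffer")
calibration_preset <- function(name = c("eg36", "buffer")) {
  name <- match.arg(name)
  switch(name,
    eg36 = detection_model(
      phi_d = c(0.18, 0.82), phi_a = c(0.84, 0.0), bg = c(0.467, 0.283)
    ),
    buffer = detection_model(
      phi_d = c(0.10, 0.90), phi_a = c(0.72, 0.0), bg = c(1.561, 0.312)
    )
  )
}

#' Ideal detection (no cross talk, no loss, no background)
#' @return A `"detection_model"` with `phi_d = c(0, 1)`, `phi_a = c(1, 0)`.
#' @export
ideal_detection <- function() {
  detection_model(phi_d = c(0, 1), phi_a = c(1, 0), bg = c(0, 0))
}
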