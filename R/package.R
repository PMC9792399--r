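#' fretjump: photon-by-photon smFRET kinetics with Bayesian nonparametrics
#'
#' Joint inference of the number of conformational states of a
#' biomolecule and all transition rates from timestamped single-photon
#' smFRET traces under continuous-wave illumination. See the methods
#' vignette for the model and sampler.
#'
#' @useDynLib fretjump, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
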