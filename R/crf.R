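# R-facing linear-chain CRF primitives. Emissions are a T x L matrix of
# log-domain scores; transitions are (L+2) x (L+2) with row/column L+1 =
# START and L+2 = STOP (1-based).

#' Viterbi decoding
#'
#' Returns the tag path maximising the sum of emission and transition scores
#' including the START and STOP transitions. Ties are broken toward the
#' lowest tag index, which makes decoding deterministic.
#'
#' @param emissions T x L matrix (tokens x tags) of log-domain scores.
#' @param transitions (L+2) x (L+2) matrix; row/col L+1 is START, L+2 STOP.
#' @return List with `path` (integer vector of tag indices, 1-based) and
#'   `score` (the maximum path score).
#' @export
viterbi_decode <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  if (nrow(emissions) < 1 || ncol(emissions) < 1)
    stop("emissions must have at least one token and one tag")
  if (any(dim(transitions) != ncol(emissions) + 2))
    stop("transitions must be (L+2) x (L+2) for L = ncol(emissions)")
  cpp_crf_viterbi(emissions, transitions)
}

#' CRF log-partition function
#'
#' Log of the sum over all tag paths of the exponentiated path score,
#' computed by the forward algorithm in log space (log-sum-exp guarded).
#'
#' @inheritParams viterbi_decode
#' @return Numeric scalar.
#' @export
log_partition <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  if (nrow(emissions) < 1 || ncol(emissions) < 1)
    stop("emissions must have at least one token and one tag")
  if (any(dim(transitions) != ncol(emissions) + 2))
    stop("transitions must be (L+2) x (L+2) for L = ncol(emissions)")
  cpp_crf_log_partition(emissions, transitions)
}
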