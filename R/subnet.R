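#' Select a subnetwork of neurons
#'
#' Local mode returns the \code{n} neurons closest (Euclidean) to the cube
#' center \eqn{(L/2, L/2, L/2)}, ties broken by neuron index; random mode
#' returns \code{n} uniform indices without replacement.
#'
#' @param network a \linkS4class{NeuronalNetwork}.
#' @param n subnetwork size, 1 <= n <= N.
#' @param mode "local" or "random".
#' @param seed optional RNG seed (random mode).
#' @return integer vector of neuron indices (local mode sorted by distance).
#' @export
selectSubnetwork <- function(network, n, mode = c("local", "random"),
                             seed = NULL) {
  mode <- match.arg(mode)
  N <- nNeurons(network)
  if (n < 1 || n > N) stop("invalid input: n must lie in [1, N]")
  if (mode == "local") {
    ctr <- network@sideLength / 2
    d <- sqrt(rowSums((network@positions - ctr)^2))
    order(d, seq_len(N))[seq_len(n)]
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample.int(N, n)
  }
}

#' Restrict a binned raster or a moment set to selected neurons
#'
#' Rows (and for moments, columns) are sliced consistently, so restricting
#' moments equals computing moments on the restricted raster exactly.
#' P(K) and triplet correlations are dropped (they are not marginals of the
#' retained quantities) and can be recomputed from the restricted raster.
#'
#' @param x a \linkS4class{BinnedRaster} or \linkS4class{MomentSet}.
#' @param indices distinct neuron indices.
#' @return the restricted object of the same class.
#' @export
setGeneric("restrictTo", function(x, indices) standardGeneric("restrictTo"))

#' @rdname restrictTo
#' @export
setMethod("restrictTo", "BinnedRaster", function(x, indices) {
  checkIndices(indices, nrow(x@up))
  methods::new("BinnedRaster",
               up = methods::as(x@up[indices, , drop = FALSE], "CsparseMatrix"),
               binWidth = x@binWidth)
})

#' @rdname restrictTo
#' @export
setMethod("restrictTo", "MomentSet", function(x, indices) {
  checkIndices(indices, length(x@meanSigma))
  methods::new("MomentSet",
               meanSigma = x@meanSigma[indices],
               pairSigma = x@pairSigma[indices, indices, drop = FALSE],
               correlation = x@correlation[indices, indices, drop = FALSE],
               nSamples = x@nSamples,
               pk = numeric(),
               triples = data.frame(i = integer(), j = integer(),
                                    k = integer(), value = numeric()),
               meta = list(restrictedFrom = length(x@meanSigma)))
})

checkIndices <- function(indices, N) {
  if (anyDuplicated(indices)) stop("invalid input: duplicate indices")
  if (length(indices) < 1 || min(indices) < 1 || max(indices) > N)
    stop("invalid input: indices out of range")
  invisible(TRUE)
}

#' Save a subnetwork selection
#'
#' One-column index CSV plus a provenance JSON (mode, n, N, seed).
#' @param indices selection from \code{\link{selectSubnetwork}}.
#' @param prefix path prefix.
#' @param provenance list stored in the JSON sidecar.
#' @return the prefix, invisibly.
#' @export
writeSelection <- function(indices, prefix, provenance = list()) {
  utils::write.csv(data.frame(index = indices),
                   paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(provenance, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(prefix)
}
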