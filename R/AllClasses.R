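#' @import methods
NULL

#' Spatially embedded directed neuronal network
#'
#' An S4 container for the integrate-and-fire substrate: \code{N} neurons
#' placed uniformly at random inside a cube of side \eqn{L = (N/\rho)^{1/3}},
#' wired by directed, weighted edges whose out-degrees follow a truncated
#' power law and whose targets are chosen with probability decaying
#' exponentially with Euclidean distance. Each neuron is excitatory or
#' inhibitory; synaptic strengths \eqn{g_{ij} \in (0, 1]}.
#'
#' @slot positions numeric matrix, N x 3, coordinates inside the cube.
#' @slot edgeSrc,edgeDst integer vectors (1-based) giving directed edges.
#' @slot strength numeric vector of synaptic strengths, one per edge.
#' @slot inhibitory logical vector, length N.
#' @slot sideLength numeric(1), cube side L.
#' @slot config list, the \code{\link{networkConfig}} used to build it.
#' @export
setClass("NeuronalNetwork",
  slots = c(positions = "matrix", edgeSrc = "integer", edgeDst = "integer",
            strength = "numeric", inhibitory = "logical",
            sideLength = "numeric", config = "list"))

setValidity("NeuronalNetwork", function(object) {
  N <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be N x 3")
  if (length(object@edgeSrc) != length(object@edgeDst) ||
      length(object@edgeSrc) != length(object@strength))
    msg <- c(msg, "edge vectors must have equal length")
  if (length(object@inhibitory) != N)
    msg <- c(msg, "inhibitory flag must have length N")
  if (any(object@edgeSrc == object@edgeDst)) msg <- c(msg, "self-edges present")
  if (length(object@strength) &&
      (any(object@strength <= 0) || any(object@strength > 1)))
    msg <- c(msg, "strengths must lie in (0, 1]")
  if (length(object@edgeSrc) &&
      (min(object@edgeSrc, object@edgeDst) < 1 ||
       max(object@edgeSrc, object@edgeDst) > N))
    msg <- c(msg, "edge indices out of range")
  if (length(msg)) msg else TRUE
})

#' Spike raster from an integrate-and-fire simulation
#'
#' Sparse record of firing events (timestep, neuron) over a measurement
#' window, together with the per-timestep firing counts used for avalanche
#' detection. Timesteps are 0-based within the recorded window.
#'
#' @slot eventTimes integer, 0-based timestep of each firing.
#' @slot eventNeurons integer, 1-based neuron index of each firing.
#' @slot counts integer, number of firings at each recorded timestep.
#' @slot nTimesteps integer(1), length of the recorded window.
#' @slot nNeurons integer(1).
#' @slot meta list of provenance (config, seed, burn-in discarded).
#' @export
setClass("SpikeRaster",
  slots = c(eventTimes = "integer", eventNeurons = "integer",
            counts = "integer", nTimesteps = "integer",
            nNeurons = "integer", meta = "list"))

setValidity("SpikeRaster", function(object) {
  msg <- character()
  if (length(object@eventTimes) != length(object@eventNeurons))
    msg <- c(msg, "event vectors must have equal length")
  if (length(object@counts) != object@nTimesteps)
    msg <- c(msg, "counts must cover nTimesteps")
  if (length(object@eventTimes) &&
      (min(object@eventTimes) < 0 || max(object@eventTimes) >= object@nTimesteps))
    msg <- c(msg, "event times outside the recorded window")
  if (sum(object@counts) != length(object@eventTimes))
    msg <- c(msg, "counts and events disagree on the total number of firings")
  if (length(msg)) msg else TRUE
})

#' Binned, binarized (+1/-1) representation of a spike raster
#'
#' Each neuron-by-bin entry is +1 if the neuron fired at least once during
#' the bin, -1 otherwise. Stored sparsely as the pattern of up-states
#' (a \linkS4class{ngCMatrix}), so large N x N_b rasters stay cheap.
#'
#' @slot up ngCMatrix, N x N_b pattern of up-states.
#' @slot binWidth integer(1), bin width in timesteps.
#' @export
setClass("BinnedRaster",
  slots = c(up = "ngCMatrix", binWidth = "integer"))

setValidity("BinnedRaster", function(object) {
  if (object@binWidth < 1L) "binWidth must be >= 1" else TRUE
})

#' Moments of a binarized raster or Ising model
#'
#' Holds the time (or ensemble) averages the maximum-entropy model
#' constrains or predicts: per-spin means, pairwise products, connected
#' correlations, the simultaneous up-count distribution P(K), and optionally
#' three-point connected correlations for a set of triples.
#'
#' @slot meanSigma numeric, length N.
#' @slot pairSigma numeric matrix, N x N symmetric, unit diagonal.
#' @slot C numeric matrix of connected correlations (diagonal NA).
#' @slot nSamples numeric(1), number of bins/configurations averaged.
#' @slot pk numeric, length N + 1, P(K) for K = 0..N (may be empty).
#' @slot triples data.frame with columns i, j, k, value (may be empty).
#' @slot meta list (standard errors, sampler diagnostics, thermo averages).
#' @export
setClass("MomentSet",
  slots = c(meanSigma = "numeric", pairSigma = "matrix", correlation = "matrix",
            nSamples = "numeric", pk = "numeric", triples = "data.frame",
            meta = "list"))

setValidity("MomentSet", function(object) {
  N <- length(object@meanSigma)
  msg <- character()
  if (any(abs(object@meanSigma) > 1 + 1e-12))
    msg <- c(msg, "mean spins must lie in [-1, 1]")
  if (!all(dim(object@pairSigma) == c(N, N)))
    msg <- c(msg, "pairSigma must be N x N")
  if (length(object@pk)) {
    if (any(object@pk < -1e-12)) msg <- c(msg, "P(K) must be non-negative")
    if (abs(sum(object@pk) - 1) > 1e-8) msg <- c(msg, "P(K) must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Pairwise Ising model
#'
#' Fields \code{h}, symmetric zero-diagonal couplings \code{J}, and a
#' logical mask marking which couplings are active (pruned couplings are
#' pinned at zero). The reference temperature at which the model represents
#' the data is \eqn{T_0 = 1}.
#'
#' @slot h numeric, length N.
#' @slot J numeric matrix, N x N symmetric, zero diagonal.
#' @slot mask logical matrix, N x N symmetric; FALSE entries force J = 0.
#' @slot meta list (learning provenance).
#' @export
setClass("IsingModel",
  slots = c(h = "numeric", J = "matrix", mask = "matrix", meta = "list"))

setValidity("IsingModel", function(object) {
  N <- length(object@h)
  msg <- character()
  if (!all(dim(object@J) == c(N, N))) msg <- c(msg, "J must be N x N")
  else {
    if (max(abs(object@J - t(object@J))) > 1e-10)
      msg <- c(msg, "J must be symmetric")
    if (any(abs(diag(object@J)) > 1e-12))
      msg <- c(msg, "J must have zero diagonal")
  }
  if (!all(dim(object@mask) == c(N, N))) msg <- c(msg, "mask must be N x N")
  else if (any(abs(object@J[!object@mask]) > 0))
    msg <- c(msg, "J must vanish on masked pairs")
  if (length(msg)) msg else TRUE
})

#' Thermodynamic response curve of an Ising model
#'
#' Per-temperature magnetization per spin, susceptibility and specific heat
#' with batch-means standard errors, as measured by Metropolis sampling.
#'
#' @slot temperature numeric grid.
#' @slot m,chi,cv numeric, aligned with the grid.
#' @slot seM,seChi,seCv numeric standard errors.
#' @slot initPolicy character(1), "random" or "all_down".
#' @slot nSamples numeric(1), Monte Carlo configurations per temperature.
#' @export
setClass("ThermoCurve",
  slots = c(temperature = "numeric", m = "numeric", chi = "numeric",
            cv = "numeric", seM = "numeric", seChi = "numeric",
            seCv = "numeric", initPolicy = "character", nSamples = "numeric"))

setValidity("ThermoCurve", function(object) {
  n <- length(object@temperature)
  msg <- character()
  if (!all(lengths(list(object@m, object@chi, object@cv, object@seM,
                        object@seChi, object@seCv)) == n))
    msg <- c(msg, "curve slots must align with the temperature grid")
  if (any(object@chi < -1e-9) || any(object@cv < -1e-9))
    msg <- c(msg, "chi and cv are variances over T and must be non-negative")
  if (length(msg)) msg else TRUE
})
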