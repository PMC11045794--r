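#' Number of neurons / spins in an object
#' @param x a NeuronalNetwork, SpikeRaster, BinnedRaster, MomentSet or
#'   IsingModel.
#' @return integer(1).
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "NeuronalNetwork", function(x) nrow(x@positions))
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpikeRaster", function(x) as.integer(x@nNeurons))
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "BinnedRaster", function(x) nrow(x@up))
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "MomentSet", function(x) length(x@meanSigma))
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "IsingModel", function(x) length(x@h))

#' Edge table of a network
#' @param x a NeuronalNetwork.
#' @return data.frame with columns source, target, g, sign (+1 excitatory
#'   source, -1 inhibitory source).
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "NeuronalNetwork", function(x) {
  data.frame(source = x@edgeSrc, target = x@edgeDst, g = x@strength,
             sign = ifelse(x@inhibitory[x@edgeSrc], -1L, 1L))
})

#' Neuron positions
#' @param x a NeuronalNetwork.
#' @return N x 3 numeric matrix.
#' @export
setGeneric("neuronPositions", function(x) standardGeneric("neuronPositions"))
#' @rdname neuronPositions
#' @export
setMethod("neuronPositions", "NeuronalNetwork", function(x) x@positions)

#' Inhibitory flags
#' @param x a NeuronalNetwork.
#' @return logical vector, length N.
#' @export
setGeneric("isInhibitory", function(x) standardGeneric("isInhibitory"))
#' @rdname isInhibitory
#' @export
setMethod("isInhibitory", "NeuronalNetwork", function(x) x@inhibitory)

#' Cube side length
#' @param x a NeuronalNetwork.
#' @return numeric(1), \eqn{L = (N/\rho)^{1/3}}.
#' @export
setGeneric("sideLength", function(x) standardGeneric("sideLength"))
#' @rdname sideLength
#' @export
setMethod("sideLength", "NeuronalNetwork", function(x) x@sideLength)

#' Out- and in-degree of every neuron
#' @param x a NeuronalNetwork.
#' @return integer vector of length N.
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))
#' @rdname outDegree
#' @export
setMethod("outDegree", "NeuronalNetwork", function(x)
  tabulate(x@edgeSrc, nbins = nNeurons(x)))

#' @rdname outDegree
#' @export
setGeneric("inDegree", function(x) standardGeneric("inDegree"))
#' @rdname outDegree
#' @export
setMethod("inDegree", "NeuronalNetwork", function(x)
  tabulate(x@edgeDst, nbins = nNeurons(x)))

#' Number of time bins
#' @param x a BinnedRaster or MomentSet.
#' @return integer(1).
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname nBins
#' @export
setMethod("nBins", "BinnedRaster", function(x) ncol(x@up))
#' @rdname nBins
#' @export
setMethod("nBins", "MomentSet", function(x) as.integer(x@nSamples))

#' Dense +1/-1 spin matrix of a binned raster
#'
#' Materializes the N x N_b matrix of binarized states. Intended for small
#' rasters; large ones should stay in the sparse representation.
#' @param x a BinnedRaster.
#' @return integer matrix with entries -1/+1.
#' @export
setGeneric("sigmaMatrix", function(x) standardGeneric("sigmaMatrix"))
#' @rdname sigmaMatrix
#' @export
setMethod("sigmaMatrix", "BinnedRaster", function(x) {
  m <- matrix(-1L, nrow(x@up), ncol(x@up))
  m[as.matrix(Matrix::which(x@up, arr.ind = TRUE))] <- 1L
  m
})

#' Accessors for moment sets
#' @param x a MomentSet.
#' @return \code{meanSigma}: numeric length N; \code{pairSigma},
#'   \code{correlations}: N x N matrices; \code{upCountDistribution}:
#'   numeric length N + 1 (P(K), possibly empty); \code{tripleCorrelations}:
#'   data.frame of three-point connected correlations.
#' @export
setGeneric("meanSigma", function(x) standardGeneric("meanSigma"))
#' @rdname meanSigma
#' @export
setMethod("meanSigma", "MomentSet", function(x) x@meanSigma)
#' @rdname meanSigma
#' @export
setGeneric("pairSigma", function(x) standardGeneric("pairSigma"))
#' @rdname meanSigma
#' @export
setMethod("pairSigma", "MomentSet", function(x) x@pairSigma)
#' @rdname meanSigma
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
#' @rdname meanSigma
#' @export
setMethod("correlations", "MomentSet", function(x) x@correlation)
#' @rdname meanSigma
#' @export
setGeneric("upCountDistribution", function(x)
  standardGeneric("upCountDistribution"))
#' @rdname meanSigma
#' @export
setMethod("upCountDistribution", "MomentSet", function(x) x@pk)
#' @rdname meanSigma
#' @export
setGeneric("tripleCorrelations", function(x)
  standardGeneric("tripleCorrelations"))
#' @rdname meanSigma
#' @export
setMethod("tripleCorrelations", "MomentSet", function(x) x@triples)

#' Firing rates from a moment set
#'
#' Converts the mean binarized state into a firing rate per timestep,
#' \eqn{r_i = (\langle\sigma_i\rangle + 1) / (2 \Delta t_b)}.
#' @param x a MomentSet.
#' @param binWidth bin width in timesteps used at binarization.
#' @return numeric vector of rates (firings per timestep).
#' @export
setGeneric("firingRates", function(x, binWidth) standardGeneric("firingRates"))
#' @rdname firingRates
#' @export
setMethod("firingRates", "MomentSet", function(x, binWidth)
  (x@meanSigma + 1) / (2 * binWidth))

#' Accessors for Ising models
#' @param x an IsingModel.
#' @return \code{fields}: numeric length N; \code{couplings}: N x N matrix;
#'   \code{couplingMask}: logical N x N matrix (FALSE = pruned).
#' @export
setGeneric("fields", function(x) standardGeneric("fields"))
#' @rdname fields
#' @export
setMethod("fields", "IsingModel", function(x) x@h)
#' @rdname fields
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))
#' @rdname fields
#' @export
setMethod("couplings", "IsingModel", function(x) x@J)
#' @rdname fields
#' @export
setGeneric("couplingMask", function(x) standardGeneric("couplingMask"))
#' @rdname fields
#' @export
setMethod("couplingMask", "IsingModel", function(x) x@mask)

#' Thermodynamic curve as a data.frame
#' @param x a ThermoCurve.
#' @param row.names,optional,... passed conventions of as.data.frame.
#' @return data.frame with columns T, m, se_m, chi, se_chi, cv, se_cv.
#' @export
setMethod("as.data.frame", "ThermoCurve",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(T = x@temperature, m = x@m, se_m = x@seM, chi = x@chi,
               se_chi = x@seChi, cv = x@cv, se_cv = x@seCv)
  })

#' Temperature of the susceptibility or specific-heat maximum
#'
#' Grid argmax; the uncertainty is half a grid step (no interpolation).
#' @param x a ThermoCurve.
#' @param what "chi" or "cv".
#' @return list with components temperature and halfStep.
#' @export
setGeneric("peakTemperature", function(x, what = c("chi", "cv"))
  standardGeneric("peakTemperature"))
#' @rdname peakTemperature
#' @export
setMethod("peakTemperature", "ThermoCurve", function(x, what = c("chi", "cv")) {
  what <- match.arg(what)
  y <- if (what == "chi") x@chi else x@cv
  i <- which.max(y)
  step <- if (length(x@temperature) > 1) diff(x@temperature)[1] else NA_real_
  list(temperature = x@temperature[i], halfStep = step / 2)
})

setMethod("show", "NeuronalNetwork", function(object) {
  N <- nNeurons(object)
  cat("NeuronalNetwork with", N, "neurons,", length(object@edgeSrc),
      "directed edges\n")
  cat("  cube side L =", format(object@sideLength, digits = 6),
      "| inhibitory fraction =", format(mean(object@inhibitory), digits = 3),
      "\n")
  cat("  out-degree range:", paste(range(outDegree(object)), collapse = "-"),
      "| strengths in [", format(min(object@strength), digits = 3), ",",
      format(max(object@strength), digits = 3), "]\n")
})

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", object@nNeurons, "neurons,", object@nTimesteps,
      "timesteps,", length(object@eventTimes), "firings\n")
})

setMethod("show", "BinnedRaster", function(object) {
  cat("BinnedRaster:", nrow(object@up), "neurons x", ncol(object@up),
      "bins (bin width", object@binWidth, "timesteps), up-fraction",
      format(Matrix::nnzero(object@up) / prod(dim(object@up)), digits = 3),
      "\n")
})

setMethod("show", "MomentSet", function(object) {
  N <- length(object@meanSigma)
  cat("MomentSet over", object@nSamples, "samples:", N, "spins\n")
  cat("  <sigma> in [", format(min(object@meanSigma), digits = 4), ",",
      format(max(object@meanSigma), digits = 4), "]")
  off <- object@correlation[upper.tri(object@correlation)]
  if (length(off))
    cat(" | C_ij in [", format(min(off), digits = 4), ",",
        format(max(off), digits = 4), "]")
  cat("\n")
  if (nrow(object@triples))
    cat("  ", nrow(object@triples), "triplet correlations\n")
})

setMethod("show", "IsingModel", function(object) {
  N <- length(object@h)
  off <- upper.tri(object@mask)
  cat("IsingModel:", N, "spins,", sum(object@mask[off]), "of", sum(off),
      "couplings active\n")
  cat("  h in [", format(min(object@h), digits = 4), ",",
      format(max(object@h), digits = 4), "] | J in [",
      format(min(object@J), digits = 4), ",",
      format(max(object@J), digits = 4), "]\n")
})

setMethod("show", "ThermoCurve", function(object) {
  cat("ThermoCurve over", length(object@temperature), "temperatures in [",
      format(min(object@temperature), digits = 3), ",",
      format(max(object@temperature), digits = 3), "], init =",
      object@initPolicy, "\n")
  pk <- peakTemperature(object, "chi")
  cat("  max chi =", format(max(object@chi), digits = 5), "at T =",
      format(pk$temperature, digits = 4), "\n")
})
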