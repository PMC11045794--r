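#' Synthetic spin rasters drawn from an Ising model with known parameters
#'
#' Ground-truth generators for testing the inference pipeline without the
#' integrate-and-fire simulator. \code{method = "exact"} draws i.i.d.
#' configurations from the enumerated Boltzmann distribution at temperature
#' T (N <= 12, at most 4096 states); \code{method = "metropolis"} uses the
#' thinned Metropolis chain and is the ground-truth generator above that
#' size.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param nBins number of configurations (bins) to draw.
#' @param method "exact" or "metropolis".
#' @param T temperature (default the reference T0 = 1).
#' @param burnIn,thin Metropolis chain controls (defaults as in
#'   \code{\link{metropolisSample}}).
#' @param seed optional RNG seed.
#' @return a \linkS4class{BinnedRaster} (nominal bin width 1).
#' @export
sampleIsingRaster <- function(model, nBins,
                              method = c("exact", "metropolis"), T = 1,
                              burnIn = NULL, thin = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  N <- length(model@h)
  if (method == "exact") {
    if (N > 12) stop("exact sampling refused for N > 12 (use metropolis)")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
    H <- -S %*% model@h - 0.5 * rowSums((S %*% model@J) * S)
    w <- exp(-(H - min(H)) / T)
    pick <- sample.int(nrow(S), nBins, replace = TRUE, prob = w / sum(w))
    up <- t(S[pick, , drop = FALSE] > 0)
    return(binnedRasterFromMatrix(up, binWidth = 1L))
  }
  if (is.null(burnIn)) burnIn <- defaultBurnIn(N)
  if (is.null(thin)) thin <- 2L * N
  res <- cpp_metropolis_raster(model@h, model@J, T, as.integer(nBins),
                               as.integer(burnIn), as.integer(thin), 0L)
  up <- Matrix::sparseMatrix(i = res$up_i + 1L, j = res$up_k + 1L,
                             dims = c(N, nBins))
  methods::new("BinnedRaster", up = methods::as(up, "nMatrix"),
               binWidth = 1L)
}

#' Independent-spin raster with specified up-probabilities
#'
#' Each neuron is up in each bin independently with probability
#' \eqn{p_i}, so \eqn{E\langle\sigma_i\rangle = 2 p_i - 1} and all
#' correlations vanish in expectation.
#'
#' @param upProbs per-neuron up-probabilities in (0, 1).
#' @param nBins number of bins.
#' @param seed optional RNG seed.
#' @return a \linkS4class{BinnedRaster}.
#' @export
sampleIndependentRaster <- function(upProbs, nBins, seed = NULL) {
  if (any(upProbs <= 0 | upProbs >= 1))
    stop("invalid input: up-probabilities must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  N <- length(upProbs)
  up <- matrix(stats::runif(N * nBins) < upProbs, N, nBins)
  binnedRasterFromMatrix(up, binWidth = 1L)
}

#' Deterministic toy rasters
#'
#' A catalog of tiny bit-exact rasters used throughout the unit tests:
#' \describe{
#'   \item{alternating_pair}{two neurons, four bins, both (+,-,+,-): perfect
#'     pair correlation.}
#'   \item{all_up}{three neurons, four bins, everything up: P(K = N) = 1.}
#'   \item{staircase_4bins}{two neurons over four bins with up-counts
#'     (2, 1, 0, 1): P(K) = (0.25, 0.5, 0.25).}
#'   \item{alternating_triplet}{three identical alternating neurons: all
#'     odd connected moments vanish.}
#' }
#'
#' @param name one of the catalog names above.
#' @return a \linkS4class{BinnedRaster}.
#' @export
toyRaster <- function(name) {
  m <- switch(name,
    alternating_pair = rbind(c(1, -1, 1, -1),
                             c(1, -1, 1, -1)),
    all_up = matrix(1, 3, 4),
    staircase_4bins = rbind(c(1, 1, -1, -1),
                            c(1, -1, -1, 1)),
    alternating_triplet = matrix(rep(c(1, -1, 1, -1), each = 3), 3, 4),
    stop("unknown toy raster: ", name))
  binnedRasterFromMatrix(m, binWidth = 1L)
}
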