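#' Binarize a spike raster into +1/-1 time bins
#'
#' Bins are half-open timestep windows \eqn{[k \Delta t_b, (k+1) \Delta t_b)}
#' for k = 0, 1, ...; a trailing partial bin is discarded. A neuron's state
#' in a bin is +1 if it fired at least once during the bin (binarization
#' saturates) and -1 otherwise.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param binWidth bin width in timesteps (default 5).
#' @return a \linkS4class{BinnedRaster}.
#' @export
binarize <- function(raster, binWidth = 5L) {
  binWidth <- as.integer(binWidth)
  if (is.na(binWidth) || binWidth <= 0) stop("invalid input: binWidth <= 0")
  if (raster@nTimesteps < binWidth)
    stop("raster shorter than one bin")
  nb <- raster@nTimesteps %/% binWidth
  bin <- raster@eventTimes %/% binWidth
  keep <- bin < nb
  up <- Matrix::sparseMatrix(i = raster@eventNeurons[keep],
                             j = bin[keep] + 1L,
                             dims = c(raster@nNeurons, nb))
  methods::new("BinnedRaster", up = methods::as(up, "nMatrix"),
               binWidth = binWidth)
}

#' Build a BinnedRaster from a dense spin or up-state matrix
#'
#' @param m an N x N_b matrix, either logical/0-1 up-states or -1/+1 spins.
#' @param binWidth nominal bin width in timesteps.
#' @return a \linkS4class{BinnedRaster}.
#' @export
binnedRasterFromMatrix <- function(m, binWidth = 5L) {
  up <- m > 0
  methods::new("BinnedRaster",
               up = methods::as(methods::as(Matrix::Matrix(up, sparse = TRUE),
                                            "nMatrix"), "CsparseMatrix"),
               binWidth = as.integer(binWidth))
}

momentSetFromStats <- function(st, withPK, triples = NULL, meta = list()) {
  N <- length(st$mean_sigma)
  pair <- st$pair_sigma
  C <- pair - outer(st$mean_sigma, st$mean_sigma)
  diag(C) <- NA_real_
  nb <- st$n_bins
  seMean <- sqrt(pmax(0, 1 - st$mean_sigma^2) / nb)
  sePair <- sqrt(pmax(0, 1 - pair^2) / nb)
  trdf <- if (is.null(triples)) {
    data.frame(i = integer(), j = integer(), k = integer(),
               value = numeric())
  } else triples
  methods::new("MomentSet", meanSigma = st$mean_sigma, pairSigma = pair,
               correlation = C, nSamples = as.numeric(nb),
               pk = if (withPK) st$pk else numeric(),
               triples = trdf,
               meta = c(meta, list(seMean = seMean, sePair = sePair)))
}

#' Compute the moments constrained or predicted by the maximum-entropy model
#'
#' Time averages over bins of the binarized states: \eqn{\langle\sigma_i\rangle},
#' \eqn{\langle\sigma_i\sigma_j\rangle}, the connected correlations
#' \eqn{C_{ij} = \langle\sigma_i\sigma_j\rangle -
#' \langle\sigma_i\rangle\langle\sigma_j\rangle}, optionally the up-count
#' distribution P(K) and three-point connected correlations
#' \eqn{T_{ijk}}. Standard errors (sample SD over \eqn{\sqrt{N_b}}, bin
#' autocorrelation ignored) are attached in the meta slot.
#'
#' For N > 120 a uniform random subsample of \code{nTriples} triples is
#' used when triplets are requested; below that, all \eqn{\binom{N}{3}}
#' triples are computed if their number does not exceed \code{nTriples}.
#'
#' @param binned a \linkS4class{BinnedRaster}.
#' @param withTriplets compute three-point correlations?
#' @param nTriples triple budget when subsampling.
#' @param withPK tabulate P(K)?
#' @return a \linkS4class{MomentSet}.
#' @export
computeMoments <- function(binned, withTriplets = FALSE, nTriples = 2000L,
                           withPK = TRUE) {
  up <- binned@up
  N <- nrow(up)
  nb <- ncol(up)
  if (nb == 0) stop("invalid input: zero bins")
  idx <- Matrix::which(up, arr.ind = TRUE)
  trip <- matrix(0L, 0, 3)
  if (withTriplets && N >= 3) {
    total <- choose(N, 3)
    if (total <= nTriples) {
      trip <- t(utils::combn(N, 3))
    } else {
      picks <- unique(t(vapply(seq_len(3 * nTriples),
        function(z) sort(sample.int(N, 3)), integer(3))))
      trip <- picks[seq_len(min(nTriples, nrow(picks))), , drop = FALSE]
    }
  }
  st <- cpp_binned_stats(as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L),
                         N, nb, TRUE,
                         matrix(as.integer(trip - 1L), ncol = 3))
  triples <- NULL
  if (withTriplets && nrow(trip)) {
    ms <- st$mean_sigma
    ps <- st$pair_sigma
    raw <- st$triple_raw
    i <- trip[, 1]; j <- trip[, 2]; k <- trip[, 3]
    tijk <- raw - ms[i] * ps[cbind(j, k)] - ms[j] * ps[cbind(i, k)] -
      ms[k] * ps[cbind(i, j)] + 2 * ms[i] * ms[j] * ms[k]
    triples <- data.frame(i = i, j = j, k = k, value = tijk)
  }
  momentSetFromStats(st, withPK, triples)
}

#' Discrete truncated power-law fit by maximum likelihood
#'
#' Fits \eqn{P(x) \propto x^{-\tau}} on the integer range
#' \eqn{[x_{min}, x_{max}]} by maximizing the truncated discrete
#' log-likelihood, with a bootstrap standard error and a Kolmogorov-Smirnov
#' goodness-of-fit statistic. By default the fit covers the intermediate
#' regime from 2 to the 99th percentile of the samples.
#'
#' @param samples integer-valued samples (avalanche sizes or durations).
#' @param xMin,xMax fit range bounds; xMax defaults to the 99th percentile.
#' @param nBoot bootstrap replicates for the standard error (0 to skip).
#' @return list with exponent, se, ks, xMin, xMax and nFit (samples in
#'   range).
#' @export
fitPowerLaw <- function(samples, xMin = 2, xMax = NULL, nBoot = 50L) {
  samples <- samples[is.finite(samples)]
  if (is.null(xMax)) xMax <- max(xMin + 1, stats::quantile(samples, 0.99))
  xMax <- floor(xMax)
  xMin <- max(1, floor(xMin))
  x <- samples[samples >= xMin & samples <= xMax]
  if (length(x) < 100)
    stop("fit failure: fewer than 100 samples in [", xMin, ", ", xMax, "]")
  if (length(unique(x)) < 2)
    stop("fit failure: degenerate input (all in-range samples equal)")
  ks_range <- xMin:xMax
  mle <- function(xs) {
    slog <- sum(log(xs))
    n <- length(xs)
    nll <- function(tau) tau * slog + n * log(sum(ks_range^(-tau)))
    stats::optimize(nll, c(0.05, 8))$minimum
  }
  tau <- mle(x)
  se <- NA_real_
  if (nBoot > 0) {
    bs <- vapply(seq_len(nBoot),
                 function(z) mle(sample(x, replace = TRUE)), numeric(1))
    se <- stats::sd(bs)
  }
  p <- ks_range^(-tau)
  p <- p / sum(p)
  modelCdf <- cumsum(p)
  empCdf <- cumsum(tabulate(x - xMin + 1L, nbins = length(ks_range))) /
    length(x)
  ks <- max(abs(modelCdf - empCdf))
  list(exponent = tau, se = se, ks = ks, xMin = xMin, xMax = xMax,
       nFit = length(x))
}

#' Sample a discrete truncated power law
#'
#' Inverse-CDF sampler for \eqn{P(x) \propto x^{-\tau}} on the integer
#' range \eqn{[x_{min}, x_{max}]}; the test-suite oracle for the power-law
#' estimator and the out-degree generator.
#'
#' @param n number of samples.
#' @param tau exponent.
#' @param xMin,xMax integer support bounds.
#' @return integer vector.
#' @export
rPowerLaw <- function(n, tau, xMin = 1L, xMax = 10000L) {
  k <- xMin:xMax
  p <- k^(-tau)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

# print doubles with enough digits to round-trip bit-exactly
fmt17 <- function(x) sprintf("%.17g", x)

#' Serialize a moment set
#'
#' Writes a JSON header (N, number of samples) plus CSV payloads: the mean
#' spins, the upper triangle of the pairwise products, and P(K) as a
#' two-column CSV.
#'
#' @param moments a \linkS4class{MomentSet}.
#' @param prefix path prefix for \code{<prefix>_*.csv} and
#'   \code{<prefix>.json}.
#' @return \code{writeMoments}: the prefix, invisibly; \code{readMoments}:
#'   the reconstructed \linkS4class{MomentSet}.
#' @export
writeMoments <- function(moments, prefix) {
  N <- nNeurons(moments)
  jsonlite::write_json(list(N = N, nSamples = moments@nSamples),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  utils::write.csv(data.frame(i = seq_len(N),
                              mean = fmt17(moments@meanSigma)),
                   paste0(prefix, "_mean.csv"), row.names = FALSE,
                   quote = FALSE)
  ut <- which(upper.tri(moments@pairSigma), arr.ind = TRUE)
  utils::write.csv(data.frame(i = ut[, 1], j = ut[, 2],
                              pair = fmt17(moments@pairSigma[ut])),
                   paste0(prefix, "_pair.csv"), row.names = FALSE,
                   quote = FALSE)
  if (length(moments@pk))
    utils::write.csv(data.frame(K = seq_along(moments@pk) - 1L,
                                p = fmt17(moments@pk)),
                     paste0(prefix, "_pk.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' @rdname writeMoments
#' @export
readMoments <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  N <- hdr$N
  mm <- utils::read.csv(paste0(prefix, "_mean.csv"))
  pp <- utils::read.csv(paste0(prefix, "_pair.csv"))
  pair <- diag(N)
  pair[cbind(pp$i, pp$j)] <- pp$pair
  pair[cbind(pp$j, pp$i)] <- pp$pair
  C <- pair - outer(mm$mean, mm$mean)
  diag(C) <- NA_real_
  pkf <- paste0(prefix, "_pk.csv")
  pk <- if (file.exists(pkf)) utils::read.csv(pkf)$p else numeric()
  methods::new("MomentSet", meanSigma = mm$mean, pairSigma = pair, correlation = C,
               nSamples = as.numeric(hdr$nSamples), pk = pk,
               triples = data.frame(i = integer(), j = integer(),
                                    k = integer(), value = numeric()),
               meta = list())
}

#' Block-bootstrap standard errors for binned means
#'
#' Diagnostic alternative to the i.i.d. standard errors attached by
#' \code{\link{computeMoments}}: resamples contiguous blocks of bins
#' (circular block bootstrap) to retain short-range bin autocorrelation.
#'
#' @param binned a \linkS4class{BinnedRaster}.
#' @param blockLength bins per block (default 20).
#' @param nBoot bootstrap replicates.
#' @return numeric vector: per-neuron SE of the mean binarized state.
#' @export
blockBootstrapSE <- function(binned, blockLength = 20L, nBoot = 100L) {
  up <- binned@up
  nb <- ncol(up)
  if (nb < 2 * blockLength) stop("raster too short for the block length")
  nBlocks <- ceiling(nb / blockLength)
  reps <- vapply(seq_len(nBoot), function(z) {
    starts <- sample.int(nb, nBlocks, replace = TRUE)
    idx <- (as.vector(outer(0:(blockLength - 1), starts, "+")) - 1L) %% nb + 1L
    idx <- idx[seq_len(nb)]
    2 * Matrix::rowMeans(up[, idx, drop = FALSE]) - 1
  }, numeric(nrow(up)))
  apply(reps, 1, stats::sd)
}
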