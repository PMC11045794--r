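#' Construct a pairwise Ising model
#'
#' @param h field vector, length N.
#' @param J coupling matrix, N x N symmetric with zero diagonal. A scalar 0
#'   is expanded to the zero matrix.
#' @param mask logical N x N matrix of active couplings; NULL means fully
#'   connected. Masked couplings are forced to zero.
#' @param meta optional provenance list.
#' @return an \linkS4class{IsingModel}.
#' @examples
#' m <- isingModel(h = c(0.5, -0.5), J = matrix(c(0, 1, 1, 0), 2))
#' isingHamiltonian(m, c(1, -1))  # 0
#' @export
isingModel <- function(h, J = 0, mask = NULL, meta = list()) {
  N <- length(h)
  if (length(J) == 1) J <- matrix(as.numeric(J), N, N)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(mask)) mask <- matrix(TRUE, N, N)
  mask <- matrix(as.logical(mask), N, N)   # drop incidental attributes
  J[!mask] <- 0
  methods::new("IsingModel", h = as.numeric(h), J = J, mask = mask,
               meta = meta)
}

#' Hamiltonian and energy of a spin configuration
#'
#' \code{isingHamiltonian} evaluates
#' \eqn{H(\sigma) = -\sum_i h_i \sigma_i - \sum_{i<j} J_{ij} \sigma_i \sigma_j};
#' \code{isingEnergy} is the convenience \eqn{E(\sigma) = -H(\sigma)}.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param sigma spin vector with entries -1/+1, length N.
#' @return numeric(1).
#' @export
isingHamiltonian <- function(model, sigma) {
  if (length(sigma) != length(model@h))
    stop("invalid input: sigma length must equal N")
  if (!all(sigma %in% c(-1, 1)))
    stop("invalid input: sigma entries must be -1 or +1")
  -sum(model@h * sigma) - 0.5 * drop(sigma %*% model@J %*% sigma)
}

#' @rdname isingHamiltonian
#' @export
isingEnergy <- function(model, sigma) -isingHamiltonian(model, sigma)

#' Exact thermal moments by enumeration
#'
#' Sums over all \eqn{2^N} configurations of the Boltzmann distribution
#' \eqn{P(\sigma) = e^{-H(\sigma)/T} / Z}. Refuses N > 20. Besides the
#' moment set, the exact \eqn{\langle M \rangle}, \eqn{\langle M^2 \rangle},
#' \eqn{\langle E \rangle}, \eqn{\langle E^2 \rangle} and \eqn{\log Z} are
#' stored in the meta slot (component \code{thermo}) for use as
#' closed-form oracles.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param T temperature (reference \eqn{T_0 = 1}).
#' @return a \linkS4class{MomentSet} (nSamples = 2^N states).
#' @examples
#' m <- isingModel(h = 0.5, J = matrix(0, 1, 1))
#' meanSigma(exactMoments(m))  # tanh(0.5)
#' @export
exactMoments <- function(model, T = 1) {
  N <- length(model@h)
  if (N > 20) stop("exact enumeration refused for N > 20")
  if (T <= 0) stop("invalid input: T must be > 0")
  st <- cpp_exact_moments(model@h, model@J, T)
  C <- st$pair_sigma - outer(st$mean_sigma, st$mean_sigma)
  diag(C) <- NA_real_
  methods::new("MomentSet", meanSigma = st$mean_sigma,
               pairSigma = st$pair_sigma, correlation = C, nSamples = 2^N,
               pk = st$pk,
               triples = data.frame(i = integer(), j = integer(),
                                    k = integer(), value = numeric()),
               meta = list(thermo = list(meanM = st$mean_M,
                                         meanM2 = st$mean_M2,
                                         meanE = st$mean_E,
                                         meanE2 = st$mean_E2,
                                         logZ = st$logZ),
                           temperature = T))
}

#' Metropolis sampling of a pairwise Ising model
#'
#' Single-spin-flip Metropolis at temperature T with acceptance
#' \eqn{\min(1, e^{-\Delta H / T})}. One configuration is one attempted
#' flip of a uniformly chosen spin; the first \code{burnIn} attempts are
#' discarded and every \code{thin}-th configuration is retained until
#' \code{nSamples} samples are collected.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param T temperature.
#' @param nSamples retained samples.
#' @param burnIn discarded attempts; default 150 N for N <= 120, else
#'   100 N^2.
#' @param thin keep-every interval in attempts (default 2 N).
#' @param initPolicy "random" or "all_down" start.
#' @param withPairs accumulate pairwise moments?
#' @param withPK tabulate the up-count distribution?
#' @param seed optional RNG seed.
#' @return list with components moments (a \linkS4class{MomentSet}),
#'   M and E (retained magnetization and energy series) and acceptRate.
#' @export
metropolisSample <- function(model, T = 1, nSamples = 1000,
                             burnIn = NULL, thin = NULL,
                             initPolicy = c("random", "all_down"),
                             withPairs = TRUE, withPK = FALSE, seed = NULL) {
  initPolicy <- match.arg(initPolicy)
  if (!is.null(seed)) set.seed(seed)
  N <- length(model@h)
  if (is.null(burnIn)) burnIn <- defaultBurnIn(N)
  if (is.null(thin)) thin <- 2L * N
  if (nSamples < 1) stop("invalid input: nSamples must be >= 1")
  res <- cpp_metropolis(model@h, model@J, T, as.integer(nSamples),
                        as.integer(burnIn), as.integer(max(1L, thin)),
                        if (initPolicy == "all_down") 1L else 0L,
                        withPairs, TRUE, withPK, integer(0))
  st <- list(mean_sigma = res$mean_sigma,
             pair_sigma = if (withPairs) res$pair_sigma else
               diag(1, N),
             pk = if (withPK) res$pk else numeric(),
             n_bins = res$n_retain)
  list(moments = momentSetFromStats(st, withPK,
                                    meta = list(temperature = T,
                                                acceptRate = res$accept_rate)),
       M = res$M, E = res$E, acceptRate = res$accept_rate)
}

defaultBurnIn <- function(N) if (N <= 120) 150L * N else 100L * N^2

#' Boltzmann-machine learning configuration
#'
#' Hyper-parameters of the moment-matching iteration. The learning rates
#' decay as \eqn{\eta_h(x) = 2 \eta_J(x) = \eta_0 x^{-\alpha}}, with
#' \eqn{\alpha = 0.4} for \eqn{N \le 40}, 0.6 for \eqn{40 < N \le 120} and
#' 1.0 otherwise; couplings learn at half the field rate because there are
#' order \eqn{N^2} of them.
#'
#' @param N system size (sets the default alpha, burn-in and thinning).
#' @param nIter iteration budget (full-scale default 60000).
#' @param alpha learning-rate exponent; NULL uses the size schedule.
#' @param eta0 learning-rate prefactor for the fields.
#' @param mC Monte Carlo configurations (attempted flips) per iteration.
#' @param burnIn discarded attempts per iteration; NULL uses 150 N
#'   (N <= 120) or 100 N^2.
#' @param thin keep-every interval (default 2 N).
#' @param tolerance early-stop threshold on the maximum moment mismatch
#'   (0 disables; the fixed-budget protocol is primary).
#' @param persistent reuse the chain state across iterations instead of
#'   restarting from initPolicy (a speed option; the restarted chain is the
#'   reference protocol).
#' @param initPolicy chain initialization per iteration.
#' @param seed optional RNG seed.
#' @return list of class \code{bmConfig}.
#' @export
bmConfig <- function(N, nIter = 60000L, alpha = NULL, eta0 = 0.5,
                     mC = 3e5, burnIn = NULL, thin = NULL, tolerance = 0,
                     persistent = FALSE,
                     initPolicy = c("random", "all_down"), seed = NULL) {
  if (nIter < 1) stop("nIter must be >= 1")
  if (is.null(alpha))
    alpha <- if (N <= 40) 0.4 else if (N <= 120) 0.6 else 1.0
  if (is.null(burnIn)) burnIn <- defaultBurnIn(N)
  if (is.null(thin)) thin <- 2L * N
  if (thin < 1) stop("thin must be >= 1")
  structure(list(N = N, nIter = as.integer(nIter), alpha = alpha,
                 eta0 = eta0, mC = mC, burnIn = as.integer(burnIn),
                 thin = as.integer(thin), tolerance = tolerance,
                 persistent = persistent,
                 initPolicy = match.arg(initPolicy), seed = seed),
            class = "bmConfig")
}

#' One Boltzmann-machine update step
#'
#' First-order moment matching:
#' \eqn{h_i \leftarrow h_i - \eta_h(x) (\langle\sigma_i\rangle^{model} -
#' \langle\sigma_i\rangle^{target})} and analogously for the couplings with
#' \eqn{\eta_J = \eta_h / 2}, applied only to unmasked pairs.
#'
#' @param model current \linkS4class{IsingModel}.
#' @param momentsTarget,momentsModel \linkS4class{MomentSet}s (data and
#'   current model estimates).
#' @param x iteration index (1-based), sets the decayed rate.
#' @param config a \code{\link{bmConfig}}.
#' @return the updated \linkS4class{IsingModel}.
#' @export
bmUpdate <- function(model, momentsTarget, momentsModel, x, config) {
  etaH <- config$eta0 * x^(-config$alpha)
  etaJ <- etaH / 2
  h <- model@h - etaH * (momentsModel@meanSigma - momentsTarget@meanSigma)
  dJ <- momentsModel@pairSigma - momentsTarget@pairSigma
  J <- model@J - etaJ * dJ
  J[!model@mask] <- 0
  diag(J) <- 0
  isingModel(h, J, model@mask, model@meta)
}

#' Fit a pairwise Ising model by Boltzmann-machine learning
#'
#' Solves the inverse Ising problem for the target moments: starting from
#' \eqn{h_i = \langle\sigma_i\rangle^{target}} and \eqn{J = 0}, iterates
#' \code{\link{bmUpdate}} with model moments estimated either by Metropolis
#' sampling (the reference protocol) or by exact enumeration (the small-N
#' oracle for parameter-recovery tests). This is the concave
#' maximum-likelihood problem of an exponential family, so with exact
#' gradients the unique optimum matches the target moments.
#'
#' @param momentsTarget a \linkS4class{MomentSet}.
#' @param config a \code{\link{bmConfig}}.
#' @param mask logical coupling mask (e.g. from \code{\link{pruneMask}});
#'   NULL = fully connected.
#' @param gradientMode "metropolis" or "exact" (N <= 20).
#' @param traceEvery record the mismatch every this many iterations.
#' @return list with components model (\linkS4class{IsingModel}), trace
#'   (data.frame x, maxMismatch, rmsMismatch), and comparison (target vs
#'   model mean spins and correlations at the final iterate).
#' @export
bmFit <- function(momentsTarget, config, mask = NULL,
                  gradientMode = c("metropolis", "exact"),
                  traceEvery = 10L) {
  gradientMode <- match.arg(gradientMode)
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- length(momentsTarget@meanSigma)
  if (gradientMode == "exact" && N > 20)
    stop("exact gradients require N <= 20")
  if (is.null(mask)) mask <- matrix(TRUE, N, N)
  model <- isingModel(momentsTarget@meanSigma, 0, mask)
  nRetain <- max(1L, as.integer(ceiling(config$mC / config$thin)))
  ut <- upper.tri(mask) & mask

  xs <- integer(0); mm <- numeric(0); rms <- numeric(0)
  mismatch0 <- NA_real_
  divergeRun <- 0L
  momentsModel <- NULL
  sigma0 <- NULL
  for (x in seq_len(config$nIter)) {
    if (gradientMode == "exact") {
      momentsModel <- exactMoments(model, 1)
    } else {
      res <- cpp_metropolis(model@h, model@J, 1.0, nRetain,
                            config$burnIn, config$thin,
                            if (config$initPolicy == "all_down") 1L else 0L,
                            TRUE, FALSE, FALSE,
                            if (config$persistent && !is.null(sigma0))
                              sigma0 else integer(0))
      if (config$persistent) sigma0 <- res$sigma_final
      st <- list(mean_sigma = res$mean_sigma, pair_sigma = res$pair_sigma,
                 pk = numeric(), n_bins = res$n_retain)
      momentsModel <- momentSetFromStats(st, FALSE)
    }
    dMean <- abs(momentsModel@meanSigma - momentsTarget@meanSigma)
    dPair <- abs(momentsModel@pairSigma - momentsTarget@pairSigma)[ut]
    mMax <- max(dMean, dPair)
    if (x == 1) mismatch0 <- mMax
    if (x == 1 || x %% traceEvery == 0 || x == config$nIter) {
      xs <- c(xs, x); mm <- c(mm, mMax)
      rms <- c(rms, sqrt(mean(c(dMean, dPair)^2)))
    }
    if (mMax > 10 * mismatch0) {
      divergeRun <- divergeRun + 1L
      if (divergeRun >= 100L) {
        e <- simpleError("learning failure: diverging moment mismatch")
        e$trace <- data.frame(x = xs, maxMismatch = mm, rmsMismatch = rms)
        stop(e)
      }
    } else divergeRun <- 0L
    if (config$tolerance > 0 && mMax < config$tolerance) break
    model <- bmUpdate(model, momentsTarget, momentsModel, x, config)
  }
  model@meta <- list(alpha = config$alpha, nIter = config$nIter,
                     mC = config$mC, gradientMode = gradientMode)
  offd <- upper.tri(mask)
  cIF <- momentsTarget@pairSigma -
    outer(momentsTarget@meanSigma, momentsTarget@meanSigma)
  cBM <- momentsModel@pairSigma -
    outer(momentsModel@meanSigma, momentsModel@meanSigma)
  list(model = model,
       trace = data.frame(x = xs, maxMismatch = mm, rmsMismatch = rms),
       comparison = list(meanTarget = momentsTarget@meanSigma,
                         meanModel = momentsModel@meanSigma,
                         cTarget = cIF[offd], cModel = cBM[offd]))
}

#' Prune weakly correlated couplings
#'
#' Builds the coupling mask of the partially-connected Ising model: a pair
#' is kept when its measured correlation reaches the threshold
#' \eqn{\eta \cdot \max(C_{ij})}; below it the coupling is pinned at zero
#' during learning. \eqn{\eta = 0} keeps every pair.
#'
#' @param C correlation matrix (diagonal ignored) or a
#'   \linkS4class{MomentSet}.
#' @param eta threshold fraction in [0, 1].
#' @return logical N x N mask (TRUE = keep), with attributes
#'   \code{removedFraction} and \code{threshold}.
#' @examples
#' C <- matrix(c(NA, 0.5, 0.05, 0.5, NA, 0.02, 0.05, 0.02, NA), 3)
#' attr(pruneMask(C, 0.2), "removedFraction")  # 2/3 of pairs removed
#' @export
pruneMask <- function(C, eta) {
  if (methods::is(C, "MomentSet")) C <- C@correlation
  if (!length(C)) stop("invalid input: empty correlation matrix")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  N <- nrow(C)
  off <- upper.tri(C)
  cmax <- max(C[off], na.rm = TRUE)
  mask <- matrix(TRUE, N, N)
  if (eta > 0) {
    thr <- eta * cmax
    keep <- !is.na(C) & C >= thr
    keep <- keep | t(keep)
    diag(keep) <- TRUE
    mask <- keep
  }
  structure(mask,
            removedFraction = 1 - sum(mask[off]) / sum(off),
            threshold = if (eta > 0) eta * cmax else -Inf)
}

#' Serialize an Ising model as JSON
#'
#' Fields as a list, couplings as an upper-triangle list of (i, j, J)
#' restricted to unmasked pairs (the mask is implicit in the listed pairs),
#' plus metadata. Round-trips exactly.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param path output path for \code{writeIsingModel}; input for
#'   \code{readIsingModel}.
#' @return \code{writeIsingModel}: path, invisibly; \code{readIsingModel}:
#'   the \linkS4class{IsingModel}.
#' @export
writeIsingModel <- function(model, path) {
  N <- length(model@h)
  ut <- which(upper.tri(model@mask) & model@mask, arr.ind = TRUE)
  jsonlite::write_json(
    list(N = N, h = model@h,
         pairs = data.frame(i = ut[, 1], j = ut[, 2],
                            J = model@J[ut]),
         meta = model@meta),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeIsingModel
#' @export
readIsingModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- obj$N
  J <- matrix(0, N, N)
  mask <- matrix(FALSE, N, N)
  diag(mask) <- TRUE
  if (length(obj$pairs) && nrow(obj$pairs)) {
    ij <- cbind(obj$pairs$i, obj$pairs$j)
    J[ij] <- obj$pairs$J
    J[ij[, 2:1, drop = FALSE]] <- obj$pairs$J
    mask[ij] <- TRUE
    mask[ij[, 2:1, drop = FALSE]] <- TRUE
  }
  isingModel(obj$h, J, mask, as.list(obj$meta))
}
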