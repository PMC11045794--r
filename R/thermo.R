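#' Fluctuation-dissipation response functions
#'
#' From aligned Monte Carlo series of the magnetization
#' \eqn{M = \sum_i \sigma_i} and energy \eqn{E = -H}:
#' \eqn{m = \langle M \rangle / N},
#' \eqn{\chi = (\langle M^2\rangle - \langle M\rangle^2) / T} and
#' \eqn{C_v = (\langle E^2\rangle - \langle E\rangle^2) / T^2}
#' (Boltzmann constant set to one). Standard errors by batch means.
#'
#' @param M,E aligned sample series.
#' @param T temperature (> 0).
#' @param nSpins system size N (for the per-spin magnetization).
#' @param nBatches batches for the batch-means standard errors.
#' @return list with m, chi, cv and their standard errors.
#' @examples
#' responseFunctions(c(2, -2, 2, -2), rep(1, 4), T = 1, nSpins = 2)$chi  # 4
#' @export
responseFunctions <- function(M, E, T, nSpins, nBatches = 20L) {
  if (T <= 0) stop("invalid input: T must be > 0")
  if (length(M) != length(E)) stop("M and E series must be aligned")
  n <- length(M)
  varP <- function(x) mean(x^2) - mean(x)^2   # population variance
  m <- mean(M) / nSpins
  chi <- varP(M) / T
  cv <- varP(E) / T^2
  nb <- max(2L, min(nBatches, n %/% 2L))
  idx <- sort(rep_len(seq_len(nb), n))   # contiguous batches
  bm <- tapply(M, idx, mean) / nSpins
  bchi <- tapply(M, idx, varP) / T
  bcv <- tapply(E, idx, varP) / T^2
  list(m = m, chi = chi, cv = cv,
       seM = stats::sd(bm) / sqrt(nb),
       seChi = stats::sd(bchi) / sqrt(nb),
       seCv = stats::sd(bcv) / sqrt(nb))
}

#' Temperature sweep of an Ising model
#'
#' Runs an independent Metropolis chain at every temperature of the grid
#' (fresh start per temperature, no annealing) and evaluates the
#' fluctuation-dissipation response functions. The "all_down" start
#' suppresses the low-temperature initialization dependence that a random
#' start exposes in rugged (spin-glass-like) landscapes.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param Tgrid temperatures; default 30 evenly spaced points on [0.1, 3].
#' @param mC Monte Carlo configurations (attempted flips) per temperature;
#'   every \code{thin}-th is retained.
#' @param initPolicy "random" or "all_down".
#' @param burnIn,thin chain controls (defaults 150 N / 100 N^2 and 2 N).
#' @param seed optional RNG seed.
#' @return a \linkS4class{ThermoCurve}.
#' @export
thermoSweep <- function(model, Tgrid = seq(0.1, 3.0, length.out = 30),
                        mC = 3e5, initPolicy = c("random", "all_down"),
                        burnIn = NULL, thin = NULL, seed = NULL) {
  initPolicy <- match.arg(initPolicy)
  if (!is.null(seed)) set.seed(seed)
  N <- length(model@h)
  if (is.null(burnIn)) burnIn <- defaultBurnIn(N)
  if (is.null(thin)) thin <- 2L * N
  nRetain <- max(2L, as.integer(ceiling(mC / thin)))
  rows <- lapply(Tgrid, function(T) {
    s <- metropolisSample(model, T = T, nSamples = nRetain, burnIn = burnIn,
                          thin = thin, initPolicy = initPolicy,
                          withPairs = FALSE)
    responseFunctions(s$M, s$E, T, N)
  })
  g <- function(f) vapply(rows, `[[`, numeric(1), f)
  methods::new("ThermoCurve", temperature = as.numeric(Tgrid),
               m = g("m"), chi = g("chi"), cv = g("cv"),
               seM = g("seM"), seChi = g("seChi"), seCv = g("seCv"),
               initPolicy = initPolicy, nSamples = as.numeric(mC))
}

#' Write / read a thermodynamic curve
#'
#' CSV with columns T, m, se_m, chi, se_chi, cv, se_cv plus a JSON sidecar
#' with the initialization policy and sampling effort.
#'
#' @param curve a \linkS4class{ThermoCurve}.
#' @param prefix path prefix (writes \code{<prefix>.csv}, \code{<prefix>.json}).
#' @return \code{writeThermoCurve}: prefix invisibly; \code{readThermoCurve}:
#'   the \linkS4class{ThermoCurve}.
#' @export
writeThermoCurve <- function(curve, prefix) {
  d <- as.data.frame(curve)
  d[] <- lapply(d, fmt17)
  utils::write.csv(d, paste0(prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(initPolicy = curve@initPolicy,
                            nSamples = curve@nSamples),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(prefix)
}

#' @rdname writeThermoCurve
#' @export
readThermoCurve <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, ".csv"))
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  methods::new("ThermoCurve", temperature = d$T, m = d$m, chi = d$chi,
               cv = d$cv, seM = d$se_m, seChi = d$se_chi, seCv = d$se_cv,
               initPolicy = hdr$initPolicy, nSamples = hdr$nSamples)
}
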