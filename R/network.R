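#' Configuration for building an integrate-and-fire network
#'
#' Collects the structural parameters of the spatially embedded scale-free
#' substrate. Defaults follow the standard parameterization: density
#' \eqn{\rho = 0.016} neurons per unit volume, connection length scale
#' \eqn{r_0 = 5}, out-degrees on \eqn{[2, 20]} with
#' \eqn{P(k_{out}) \propto k_{out}^{-2}}, and initial strengths uniform on
#' \eqn{[0.04, 0.06]}.
#'
#' @param N neuron count (>= 2).
#' @param rho spatial density (neurons per unit volume).
#' @param r0 connection length scale.
#' @param koutMin,koutMax out-degree bounds; koutMax must be < N.
#' @param gammaK out-degree power-law exponent.
#' @param pIn inhibitory fraction in [0, 0.5].
#' @param gInitLow,gInitHigh initial strength interval.
#' @param seed optional RNG seed applied by \code{\link{buildNetwork}}.
#' @return a validated list of class \code{networkConfig}.
#' @export
networkConfig <- function(N, rho = 0.016, r0 = 5, koutMin = 2L, koutMax = 20L,
                          gammaK = 2, pIn = 0, gInitLow = 0.04,
                          gInitHigh = 0.06, seed = NULL) {
  N <- as.integer(N)
  koutMin <- as.integer(koutMin)
  koutMax <- as.integer(koutMax)
  if (is.na(N) || N < 2) stop("invalid configuration: N must be >= 2")
  if (koutMin < 1) stop("invalid configuration: koutMin must be >= 1")
  if (koutMin > koutMax) stop("invalid configuration: koutMin > koutMax")
  if (koutMax >= N)
    stop("invalid configuration: koutMax must be < N ",
         "(targets are drawn without replacement)")
  if (pIn < 0 || pIn > 0.5)
    stop("invalid configuration: pIn must lie in [0, 0.5]")
  if (gInitLow >= gInitHigh)
    stop("invalid configuration: gInitLow must be < gInitHigh")
  if (rho <= 0 || r0 <= 0) stop("invalid configuration: rho and r0 positive")
  structure(list(N = N, rho = rho, r0 = r0, koutMin = koutMin,
                 koutMax = koutMax, gammaK = gammaK, pIn = pIn,
                 gInitLow = gInitLow, gInitHigh = gInitHigh, seed = seed),
            class = "networkConfig")
}

# inverse-CDF sample from P(k) propto k^(-gamma) on {kmin, ..., kmax}
sampleOutDegrees <- function(n, kmin, kmax, gamma) {
  k <- kmin:kmax
  p <- k^(-gamma)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Build a spatially embedded scale-free directed network
#'
#' Places \code{N} neurons uniformly inside a cube of side
#' \eqn{L = (N/\rho)^{1/3}}, samples an out-degree for each neuron from the
#' truncated power law, and wires each source to distinct targets drawn
#' without replacement with probability proportional to
#' \eqn{e^{-r / r_0}} of the Euclidean distance \eqn{r} (open boundaries,
#' kernel normalized per source). Any neuron left without incoming
#' connections receives one repair edge from a donor chosen with the same
#' distance kernel, subject to the out-degree cap. Initial strengths are
#' uniform on the configured interval; exactly \code{round(pIn * N)} neurons
#' are flagged inhibitory, chosen uniformly.
#'
#' @param config a \code{\link{networkConfig}}.
#' @return a \linkS4class{NeuronalNetwork}.
#' @examples
#' net <- buildNetwork(networkConfig(N = 50, seed = 1))
#' range(outDegree(net))
#' all(inDegree(net) >= 1)
#' @export
buildNetwork <- function(config) {
  if (!inherits(config, "networkConfig"))
    stop("config must be created by networkConfig()")
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$N
  L <- (N / config$rho)^(1 / 3)
  pos <- matrix(stats::runif(3 * N, 0, L), ncol = 3)
  dmat <- as.matrix(stats::dist(pos))
  kern <- exp(-dmat / config$r0)
  diag(kern) <- 0

  kout <- sampleOutDegrees(N, config$koutMin, config$koutMax, config$gammaK)
  srcs <- vector("list", N)
  for (i in seq_len(N)) {
    srcs[[i]] <- sample.int(N, kout[i], replace = FALSE, prob = kern[i, ])
  }
  edgeSrc <- rep.int(seq_len(N), kout)
  edgeDst <- unlist(srcs, use.names = FALSE)

  # in-degree repair: give every orphan one incoming edge, distance-weighted
  indeg <- tabulate(edgeDst, nbins = N)
  orphans <- which(indeg == 0)
  repaired <- 0L
  for (j in orphans) {
    deg <- tabulate(edgeSrc, nbins = N)
    w <- kern[, j]
    w[deg >= config$koutMax] <- 0          # donors at the out-degree cap
    w[j] <- 0
    # avoid duplicating an existing edge into j (there are none: j is orphan)
    if (all(w == 0)) stop("in-degree repair failed: no eligible donor")
    donor <- sample.int(N, 1L, prob = w)
    edgeSrc <- c(edgeSrc, donor)
    edgeDst <- c(edgeDst, j)
    repaired <- repaired + 1L
  }
  if (repaired > 0L)
    message("in-degree repair added ", repaired, " edge(s)")

  g <- stats::runif(length(edgeSrc), config$gInitLow, config$gInitHigh)
  nInh <- round(config$pIn * N)
  inhibitory <- rep(FALSE, N)
  if (nInh > 0) inhibitory[sample.int(N, nInh)] <- TRUE

  methods::new("NeuronalNetwork", positions = pos,
               edgeSrc = as.integer(edgeSrc), edgeDst = as.integer(edgeDst),
               strength = g, inhibitory = inhibitory, sideLength = L,
               config = unclass(config))
}

# compressed out-adjacency (0-based) for the C engine
networkCSR <- function(net) {
  N <- nNeurons(net)
  o <- order(net@edgeSrc, net@edgeDst)
  src <- net@edgeSrc[o]
  dst <- net@edgeDst[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = N)))
  list(ptr = as.integer(ptr), idx = as.integer(dst - 1L),
       g = net@strength[o], order = o,
       sign = ifelse(net@inhibitory, -1L, 1L))
}

#' Write / read a network as an edge-list CSV plus JSON header
#'
#' The CSV has columns source, target, g, sign; the JSON header carries N,
#' L, the build configuration and the positions and inhibitory flags so the
#' reader round-trips the object exactly.
#'
#' @param net a \linkS4class{NeuronalNetwork}.
#' @param prefix path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @return \code{writeNetwork}: the prefix, invisibly. \code{readNetwork}:
#'   the reconstructed \linkS4class{NeuronalNetwork}.
#' @export
writeNetwork <- function(net, prefix) {
  ed <- edgeTable(net)
  ed$g <- fmt17(ed$g)   # 17 significant digits: doubles round-trip exactly
  utils::write.csv(ed, paste0(prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  hdr <- list(N = nNeurons(net), L = net@sideLength, config = net@config,
              positions = net@positions, inhibitory = net@inhibitory)
  jsonlite::write_json(hdr, paste0(prefix, ".json"), digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(prefix)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(prefix) {
  ed <- utils::read.csv(paste0(prefix, ".csv"))
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  methods::new("NeuronalNetwork",
               positions = matrix(unlist(hdr$positions), ncol = 3,
                                  byrow = is.list(hdr$positions)),
               edgeSrc = as.integer(ed$source),
               edgeDst = as.integer(ed$target),
               strength = as.numeric(ed$g),
               inhibitory = as.logical(hdr$inhibitory),
               sideLength = as.numeric(hdr$L),
               config = as.list(hdr$config))
}
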