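# shared generators for the unit tests; everything is built in code under
# the seed active in the calling test

randomIsingModel <- function(N, hSd = 0.5, jSd = 0.3) {
  h <- rnorm(N, 0, hSd)
  J <- matrix(rnorm(N * N, 0, jSd), N)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  isingModel(h, J)
}

# raster with events at given (timestep, neuron) pairs
makeRaster <- function(times, neurons, nTimesteps, nNeurons) {
  counts <- tabulate(times + 1L, nbins = nTimesteps)
  methods::new("SpikeRaster", eventTimes = as.integer(times),
               eventNeurons = as.integer(neurons),
               counts = as.integer(counts),
               nTimesteps = as.integer(nTimesteps),
               nNeurons = as.integer(nNeurons), meta = list())
}

# a small critical-ish pipeline cached across tests within one run
smallCriticalPipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    net <- buildNetwork(networkConfig(N = 40, seed = 401))
    dyn <- dynamicsConfig(seed = 402)
    net <- suppressMessages(runShaping(net, dyn))
    dyn$seed <- 403
    tn <- tuneCriticality(net, dyn, nAvalanches = 1500)
    dyn$deltaURec <- tn$deltaURec
    dyn$seed <- 404
    sim <- simulateActivity(net, dyn, nTimesteps = 4e5)
    cache <<- list(net = net, dyn = dyn, tune = tn, sim = sim,
                   moments = computeMoments(binarize(sim$raster, 5)))
    cache
  }
})
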