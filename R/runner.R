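#' Desk-scale experiment presets
#'
#' Canned end-to-end configurations at desk scale (small networks, reduced
#' bin counts and learning budgets); the full-scale knobs (N_b = 1e7
#' bins, 60000 learning iterations, 3e5 configurations per iteration) are
#' plain configuration values and can be set explicitly.
#'
#' @param name "firing_stats" (firing statistics of N = 40 networks),
#'   "thermo_small" (thermodynamics over N = 20 and 40 with replicas), or
#'   "prune_small" (pruned-coupling fractions on one N = 80 network).
#' @param seed global seed.
#' @return an experiment configuration list for \code{\link{runExperiment}}.
#' @export
deskPreset <- function(name, seed = 1L) {
  switch(name,
    firing_stats = list(
      seed = seed, N = 40, replicates = 3,
      network = list(), dynamics = list(),
      tune = list(grid = c(0.002, 0.004, 0.008, 0.015, 0.03),
                  nAvalanches = 2000),
      simulate = list(nAvalanches = 8000),
      stats = list(binWidth = 5)),
    thermo_small = list(
      seed = seed, N = c(20, 40), replicates = 3,
      # out-degree cap below the smallest N (k_out < N is required for
      # sampling targets without replacement)
      network = list(koutMax = 19), dynamics = list(),
      tune = list(grid = c(0.002, 0.004, 0.008, 0.015, 0.03),
                  nAvalanches = 1500),
      simulate = list(nAvalanches = 6000),
      stats = list(binWidth = 5),
      fit = list(nIter = 1200, mC = 1e4, eta0 = 0.5),
      thermo = list(mC = 4e4, initPolicy = "all_down")),
    prune_small = list(
      seed = seed, N = 80, replicates = 1,
      network = list(), dynamics = list(),
      tune = list(grid = c(0.002, 0.004, 0.008, 0.015, 0.03),
                  nAvalanches = 1500),
      simulate = list(nTimesteps = 5e5),
      stats = list(binWidth = 5),
      prune = list(eta = c(0.10, 0.15, 0.20))),
    stop("unknown preset: ", name))
}

#' Run a staged experiment
#'
#' Executes the staged pipeline (network construction, shaping, criticality
#' tuning, simulation, binned statistics, Boltzmann-machine fit, pruning,
#' thermodynamic sweep, subnetwork restriction) for each system size and
#' replicate in the configuration, writing serialized artifacts and a
#' manifest. One global seed spawns independent per-run, per-stage seeds,
#' so re-running with the same configuration reproduces every output
#' exactly and changing one stage does not perturb the RNG stream of
#' another.
#'
#' @param config nested list (see \code{\link{deskPreset}}); stages present
#'   in the list are run, absent ones skipped. An empty stage list writes
#'   the manifest only.
#' @param dir output directory (created).
#' @return the run directory, invisibly; the manifest lists all artifacts.
#' @export
runExperiment <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stageNames <- c("network", "shaping", "tune", "simulate", "stats", "fit",
                  "prune", "thermo", "subnet")
  Ns <- if (is.null(config$N)) integer() else config$N
  reps <- if (is.null(config$replicates)) 1L else config$replicates
  set.seed(if (is.null(config$seed)) 1L else config$seed)
  nRuns <- length(Ns) * reps
  seedTab <- if (nRuns > 0)
    matrix(sample.int(.Machine$integer.max - 1L,
                      nRuns * length(stageNames)),
           nrow = nRuns) else matrix(integer(), 0, length(stageNames))
  colnames(seedTab) <- stageNames

  manifest <- list(config = config, created = format(t0),
                   package = as.character(utils::packageVersion("NeuroIsing")),
                   runs = list())
  run <- 0L
  for (N in Ns) for (r in seq_len(reps)) {
    run <- run + 1L
    sub <- file.path(dir, sprintf("run_N%d_r%d", N, r))
    dir.create(sub, showWarnings = FALSE)
    seeds <- seedTab[run, ]
    files <- character()
    tStart <- Sys.time()

    netArgs <- config$network
    netArgs$N <- N
    netArgs$seed <- seeds[["network"]]
    net <- do.call(networkConfig, netArgs)
    net <- buildNetwork(net)
    writeNetwork(net, file.path(sub, "network"))
    files <- c(files, "network.csv", "network.json")

    dynArgs <- config$dynamics
    if (is.null(dynArgs)) dynArgs <- list()
    dynArgs$seed <- NULL
    dyn <- do.call(dynamicsConfig, dynArgs)

    if (!identical(config$shaping, FALSE)) {
      dyn$seed <- seeds[["shaping"]]
      net <- runShaping(net, dyn)
      dyn$seed <- NULL
    }

    if (!is.null(config$tune)) {
      dyn$seed <- seeds[["tune"]]
      tn <- do.call(tuneCriticality,
                    c(list(network = net, config = dyn), config$tune))
      dyn$deltaURec <- tn$deltaURec
      dyn$seed <- NULL
      utils::write.csv(tn$trace, file.path(sub, "tune_trace.csv"),
                       row.names = FALSE)
      files <- c(files, "tune_trace.csv")
    }

    moments <- NULL
    binned <- NULL
    if (!is.null(config$simulate)) {
      dyn$seed <- seeds[["simulate"]]
      sim <- do.call(simulateActivity,
                     c(list(network = net, config = dyn), config$simulate))
      dyn$seed <- NULL
      writeRaster(sim$raster, file.path(sub, "raster"))
      utils::write.csv(sim$avalanches, file.path(sub, "avalanches.csv"),
                       row.names = FALSE)
      files <- c(files, "raster.tsv", "raster.json", "avalanches.csv")
      if (!is.null(config$stats)) {
        bw <- if (is.null(config$stats$binWidth)) 5L else
          config$stats$binWidth
        set.seed(seeds[["stats"]])
        binned <- binarize(sim$raster, bw)
        moments <- computeMoments(binned,
          withTriplets = isTRUE(config$stats$withTriplets))
        writeMoments(moments, file.path(sub, "moments"))
        files <- c(files, "moments.json", "moments_mean.csv",
                   "moments_pair.csv", "moments_pk.csv")
      }
    }

    model <- NULL
    if (!is.null(config$fit) && !is.null(moments)) {
      fitArgs <- config$fit
      fitArgs$N <- N
      fitArgs$seed <- seeds[["fit"]]
      bc <- do.call(bmConfig, fitArgs)
      mask <- NULL
      if (!is.null(config$prune) && length(config$prune$eta) == 1)
        mask <- pruneMask(moments, config$prune$eta)
      fit <- bmFit(moments, bc, mask = mask)
      model <- fit$model
      writeIsingModel(model, file.path(sub, "model.json"))
      utils::write.csv(fit$trace, file.path(sub, "fit_trace.csv"),
                       row.names = FALSE)
      files <- c(files, "model.json", "fit_trace.csv")
    }

    if (!is.null(config$prune) && !is.null(moments)) {
      pr <- vapply(config$prune$eta, function(e)
        attr(pruneMask(moments, e), "removedFraction"), numeric(1))
      utils::write.csv(data.frame(eta = config$prune$eta,
                                  removedFraction = pr),
                       file.path(sub, "prune.csv"), row.names = FALSE)
      files <- c(files, "prune.csv")
    }

    if (!is.null(config$thermo) && !is.null(model)) {
      thArgs <- config$thermo
      thArgs$seed <- seeds[["thermo"]]
      curve <- do.call(thermoSweep, c(list(model = model), thArgs))
      writeThermoCurve(curve, file.path(sub, "thermo"))
      files <- c(files, "thermo.csv", "thermo.json")
    }

    if (!is.null(config$subnet) && !is.null(binned)) {
      idx <- selectSubnetwork(net, config$subnet$n,
                              mode = config$subnet$mode,
                              seed = seeds[["subnet"]])
      writeSelection(idx, file.path(sub, "subnet"),
                     provenance = list(n = config$subnet$n,
                                       mode = config$subnet$mode, N = N))
      subm <- computeMoments(restrictTo(binned, idx))
      writeMoments(subm, file.path(sub, "subnet_moments"))
      files <- c(files, "subnet.csv", "subnet.json", "subnet_moments.json",
                 "subnet_moments_mean.csv", "subnet_moments_pair.csv",
                 "subnet_moments_pk.csv")
    }

    manifest$runs[[basename(sub)]] <- list(
      N = N, replicate = r, seeds = as.list(seeds),
      files = files[file.exists(file.path(sub, files))],
      wallSeconds = as.numeric(difftime(Sys.time(), tStart, units = "secs")))
  }
  manifest$totalWallSeconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), force = TRUE,
                       null = "null")
  invisible(dir)
}

#' Summary tables from a completed run directory
#'
#' Reads the manifest and serialized artifacts and assembles comparison
#' tables: target-versus-model moments where a fit is present, pruning
#' fractions, and the per-run thermodynamic peak summary. Reporting twice
#' on the same directory yields identical tables.
#'
#' @param dir a directory written by \code{\link{runExperiment}}.
#' @return list of data.frames: runs, peaks, prune, momentRange.
#' @export
reportExperiment <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing artifact: manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  runNames <- names(manifest$runs)
  peaks <- list(); prune <- list(); momentRange <- list(); runs <- list()
  for (rn in runNames) {
    sub <- file.path(dir, rn)
    info <- manifest$runs[[rn]]
    runs[[rn]] <- data.frame(run = rn, N = info$N, replicate = info$replicate)
    mj <- file.path(sub, "moments")
    if (file.exists(paste0(mj, ".json"))) {
      mo <- readMoments(mj)
      off <- upper.tri(mo@correlation)
      momentRange[[rn]] <- data.frame(
        run = rn, minMean = min(meanSigma(mo)), maxMean = max(meanSigma(mo)),
        minC = min(mo@correlation[off]), maxC = max(mo@correlation[off]))
    }
    tc <- file.path(sub, "thermo")
    if (file.exists(paste0(tc, ".csv"))) {
      curve <- readThermoCurve(tc)
      pk <- peakTemperature(curve, "chi")
      peaks[[rn]] <- data.frame(run = rn, N = info$N,
                                TchiMax = pk$temperature,
                                chiMax = max(curve@chi),
                                cvMax = max(curve@cv))
    }
    pc <- file.path(sub, "prune.csv")
    if (file.exists(pc)) {
      d <- utils::read.csv(pc)
      d$run <- rn
      prune[[rn]] <- d
    }
  }
  bindOrEmpty <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame()
  list(runs = bindOrEmpty(runs), peaks = bindOrEmpty(peaks),
       prune = bindOrEmpty(prune), momentRange = bindOrEmpty(momentRange))
}
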