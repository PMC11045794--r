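#' Write / read a spike raster as sparse text
#'
#' One firing per line, "t<TAB>neuron_id" (0-based timestep, 1-based
#' neuron), plus a JSON sidecar with N, the number of timesteps and the
#' simulation provenance. Round-trips exactly.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param prefix path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return \code{writeRaster}: the prefix, invisibly; \code{readRaster}:
#'   the reconstructed \linkS4class{SpikeRaster}.
#' @export
writeRaster <- function(raster, prefix) {
  utils::write.table(data.frame(t = raster@eventTimes,
                                neuron = raster@eventNeurons),
                     paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(N = raster@nNeurons,
                            nTimesteps = raster@nTimesteps,
                            meta = raster@meta),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(prefix)
}

#' @rdname writeRaster
#' @export
readRaster <- function(prefix) {
  ev <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nT <- as.integer(hdr$nTimesteps)
  counts <- tabulate(ev$t + 1L, nbins = nT)
  methods::new("SpikeRaster", eventTimes = as.integer(ev$t),
               eventNeurons = as.integer(ev$neuron),
               counts = as.integer(counts), nTimesteps = nT,
               nNeurons = as.integer(hdr$N), meta = as.list(hdr$meta))
}
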