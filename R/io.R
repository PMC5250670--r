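#' Write / read a spike raster as tab-separated text
#'
#' Columns `time_ms`, `neuron`, `cell_type`.
#'
#' @param raster Raster tibble or an `snn_sim`.
#' @param path Output file.
#' @return `write_raster()` returns the path invisibly; `read_raster()` the
#'   raster tibble.
#' @export
write_raster <- function(raster, path) {
  if (inherits(raster, "snn_sim")) raster <- raster$raster
  utils::write.table(raster, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}
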