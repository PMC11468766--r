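#' @title Image input/output
#' @name imaging_io
#' @description Multichannel TIFF reading and writing for channel stacks
#'   (one page per channel, donor/fret/acceptor order) with a JSON sidecar
#'   carrying pixel size, bit depth and acquisition metadata, plus float
#'   TIFF / CSV export of ratio and pressure maps.
NULL

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a channel stack as multipage TIFF + JSON sidecar
#'
#' Channels are stored as one TIFF page each in donor, FRET, acceptor
#' order, in an 8- or 16-bit container depending on bit depth; the sidecar
#' records the logical bit depth, pixel size, channel order, control flag
#' and time index.
#'
#' @param stack A [channel_stack()].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  container_bits <- if (stack$bit_depth <= 8) 8L else 16L
  scale <- 2^container_bits - 1
  pages <- list(stack$donor / scale, stack$fret / scale,
                stack$acceptor / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = container_bits)
  jsonlite::write_json(list(
    channels = c("donor", "fret", "acceptor"),
    bit_depth = stack$bit_depth, container_bits = container_bits,
    pixel_size_um = stack$pixel_size_um,
    time_index = stack$time_index, is_control = stack$is_control,
    tool = paste0("osmofret ", as.character(utils::packageVersion("osmofret")))
  ), sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) stop("expected a 3-page (donor/fret/acceptor) TIFF")
  scale <- 2^meta$container_bits - 1
  ch <- lapply(pages, function(p) round(p * scale))
  channel_stack(ch[[1]], ch[[2]], ch[[3]], bit_depth = meta$bit_depth,
                pixel_size_um = meta$pixel_size_um,
                time_index = if (is.null(meta$time_index))
                  NA_integer_
                else suppressWarnings(as.integer(meta$time_index)),
                is_control = isTRUE(meta$is_control))
}

#' Export a ratio or pressure map
#'
#' Writes the map values as a 32-bit float TIFF normalized to `[0, 1]`
#' (the normalization scale is recorded in a JSON sidecar; excluded pixels
#' are stored as 0 and identified by the mask), the mask as an 8-bit TIFF,
#' and a long-format CSV summary (`row`, `col`, `value`, `status`) of the
#' masked pixels with unscaled values.
#'
#' @param map A `ratio_map` or `pressure_map`.
#' @param path_prefix Output path prefix; writes `<prefix>.tif`,
#'   `<prefix>.json`, `<prefix>_mask.tif` and `<prefix>.csv`.
#' @return `path_prefix`, invisibly.
#' @export
write_map <- function(map, path_prefix) {
  stopifnot(inherits(map, c("ratio_map", "pressure_map")))
  vals <- map$values
  vals[is.na(vals)] <- 0
  scale <- max(vals, 1)
  tiff::writeTIFF(vals / scale, paste0(path_prefix, ".tif"),
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(kind = class(map)[1], value_scale = scale,
                            pixel_size_um = map$pixel_size_um),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(map$mask * 1, paste0(path_prefix, "_mask.tif"),
                  bits.per.sample = 8)
  idx <- which(map$mask, arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              value = map$values[map$mask],
                              status = map$status[map$mask]),
                   paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(path_prefix)
}
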