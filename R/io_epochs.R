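#' Serialize an EpochSet to a binary tensor with a JSON sidecar
#'
#' Writes the trials x channels x time tensor as little-endian float64
#' (column-major, trial index fastest) to \code{<path>.bin} and all metadata —
#' dimensions, time base, per-trial levels, kept mask, channel names,
#' interpolated channels, subject metadata and the processing log — to
#' \code{<path>.json}.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param path output path without extension.
#' @return \code{path}, invisibly.
#' @seealso [readEpochs()]
#' @export
writeEpochs <- function(epochs, path) {
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  writeBin(as.vector(epochs@data), con, size = 8, endian = "little")
  close(con)
  meta <- list(
    format = "tactileERP-epochs-v1",
    dim = dim(epochs@data),
    dim_order = c("trial", "channel", "time"),
    time_ms = epochs@timeMs,
    levels = epochs@levels,
    kept_mask = epochs@keptMask,
    channel_names = epochs@channelNames,
    interpolated_channels = epochs@interpolatedChannels,
    subject = epochs@subjectMeta,
    log = epochs@log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EpochSet written by [writeEpochs()]
#'
#' @param path path without extension (expects \code{.bin} and \code{.json}).
#' @return an \linkS4class{EpochSet}.
#' @export
readEpochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "tactileERP-epochs-v1"))
    stop("not a tactileERP epochs container: ", path)
  d <- as.integer(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  close(con)
  sm <- as.list(meta$subject)
  new("EpochSet", data = array(x, dim = d), timeMs = meta$time_ms,
      levels = as.character(meta$levels),
      keptMask = as.logical(meta$kept_mask),
      channelNames = as.character(meta$channel_names),
      interpolatedChannels = as.character(meta$interpolated_channels %||%
                                            character()),
      subjectMeta = sm, log = as.character(meta$log %||% character()))
}

#' Render a topographic map to a PNG or the active device
#'
#' Draws the 2-D montage as a schematic head (circle plus nose), with each
#' electrode coloured by its map value on a symmetric diverging scale and
#' labelled. Intended for quick inspection of group-difference and p-value
#' maps.
#'
#' @param topo a TopoMap data.frame (from [groupDifferenceTopomap()] or
#'   [levelAnovaTopomap()]), with columns \code{electrode, value, x, y}.
#' @param file optional PNG path; when NULL, draws on the active device.
#' @param main plot title.
#' @param cex point expansion.
#' @return \code{file} (or NULL), invisibly.
#' @export
plotTopomap <- function(topo, file = NULL, main = "", cex = 3) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  v <- topo$value
  lim <- max(abs(v), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  col <- pal[1 + round(50 * (1 + pmax(pmin(v / lim, 1), -1)))]
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.1 * cos(th), 1.1 * sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(1.09, 1.25, 1.09))   # nose
  graphics::points(topo$x, topo$y, pch = 21, bg = col, cex = cex)
  graphics::text(topo$x, topo$y - 0.12, topo$electrode, cex = 0.7)
  invisible(file)
}
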