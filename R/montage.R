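#' Standard 32-channel 10/20 montage
#'
#' Electrode names and 2-D scalp positions (top-down projection, unit head
#' radius, nose towards positive y) for a 32-channel saline-cap layout. The
#' online reference site (CPz) and ground (AFz) are part of the montage but are
#' excluded from topographic maps, leaving the 30 plotted scalp electrodes.
#'
#' @param channels optional character vector restricting the montage to a
#'   subset of channels (order preserved).
#' @return a data.frame with columns \code{channel}, \code{x}, \code{y},
#'   \code{role} (\code{"eeg"}, \code{"ref"} or \code{"gnd"}).
#' @examples
#' m <- standardMontage()
#' nrow(m)                       # 32
#' sum(m$role == "eeg")          # 30 plotted electrodes
#' @export
standardMontage <- function(channels = NULL) {
  m <- data.frame(
    channel = c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FCz", "FC2", "FC6",
                "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CPz", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8",
                "POz", "O1", "Oz", "O2", "AFz"),
    x = c(-0.31, 0.31, -0.81, -0.41, 0, 0.41, 0.81,
          -0.69, -0.23, 0, 0.23, 0.69,
          -1, -0.5, 0, 0.5, 1,
          -0.69, -0.23, 0, 0.23, 0.69,
          -0.81, -0.41, 0, 0.41, 0.81,
          0, -0.31, 0, 0.31, 0),
    y = c(0.95, 0.95, 0.59, 0.52, 0.5, 0.52, 0.59,
          0.28, 0.26, 0.26, 0.26, 0.28,
          0, 0, 0, 0, 0,
          -0.28, -0.26, -0.26, -0.26, -0.28,
          -0.59, -0.52, -0.5, -0.52, -0.59,
          -0.75, -0.95, -1, -0.95, 0.75),
    stringsAsFactors = FALSE
  )
  m$role <- "eeg"
  m$role[m$channel == "CPz"] <- "ref"
  m$role[m$channel == "AFz"] <- "gnd"
  if (!is.null(channels)) {
    missing <- setdiff(channels, m$channel)
    if (length(missing))
      stop("unknown montage channels: ", paste(missing, collapse = ", "))
    m <- m[match(channels, m$channel), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Pairwise electrode distances on the 2-D montage
#' @param montage a montage data.frame from [standardMontage()].
#' @return symmetric distance matrix with channel dimnames.
#' @keywords internal
montageDistances <- function(montage) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  dimnames(d) <- list(montage$channel, montage$channel)
  d
}
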