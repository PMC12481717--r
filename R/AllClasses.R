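#' @import methods
NULL

LEVEL_LABELS <- paste0("L", 1:5)

#' EEGRecording: continuous multi-channel EEG with a stimulus event table
#'
#' Container for one subject's continuous recording: a channels x samples
#' matrix in microvolts, the sampling rate, channel names, a stimulus event
#' table (onset sample and level label L1..L5) and subject metadata
#' (id, group, age in years).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot rate sampling rate in Hz.
#' @slot channelNames character vector of 10/20 labels (rownames of data).
#' @slot events data.frame with columns \code{onset_sample} (1-based) and
#'   \code{level} (one of L1..L5).
#' @slot subjectMeta list with \code{id}, \code{group}, \code{age}.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric",
                 channelNames = "character", events = "data.frame",
                 subjectMeta = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@channelNames))
      msg <- c(msg, "channelNames length must equal nrow(data)")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (nrow(object@events)) {
      if (!all(c("onset_sample", "level") %in% names(object@events)))
        msg <- c(msg, "events must have onset_sample and level columns")
      else {
        if (!all(object@events$level %in% LEVEL_LABELS))
          msg <- c(msg, "event levels must be L1..L5")
        # every event must admit the full 1000 ms post-stimulus window
        if (any(object@events$onset_sample + object@rate - 1 > ncol(object@data)))
          msg <- c(msg, "event onset + 1000 ms must fit inside the recording")
        if (any(object@events$onset_sample < 1))
          msg <- c(msg, "event onsets must be positive sample indices")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' EpochSet: trials x channels x time tensor of stimulus-locked epochs
#'
#' @slot data numeric array, trials x channels x time, microvolts.
#' @slot timeMs time axis in ms relative to stimulus onset (default -500..999).
#' @slot levels per-trial level label L1..L5.
#' @slot keptMask per-trial logical; FALSE marks artifact-rejected trials.
#' @slot channelNames channel labels (dimnames of the channel axis).
#' @slot interpolatedChannels channels replaced by spatial interpolation.
#' @slot subjectMeta list with id, group, age.
#' @slot log character vector recording each processing step and parameter.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", timeMs = "numeric", levels = "character",
                 keptMask = "logical", channelNames = "character",
                 interpolatedChannels = "character", subjectMeta = "list",
                 log = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
      msg <- c(msg, "data must be trials x channels x time")
    else {
      if (d[1] != length(object@levels)) msg <- c(msg, "levels length != n trials")
      if (d[1] != length(object@keptMask)) msg <- c(msg, "keptMask length != n trials")
      if (d[2] != length(object@channelNames)) msg <- c(msg, "channelNames length != n channels")
      if (d[3] != length(object@timeMs)) msg <- c(msg, "timeMs length != n time points")
    }
    if (length(object@levels) && !all(object@levels %in% LEVEL_LABELS))
      msg <- c(msg, "levels must be L1..L5")
    if (length(msg)) msg else TRUE
  })

#' Evoked: per-condition trial-averaged waveform for one subject
#'
#' @slot data numeric matrix, channels x time, microvolts.
#' @slot timeMs time axis in ms.
#' @slot level condition label L1..L5.
#' @slot nTrials number of kept trials averaged.
#' @slot channelNames channel labels.
#' @slot subjectMeta list with id, group, age.
#' @exportClass Evoked
setClass("Evoked",
  representation(data = "matrix", timeMs = "numeric", level = "character",
                 nTrials = "integer", channelNames = "character",
                 subjectMeta = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@channelNames))
      msg <- c(msg, "channelNames length != nrow(data)")
    if (ncol(object@data) != length(object@timeMs))
      msg <- c(msg, "timeMs length != ncol(data)")
    if (!object@level %in% LEVEL_LABELS)
      msg <- c(msg, "level must be one of L1..L5")
    if (length(msg)) msg else TRUE
  })

#' CVSeries: sliding-window across-level coefficient of variation
#'
#' One subject x electrode time series of the across-level CV statistic on a
#' sliding-window time base. Windows whose pooled mean magnitude fell below the
#' epsilon guard are flagged.
#'
#' @slot subject subject id.
#' @slot electrode electrode label.
#' @slot windowCentersMs window center times, ms post-stimulus.
#' @slot cv dimensionless CV values (non-negative by the magnitude convention).
#' @slot flagged logical, TRUE where the epsilon guard was hit.
#' @slot windowWidth window width, ms.
#' @slot step step length, ms.
#' @slot span analysed span (start, end), ms post-stimulus.
#' @exportClass CVSeries
setClass("CVSeries",
  representation(subject = "character", electrode = "character",
                 windowCentersMs = "numeric", cv = "numeric",
                 flagged = "logical", windowWidth = "numeric",
                 step = "numeric", span = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@cv) != length(object@windowCentersMs))
      msg <- c(msg, "cv length != windowCentersMs length")
    if (length(object@cv) != length(object@flagged))
      msg <- c(msg, "flagged length != cv length")
    if (any(object@cv < 0, na.rm = TRUE))
      msg <- c(msg, "cv must be non-negative")
    if (length(object@span) != 2L)
      msg <- c(msg, "span must be (start, end)")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", object@subjectMeta$id %||% "<unnamed>",
      sprintf("(%s, age %.2f y)\n", object@subjectMeta$group %||% "?",
              object@subjectMeta$age %||% NA_real_))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples, %d kept\n",
              d[1], d[2], d[3], sum(object@keptMask)))
  cat(sprintf("  time %g..%g ms; interpolated: %s\n",
              min(object@timeMs), max(object@timeMs),
              if (length(object@interpolatedChannels))
                paste(object@interpolatedChannels, collapse = ",") else "none"))
})

setMethod("show", "Evoked", function(object) {
  cat(sprintf("Evoked (%s): %d channels x %d samples, averaged %d trials\n",
              object@level, nrow(object@data), ncol(object@data),
              object@nTrials))
})

setMethod("show", "CVSeries", function(object) {
  cat(sprintf("CVSeries %s/%s: %d windows (%g ms wide, %g ms step) over %g..%g ms, %d flagged\n",
              object@subject, object@electrode, length(object@cv),
              object@windowWidth, object@step, object@span[1], object@span[2],
              sum(object@flagged)))
})
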