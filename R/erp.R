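#' Trial-average kept epochs into per-level evoked responses
#'
#' Arithmetic mean over the kept trials of each stimulus level.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param levels which levels to average (default all present).
#' @return named list of \linkS4class{Evoked}, one per level.
#' @export
averageEvoked <- function(epochs, levels = sort(unique(epochs@levels))) {
  out <- list()
  for (lv in levels) {
    sel <- epochs@levels == lv & epochs@keptMask
    if (!any(sel))
      stop("no kept trials for level ", lv)
    m <- colMeans(epochs@data[sel, , , drop = FALSE])
    rownames(m) <- epochs@channelNames
    out[[lv]] <- new("Evoked", data = m, timeMs = epochs@timeMs, level = lv,
                     nTrials = sum(sel), channelNames = epochs@channelNames,
                     subjectMeta = epochs@subjectMeta)
  }
  out
}

#' Peak-window component amplitude and latency
#'
#' Finds the polarity-appropriate extremum (maximum for P-components, minimum
#' for N-components) within the component's fixed search window, then reports
#' the mean amplitude over the 20 ms window centred on that peak (clipped at
#' the search-window edges if the peak lies within 10 ms of a boundary) and the
#' peak latency. For a flat window the earliest extremum is taken.
#'
#' @param evoked an \linkS4class{Evoked}.
#' @param electrode channel name.
#' @param component one of P100, N140, P200, N200, P300.
#' @param windows search windows (default [componentWindows()]).
#' @param meanHalfWidth half-width of the averaging window, ms (default 10).
#' @return list with \code{amplitude} (signed, microvolts),
#'   \code{peakLatency} (ms) and \code{tie} (logical, TRUE if the extremum was
#'   not unique).
#' @export
peakWindowAmplitude <- function(evoked, electrode, component,
                                windows = componentWindows(),
                                meanHalfWidth = 10) {
  if (!electrode %in% evoked@channelNames)
    stop("electrode not present: ", electrode)
  win <- windows[[component]]
  if (is.null(win)) stop("no search window defined for component ", component)
  t <- evoked@timeMs
  sel <- which(t >= win[1] & t <= win[2])
  if (!length(sel)) stop("search window outside evoked time range")
  x <- evoked@data[match(electrode, evoked@channelNames), sel]
  pol <- componentPolarity(component)
  xe <- pol * x
  pk <- sel[which.max(xe)]               # earliest extremum on ties
  tie <- sum(xe == max(xe)) > 1L
  peakMs <- t[pk]
  lo <- max(win[1], peakMs - meanHalfWidth)
  hi <- min(win[2], peakMs + meanHalfWidth)
  msel <- which(t >= lo & t <= hi)
  list(amplitude = mean(evoked@data[match(electrode, evoked@channelNames), msel]),
       peakLatency = peakMs, tie = tie)
}

ANALYSIS_ELECTRODES <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4")

#' Build the long-format component table for a cohort
#'
#' One row per (subject, electrode, component, level): signed mean amplitude
#' from the peak-centred 20 ms rule and the peak latency, plus subject group
#' and age. The default electrode set is the eight analysis sites FP1/2, F3/4,
#' C3/4, P3/4.
#'
#' @param cohortEvoked named list: per subject, a list of per-level
#'   \linkS4class{Evoked} objects (as returned by [averageEvoked()]).
#' @param electrodes electrodes to quantify (default the 8 analysis sites,
#'   restricted to channels present).
#' @param components components to quantify (default all five).
#' @return data.frame with columns \code{subject, group, age, electrode,
#'   component, level, amplitude_uV, peak_latency_ms}.
#' @export
buildComponentTable <- function(cohortEvoked,
                                electrodes = ANALYSIS_ELECTRODES,
                                components = names(componentWindows())) {
  gaps <- character()
  nMax <- length(cohortEvoked) * 5L * length(electrodes) * length(components)
  subject <- group <- electrode <- component <- level <- character(nMax)
  age <- amplitude <- latency <- numeric(nMax)
  k <- 0L
  for (subj in names(cohortEvoked)) {
    evs <- cohortEvoked[[subj]]
    for (lv in LEVEL_LABELS) {
      ev <- evs[[lv]]
      if (is.null(ev)) { gaps <- c(gaps, paste0(subj, "/", lv)); next }
      meta <- ev@subjectMeta
      el <- intersect(electrodes, ev@channelNames)
      if (!length(el))
        stop("none of the requested electrodes present for ", subj)
      for (e in el) {
        for (cp in components) {
          pw <- peakWindowAmplitude(ev, e, cp)
          k <- k + 1L
          subject[k] <- subj; group[k] <- meta$group; age[k] <- meta$age
          electrode[k] <- e; component[k] <- cp; level[k] <- lv
          amplitude[k] <- pw$amplitude; latency[k] <- pw$peakLatency
        }
      }
    }
  }
  if (length(gaps))
    stop("missing evoked responses for: ", paste(gaps, collapse = ", "))
  idx <- seq_len(k)
  data.frame(subject = subject[idx], group = group[idx], age = age[idx],
             electrode = electrode[idx], component = component[idx],
             level = level[idx], amplitude_uV = amplitude[idx],
             peak_latency_ms = latency[idx], stringsAsFactors = FALSE)
}

#' Compute a subject's evoked responses end to end
#'
#' Convenience wrapper: preprocess a recording and trial-average per level.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param ... passed to [preprocessRecording()].
#' @return named list of per-level \linkS4class{Evoked}.
#' @export
subjectEvoked <- function(recording, ...) {
  averageEvoked(preprocessRecording(recording, ...))
}
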