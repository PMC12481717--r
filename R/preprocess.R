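#' Zero-phase Butterworth band-pass filter
#'
#' Applies a zero-phase third-order Butterworth band-pass per channel,
#' realized as a cascade of an order-\code{order} high-pass at \code{low} Hz
#' and an order-\code{order} low-pass at \code{high} Hz, each run forward and
#' backward (filtfilt) so the net phase is zero and no component latency is
#' shifted. Signals are odd-reflection padded before filtering to suppress
#' edge transients; the amplitude response is the squared Butterworth
#' magnitude, so stop-band attenuation is doubled (in dB) relative to a
#' single pass.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param low high-pass edge, Hz (default 0.01).
#' @param high low-pass edge, Hz (default 12).
#' @param order Butterworth order of each cascade section (default 3).
#' @param padSeconds reflection-padding length, seconds; defaults to three
#'   time constants of the slowest (high-pass) section, capped by the signal
#'   length.
#' @return the filtered \linkS4class{EEGRecording}; events unchanged.
#' @export
bandpassFilter <- function(recording, low = 0.01, high = 12, order = 3,
                           padSeconds = 3 / (2 * pi * low)) {
  rate <- recording@rate
  if (!(low > 0 && low < high && high < rate / 2))
    stop("need 0 < low < high < Nyquist")
  if (order < 1) stop("order must be >= 1")
  x <- recording@data
  if (!all(is.finite(x))) stop("recording contains non-finite samples")
  hp <- signal::butter(order, low / (rate / 2), "high")
  lp <- signal::butter(order, high / (rate / 2), "low")
  out <- .filtfiltCascade(x, list(hp$b, lp$b), list(hp$a, lp$a),
                          list(filterStepState(hp$b, hp$a),
                               filterStepState(lp$b, lp$a)),
                          as.integer(min(padSeconds * rate, ncol(x) - 1)))
  dimnames(out) <- dimnames(x)
  initialize(recording, data = out)
}

# Steady-state direct-form-II-transposed filter state for a unit-step input:
# the state vector zi with (I - A') zi = B, so that filtering a constant
# signal c from initial state c * zi yields exactly c * H(1) with no
# transient (the lfilter_zi construction).
filterStepState <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  m <- length(a) - 1L
  if (m == 0L) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(1, m - 1L, m - 1L), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(A), B)
}

#' Detect bad channels from the channel power spectrum
#'
#' Computes each channel's log total power over 0.5-100 Hz from a Welch
#' spectrum (median across segments, so transient artifacts such as blinks do
#' not dominate a channel's estimate) and flags channels whose log power
#' deviates from the cross-channel median by more than \code{zThreshold}
#' robust z-units (median/MAD), in either direction.
#'
#' @param recording an \linkS4class{EEGRecording} with at least 8 channels.
#' @param zThreshold robust z cut-off (default 3.5).
#' @return character vector of flagged channel names (possibly empty).
#' @export
detectBadChannels <- function(recording, zThreshold = 3.5) {
  x <- recording@data
  if (nrow(x) < 8) stop("need at least 8 channels")
  rate <- recording@rate
  hi <- min(100, rate / 2 * 0.99)
  logPow <- vapply(seq_len(nrow(x)), function(i) {
    p <- welchPSD(x[i, ], rate, average = "median")
    sel <- p$freq >= 0.5 & p$freq <= hi
    tot <- sum(p$psd[sel]) * (p$freq[2] - p$freq[1])
    log10(tot + .Machine$double.xmin)
  }, numeric(1))
  z <- robustZ(logPow)
  recording@channelNames[abs(z) > zThreshold]
}

#' Interpolate bad channels on the 2-D montage
#'
#' Replaces each bad channel (in every trial) by the inverse-distance-weighted
#' average of its 4 nearest good channels on the 2-D scalp layout.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param bad character vector of channel names to replace.
#' @param montage montage data.frame covering the epoch channels.
#' @param k number of nearest good neighbours (default 4).
#' @return the \linkS4class{EpochSet} with bad channels replaced and
#'   \code{interpolatedChannels} updated.
#' @export
interpolateChannels <- function(epochs, bad, montage = standardMontage(),
                                k = 4) {
  if (!length(bad)) return(epochs)
  chan <- epochs@channelNames
  if (!all(bad %in% chan)) stop("bad channels not all present in epochs")
  good <- setdiff(chan, bad)
  if (length(good) < 3) stop("fewer than 3 good channels left to interpolate from")
  if (!all(chan %in% montage$channel)) stop("montage does not cover epoch channels")
  d <- montageDistances(montage[match(chan, montage$channel), , drop = FALSE])
  x <- epochs@data
  for (b in bad) {
    db <- d[b, good]
    nb <- names(sort(db))[seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[b, nb], 1e-6)
    w <- w / sum(w)
    bi <- match(b, chan)
    acc <- 0
    for (j in seq_along(nb))
      acc <- acc + w[j] * x[, match(nb[j], chan), , drop = FALSE]
    x[, bi, ] <- acc
  }
  initialize(epochs, data = x,
             interpolatedChannels = union(epochs@interpolatedChannels, bad),
             log = c(epochs@log,
                     sprintf("interpolate: %s (k=%d)",
                             paste(bad, collapse = ","), k)))
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' One epoch per event on a half-open \code{[tmin, tmax)} ms window relative to
#' stimulus onset; the default -500..1000 ms window yields exactly 1500 samples
#' at 1000 Hz (the sample at +1000 ms is excluded).
#'
#' @param recording an \linkS4class{EEGRecording} with events.
#' @param tmin,tmax epoch window in ms relative to onset (defaults -500, 1000).
#' @return an \linkS4class{EpochSet}; trial levels carried over from the event
#'   table; all trials initially kept.
#' @export
epochRecording <- function(recording, tmin = -500, tmax = 1000) {
  rate <- recording@rate
  ev <- recording@events
  if (!nrow(ev)) stop("recording has no events")
  o0 <- round(tmin * rate / 1000)
  o1 <- round(tmax * rate / 1000) - 1L   # half-open: exclude tmax
  nT <- o1 - o0 + 1L
  nSamp <- ncol(recording@data)
  lo <- ev$onset_sample + o0
  hi <- ev$onset_sample + o1
  badEv <- which(lo < 1 | hi > nSamp)
  if (length(badEv))
    stop("event(s) too close to the recording edge: ",
         paste(badEv, collapse = ", "))
  nCh <- nrow(recording@data)
  arr <- array(0, dim = c(nrow(ev), nCh, nT))
  for (i in seq_len(nrow(ev)))
    arr[i, , ] <- recording@data[, lo[i]:hi[i]]
  new("EpochSet", data = arr,
      timeMs = (o0:o1) * 1000 / rate,
      levels = ev$level,
      keptMask = rep(TRUE, nrow(ev)),
      channelNames = recording@channelNames,
      interpolatedChannels = character(),
      subjectMeta = recording@subjectMeta,
      log = sprintf("epoch: tmin=%g tmax=%g (%d trials x %d samples)",
                    tmin, tmax, nrow(ev), nT))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (default the full -500..0 ms pre-stimulus interval).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param window (start, end) ms; must lie within \code{[-500, 0]}.
#' @return the corrected \linkS4class{EpochSet}.
#' @export
baselineCorrect <- function(epochs, window = c(-500, 0)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- epochs@timeMs >= window[1] & epochs@timeMs < window[2]
  if (!any(sel)) stop("empty baseline window")
  x <- epochs@data
  d <- dim(x)
  bl <- rowMeans(matrix(x[, , sel, drop = FALSE], d[1] * d[2]))
  x <- x - bl   # recycles over the time axis (dim 3 last)
  initialize(epochs, data = x,
             log = c(epochs@log,
                     sprintf("baseline: [%g,%g] ms", window[1], window[2])))
}

#' Reject artifact trials by peak-to-peak amplitude
#'
#' Marks as rejected (kept mask set FALSE) every trial whose maximum
#' cross-channel peak-to-peak amplitude exceeds the threshold; the data are not
#' modified, so rejection is reversible and monotone in the threshold.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param peakToPeakMax threshold, microvolts (default 200).
#' @return the \linkS4class{EpochSet} with an updated kept mask.
#' @export
rejectArtifactTrials <- function(epochs, peakToPeakMax = 200) {
  if (peakToPeakMax <= 0) stop("peakToPeakMax must be positive")
  x <- epochs@data
  d <- dim(x)
  m <- matrix(x, d[1] * d[2])          # (trial, channel) rows x time columns
  rng <- apply(m, 1, function(v) max(v) - min(v))
  ptp <- apply(matrix(rng, d[1], d[2]), 1, max)
  keep <- ptp <= peakToPeakMax
  if (mean(!keep) > 0.5)
    warning(sprintf("threshold %g uV rejects %.0f%% of trials",
                    peakToPeakMax, 100 * mean(!keep)))
  initialize(epochs, keptMask = epochs@keptMask & keep,
             log = c(epochs@log,
                     sprintf("reject: ptp>%g uV -> %d rejected",
                             peakToPeakMax, sum(!keep))))
}

#' Full preprocessing pipeline for one recording
#'
#' Runs the stages in their canonical order: band-pass filter, (optional)
#' bad-channel detection, epoching, baseline correction, (optional)
#' interpolation of detected channels, peak-to-peak artifact rejection.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param low,high,order band-pass parameters (defaults 0.01 Hz, 12 Hz, 3).
#' @param tmin,tmax epoch window, ms (defaults -500, 1000).
#' @param baselineWindow baseline window, ms (default c(-500, 0)).
#' @param peakToPeakMax rejection threshold, microvolts (default 200).
#' @param detectBad detect and interpolate bad channels (default TRUE when the
#'   recording has at least 8 channels).
#' @param zThreshold bad-channel robust z cut-off (default 3.5).
#' @param montage montage for interpolation.
#' @return an \linkS4class{EpochSet}.
#' @export
preprocessRecording <- function(recording, low = 0.01, high = 12, order = 3,
                                tmin = -500, tmax = 1000,
                                baselineWindow = c(-500, 0),
                                peakToPeakMax = 200,
                                detectBad = nrow(recording@data) >= 8,
                                zThreshold = 3.5,
                                montage = standardMontage()) {
  rec <- bandpassFilter(recording, low, high, order)
  bad <- if (detectBad) detectBadChannels(rec, zThreshold) else character()
  ep <- epochRecording(rec, tmin, tmax)
  ep <- baselineCorrect(ep, baselineWindow)
  if (length(bad))
    ep <- interpolateChannels(ep, bad,
                              montage[match(ep@channelNames, montage$channel), ,
                                      drop = FALSE])
  rejectArtifactTrials(ep, peakToPeakMax)
}
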