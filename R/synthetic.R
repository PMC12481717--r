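#' Component search windows (ms post-stimulus)
#'
#' The five somatosensory ERP components are quantified inside fixed search
#' windows: P100 in 50-100 ms, N140 in 100-150 ms, P200 in 150-200 ms, N200 in
#' 250-300 ms and P300 in 300-350 ms. The 200-250 ms gap is deliberately
#' unassigned.
#'
#' @return named list of (start, end) ms vectors.
#' @export
componentWindows <- function() {
  list(P100 = c(50, 100), N140 = c(100, 150), P200 = c(150, 200),
       N200 = c(250, 300), P300 = c(300, 350))
}

componentPolarity <- function(component) {
  ifelse(substr(component, 1, 1) == "P", 1, -1)
}

#' Default ERP component templates
#'
#' One template per component: a one-cycle raised-cosine (Hanning) bump of the
#' stated width, peaking at \code{latencyMean} ms with trial-to-trial Gaussian
#' latency jitter, polarity +1 for P-components and -1 for N-components, a
#' multiplicative gain per stimulus level (non-decreasing, stronger stimulus
#' gives a larger response), and a Gaussian spatial topography centred on a
#' component-specific electrode.
#'
#' @param montage montage data.frame (default [standardMontage()]).
#' @param levelGain 5-vector of multiplicative gains for L1..L5; must be
#'   non-decreasing.
#' @param topoSigma spatial width (montage units) of the Gaussian topography.
#' @return named list of component templates; each has \code{name},
#'   \code{polarity}, \code{latencyMean}, \code{latencyJitterSd}, \code{width},
#'   \code{baseAmplitude} (microvolts), \code{levelGain} and \code{topography}
#'   (named weights in [0,1]).
#' @export
componentTemplates <- function(montage = standardMontage(),
                               levelGain = c(0.6, 0.8, 1.0, 1.2, 1.4),
                               topoSigma = 0.6) {
  stopifnot(length(levelGain) == 5, !is.unsorted(levelGain))
  defs <- data.frame(
    name = c("P100", "N140", "P200", "N200", "P300"),
    latencyMean = c(75, 125, 175, 275, 325),
    latencyJitterSd = c(3, 3, 4, 5, 6),
    width = c(100, 110, 130, 140, 160),
    baseAmplitude = c(8, 9, 14, 11, 10),
    center = c("C4", "C3", "FP2", "F3", "C4"),
    stringsAsFactors = FALSE
  )
  templates <- lapply(seq_len(nrow(defs)), function(i) {
    ce <- defs$center[i]
    if (!ce %in% montage$channel) ce <- montage$channel[1]
    cx <- montage$x[montage$channel == ce]
    cy <- montage$y[montage$channel == ce]
    w <- exp(-((montage$x - cx)^2 + (montage$y - cy)^2) / (2 * topoSigma^2))
    names(w) <- montage$channel
    list(name = defs$name[i],
         polarity = componentPolarity(defs$name[i]),
         latencyMean = defs$latencyMean[i],
         latencyJitterSd = defs$latencyJitterSd[i],
         width = defs$width[i],
         baseAmplitude = defs$baseAmplitude[i],
         levelGain = levelGain,
         topography = w)
  })
  names(templates) <- defs$name
  validateTemplates(templates)
  templates
}

validateTemplates <- function(templates) {
  wins <- componentWindows()
  for (tp in templates) {
    pol <- componentPolarity(tp$name)
    if (tp$polarity != pol)
      stop(tp$name, ": polarity must be ", pol)
    w <- wins[[tp$name]]
    if (is.null(w)) stop("unknown component: ", tp$name)
    if (tp$latencyMean < w[1] || tp$latencyMean > w[2])
      stop(tp$name, ": latencyMean ", tp$latencyMean,
           " outside search window [", w[1], ",", w[2], "]")
    if (is.unsorted(tp$levelGain))
      stop(tp$name, ": levelGain must be non-decreasing over L1..L5")
    if (any(tp$topography < 0 | tp$topography > 1))
      stop(tp$name, ": topography weights must lie in [0,1]")
  }
  invisible(TRUE)
}

#' Group effect specification for the synthetic cohort
#'
#' Encodes how the ASD-like group differs from the TD-like group:
#' \code{amplitudeDelta} is an additive change (microvolts) to component
#' *magnitude* at specific (electrode, component) sites — negative values mean
#' a reduced response in the ASD-like group; \code{dispersionFactor} multiplies
#' the per-trial latency jitter SD (temporally more dispersed responses);
#' \code{ageSlope} is a linear age effect (microvolts/year on component
#' magnitude, applied to both groups around the cohort mean age).
#'
#' The default plants -10 microvolt magnitude reductions at P200/FP2, N200/F3
#' and P300/C4 and a 1.5x latency dispersion in the ASD-like group.
#'
#' @param amplitudeDelta named numeric vector, names "ELECTRODE.COMPONENT".
#' @param dispersionFactor latency-jitter multiplier for the ASD-like group
#'   (must be >= 1).
#' @param ageSlope microvolts per year.
#' @return list of class \code{GroupEffectSpec}.
#' @export
groupEffectSpec <- function(amplitudeDelta = c(FP2.P200 = -10,
                                               F3.N200 = -10,
                                               C4.P300 = -10),
                            dispersionFactor = 1.5,
                            ageSlope = -0.29) {
  if (dispersionFactor < 1)
    stop("dispersionFactor must be >= 1")
  structure(list(amplitudeDelta = amplitudeDelta,
                 dispersionFactor = dispersionFactor,
                 ageSlope = ageSlope),
            class = "GroupEffectSpec")
}

#' Cohort specification for the synthetic generator
#'
#' Defines the acquisition the generator emulates: two cohorts of
#' \code{nPerGroup} children aged 1-5 years, 5 stimulus levels presented in
#' seeded random order with \code{trialsPerLevel} repeats each, 1 s stimulation
#' followed by 0.5 s rest (1.5 s stimulus-onset asynchrony), continuous EEG at
#' 1000 Hz on a 32-channel 10/20 montage.
#'
#' @param nPerGroup subjects per group (default 36).
#' @param trialsPerLevel repeats of each of the 5 levels (default 80).
#' @param samplingRate Hz (default 1000).
#' @param montage montage data.frame.
#' @param ageRange years, uniform sampling range (default 1.17-5.17).
#' @param noiseSd microvolts total background-noise SD per sample (default 15).
#' @param pinkFraction fraction of noise variance given to 1/f-shaped noise
#'   (default 0.5; remainder is white).
#' @param spatialCorr logical; spatially correlate noise across electrodes via
#'   a montage-distance Gaussian kernel (default TRUE).
#' @param subjectAmpSd microvolts; SD of the per-subject random shift of
#'   component magnitude (between-subject variability, default 1.75).
#' @param blinkRate stereotyped frontal blink artifacts per minute (default 1).
#' @param blinkAmplitude microvolts peak blink amplitude (default 250).
#' @param seed integer; identical seed gives a bit-identical dataset.
#' @return list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nPerGroup = 36, trialsPerLevel = 80,
                       samplingRate = 1000, montage = standardMontage(),
                       ageRange = c(1.17, 5.17), noiseSd = 15,
                       pinkFraction = 0.5, spatialCorr = TRUE,
                       subjectAmpSd = 1.75, blinkRate = 1,
                       blinkAmplitude = 250, seed = 1L) {
  stopifnot(nPerGroup >= 1, trialsPerLevel >= 1, samplingRate > 0,
            length(ageRange) == 2, ageRange[1] <= ageRange[2],
            noiseSd >= 0, pinkFraction >= 0, pinkFraction <= 1,
            subjectAmpSd >= 0, blinkRate >= 0)
  structure(list(nPerGroup = as.integer(nPerGroup),
                 levels = 5L,
                 trialsPerLevel = as.integer(trialsPerLevel),
                 samplingRate = samplingRate,
                 montage = montage,
                 ageRange = ageRange,
                 noiseSd = noiseSd,
                 pinkFraction = pinkFraction,
                 spatialCorr = spatialCorr,
                 subjectAmpSd = subjectAmpSd,
                 blinkRate = blinkRate,
                 blinkAmplitude = blinkAmplitude,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Seeded random presentation order: 5 levels x trialsPerLevel repeats,
# permuted, 1.5 s onset asynchrony after a 2 s lead-in.
makeEventSchedule <- function(spec, subjectSeed) {
  nEv <- spec$levels * spec$trialsPerLevel
  lv <- rep(LEVEL_LABELS[seq_len(spec$levels)], each = spec$trialsPerLevel)
  ord <- withSeed(deriveSeed(subjectSeed, "events"), sample.int(nEv))
  onset <- round(2 * spec$samplingRate) + (seq_len(nEv) - 1L) * round(1.5 * spec$samplingRate) + 1L
  data.frame(onset_sample = as.integer(onset), level = lv[ord],
             stringsAsFactors = FALSE)
}

# Subject-level draws (age, amplitude random effect), deterministic per
# (cohort seed, group, subject index).
subjectDraws <- function(spec, group, subjectIndex) {
  s <- deriveSeed(spec$seed, paste0("subject:", group, ":", subjectIndex))
  withSeed(s, {
    list(age = stats::runif(1, spec$ageRange[1], spec$ageRange[2]),
         ampShift = stats::rnorm(1, 0, spec$subjectAmpSd),
         seed = s)
  })
}

# Raised-cosine bump sampled at 1/rate around a given latency.
hanningKernel <- function(latencyMs, widthMs, rate) {
  half <- widthMs / 2
  t0 <- ceiling((latencyMs - half) * rate / 1000)
  t1 <- floor((latencyMs + half) * rate / 1000)
  tMs <- (t0:t1) * 1000 / rate
  list(offsets = t0:t1,
       values = 0.5 * (1 + cos(2 * pi * (tMs - latencyMs) / widthMs)))
}

# 1/f-shaped ("pink") noise by IIR spectral shaping of white noise
# (pole-zero cascade approximating a -10 dB/decade magnitude slope over the
# EEG band; scale-free, so usable at any sampling rate), unit variance.
pinkNoiseMatrix <- function(nCh, n, rate) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  burn <- min(n, 2000L)
  w <- matrix(stats::rnorm((n + burn) * nCh), n + burn, nCh)
  v <- stats::filter(w, b, method = "convolution", sides = 1)
  v[seq_len(length(b) - 1L), ] <- 0
  x <- stats::filter(v, -a[-1], method = "recursive")[
    (burn + 1L):(burn + n), , drop = FALSE]
  t(x) / apply(x, 2, stats::sd)
}

#' Generate one subject's continuous recording
#'
#' Synthesizes a continuous multi-channel EEG recording: per-event evoked
#' responses built from the component templates (scaled by stimulus-level gain,
#' the subject's random amplitude shift, a linear age effect and — for the
#' ASD-like group — the planted group deltas and latency dispersion), plus
#' spatially correlated white + 1/f background noise and optional stereotyped
#' frontal blink artifacts.
#'
#' @param spec a [cohortSpec()].
#' @param templates component templates from [componentTemplates()].
#' @param effects a [groupEffectSpec()].
#' @param subjectIndex 1-based index within the group.
#' @param group \code{"ASD"} or \code{"TD"}.
#' @return an \linkS4class{EEGRecording}.
#' @examples
#' sp <- cohortSpec(nPerGroup = 1, trialsPerLevel = 2, noiseSd = 0,
#'                  blinkRate = 0, seed = 7)
#' rec <- generateRecording(sp, componentTemplates(), groupEffectSpec(), 1, "TD")
#' rec
#' @export
generateRecording <- function(spec, templates = componentTemplates(spec$montage),
                              effects = groupEffectSpec(),
                              subjectIndex = 1L, group = c("TD", "ASD")) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "CohortSpec"))
  if (subjectIndex > spec$nPerGroup)
    stop("subjectIndex exceeds nPerGroup")
  validateTemplates(templates)
  wins <- componentWindows()
  for (tp in templates) {
    if (tp$latencyMean + tp$width / 2 > 1000 || tp$latencyMean - tp$width / 2 < -500)
      stop(tp$name, ": template latency/width falls outside the -500..1000 ms epoch window")
  }
  chan <- spec$montage$channel
  nCh <- length(chan)
  rate <- spec$samplingRate
  draws <- subjectDraws(spec, group, subjectIndex)
  events <- makeEventSchedule(spec, draws$seed)
  nSamp <- max(events$onset_sample) + round(1.5 * rate)
  ageCenter <- mean(spec$ageRange)
  dispersion <- if (group == "ASD") effects$dispersionFactor else 1

  data <- withSeed(deriveSeed(draws$seed, "noise"), {
    if (spec$noiseSd > 0) {
      x <- sqrt(1 - spec$pinkFraction) *
        matrix(stats::rnorm(nCh * nSamp), nCh, nSamp)
      if (spec$pinkFraction > 0)
        x <- x + sqrt(spec$pinkFraction) * pinkNoiseMatrix(nCh, nSamp, rate)
      if (spec$spatialCorr && nCh > 1) {
        d <- montageDistances(spec$montage)
        K <- exp(-(d / 0.5)^2) + diag(1e-4, nCh)
        x <- t(chol(K / mean(diag(K)))) %*% x
        x <- x / mean(apply(x[, seq_len(min(nSamp, 5000)), drop = FALSE], 1, stats::sd))
      }
      spec$noiseSd * x
    } else matrix(0, nCh, nSamp)
  })

  # evoked responses
  deltaMat <- matrix(0, nCh, length(templates),
                     dimnames = list(chan, names(templates)))
  if (group == "ASD" && length(effects$amplitudeDelta)) {
    for (nm in names(effects$amplitudeDelta)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        stop("amplitudeDelta names must be ELECTRODE.COMPONENT: ", nm)
      if (parts[1] %in% chan && parts[2] %in% names(templates))
        deltaMat[parts[1], parts[2]] <- effects$amplitudeDelta[[nm]]
    }
  }
  withSeed(deriveSeed(draws$seed, "evoked"), {
    levIdx <- match(events$level, LEVEL_LABELS)
    for (tp in templates) {
      jit <- stats::rnorm(nrow(events), 0, tp$latencyJitterSd * dispersion)
      # per-electrode signed amplitude for each event
      mag <- tp$baseAmplitude * tp$levelGain[levIdx] + draws$ampShift +
        effects$ageSlope * (draws$age - ageCenter)
      for (i in seq_len(nrow(events))) {
        k <- hanningKernel(tp$latencyMean + jit[i], tp$width, rate)
        ampVec <- tp$polarity * (mag[i] * tp$topography + deltaMat[, tp$name])
        idx <- events$onset_sample[i] + k$offsets
        ok <- idx >= 1 & idx <= nSamp
        data[, idx[ok]] <- data[, idx[ok]] + outer(ampVec, k$values[ok])
      }
    }
    # blink artifacts: frontal-weighted 400 ms bumps at Poisson times
    if (spec$blinkRate > 0) {
      nBlinks <- stats::rpois(1, spec$blinkRate * nSamp / rate / 60)
      if (nBlinks > 0) {
        bw <- exp(-((spec$montage$x)^2 + (spec$montage$y - 1)^2) / (2 * 0.35^2))
        onsets <- sort(stats::runif(nBlinks, 0, nSamp / rate - 0.5))
        for (o in onsets) {
          k <- hanningKernel(o * 1000 + 200, 400, rate)
          idx <- k$offsets
          ok <- idx >= 1 & idx <= nSamp
          data[, idx[ok]] <- data[, idx[ok]] +
            outer(spec$blinkAmplitude * bw, k$values[ok])
        }
      }
    }
    data
  }) -> data

  rownames(data) <- chan
  new("EEGRecording", data = data, rate = rate, channelNames = chan,
      events = events,
      subjectMeta = list(id = sprintf("%s%02d", group, subjectIndex),
                         group = group, age = draws$age))
}

#' Simulate a full two-group cohort
#'
#' @param spec a [cohortSpec()].
#' @param templates component templates.
#' @param effects a [groupEffectSpec()].
#' @param groups which groups to simulate.
#' @return list with \code{recordings} (list of \linkS4class{EEGRecording})
#'   and \code{manifest} (data.frame: subject, group, age, n_events).
#' @export
simulateCohort <- function(spec, templates = componentTemplates(spec$montage),
                           effects = groupEffectSpec(),
                           groups = c("ASD", "TD")) {
  recs <- list()
  for (g in groups) {
    for (i in seq_len(spec$nPerGroup)) {
      r <- generateRecording(spec, templates, effects, i, g)
      recs[[r@subjectMeta$id]] <- r
    }
  }
  manifest <- do.call(rbind, lapply(recs, function(r) {
    data.frame(subject = r@subjectMeta$id, group = r@subjectMeta$group,
               age = r@subjectMeta$age, n_events = nrow(r@events),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest)
}

#' Event-count bookkeeping for a cohort specification
#'
#' Number of stimulus events the generator schedules per group
#' (levels x trials per level x subjects), verified against the per-subject
#' event schedules.
#'
#' @param spec a [cohortSpec()].
#' @return integer event count per group.
#' @export
cohortEventsPerGroup <- function(spec) {
  perSubject <- vapply(seq_len(spec$nPerGroup), function(i) {
    nrow(makeEventSchedule(spec, subjectDraws(spec, "TD", i)$seed))
  }, integer(1))
  sum(perSubject)
}
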