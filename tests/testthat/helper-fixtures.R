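# Shared fixtures: small montages, deterministic template sets and in-code
# constructors for recordings/epochs/evokeds used across the suite.

mont3 <- function() standardMontage(c("FP2", "F3", "C4"))
mont8 <- function() standardMontage(c("FP1", "FP2", "F3", "F4",
                                      "C3", "C4", "P3", "P4"))

# templates with zero latency jitter (deterministic evoked shapes)
rigidTemplates <- function(montage = mont3(), ...) {
  tp <- componentTemplates(montage, ...)
  for (n in names(tp)) tp[[n]]$latencyJitterSd <- 0
  tp
}

# noise-free, artifact-free cohort spec for identity checks
quietSpec <- function(montage = mont3(), nPerGroup = 1, trialsPerLevel = 2,
                      seed = 7, ...) {
  cohortSpec(nPerGroup = nPerGroup, trialsPerLevel = trialsPerLevel,
             montage = montage, noiseSd = 0, blinkRate = 0,
             subjectAmpSd = 0, seed = seed, ...)
}

nullEffects <- function() {
  groupEffectSpec(amplitudeDelta = numeric(0), dispersionFactor = 1,
                  ageSlope = 0)
}

# a bare recording around a given signal matrix
makeRecording <- function(data, rate = 1000,
                          channels = paste0("ch", seq_len(nrow(data))),
                          events = data.frame(onset_sample = integer(),
                                              level = character()),
                          meta = list(id = "S1", group = "TD", age = 3)) {
  rownames(data) <- channels
  new("EEGRecording", data = data, rate = rate, channelNames = channels,
      events = events, subjectMeta = meta)
}

# a bare EpochSet
makeEpochs <- function(data, timeMs = seq(-500, length.out = dim(data)[3]),
                       levels = rep("L1", dim(data)[1]),
                       channels = paste0("ch", seq_len(dim(data)[2])),
                       meta = list(id = "S1", group = "TD", age = 3)) {
  new("EpochSet", data = data, timeMs = timeMs, levels = levels,
      keptMask = rep(TRUE, dim(data)[1]), channelNames = channels,
      interpolatedChannels = character(), subjectMeta = meta,
      log = character())
}

# a bare Evoked holding one waveform per channel
makeEvoked <- function(data, timeMs = seq(0, length.out = ncol(data)),
                       level = "L1",
                       channels = paste0("ch", seq_len(nrow(data))),
                       meta = list(id = "S1", group = "TD", age = 3)) {
  rownames(data) <- channels
  new("Evoked", data = data, timeMs = timeMs, level = level,
      nTrials = 1L, channelNames = channels, subjectMeta = meta)
}

# five per-level evokeds whose value at every time point is `levelValues[l]`
constantLevelEvokeds <- function(levelValues, nTime = 500, channel = "FP2") {
  stopifnot(length(levelValues) == 5)
  out <- list()
  for (l in 1:5) {
    out[[paste0("L", l)]] <- makeEvoked(
      matrix(levelValues[l], 1, nTime), timeMs = seq(0, nTime - 1),
      level = paste0("L", l), channels = channel)
  }
  out
}

# evoked set for one simulated subject, preprocessed with default parameters
subjectEvokedQuick <- function(spec, templates, effects, i, group,
                               detectBad = FALSE) {
  averageEvoked(preprocessRecording(
    generateRecording(spec, templates, effects, i, group),
    detectBad = detectBad, montage = spec$montage))
}

# component table for a planted-delta cohort at the three analysis sites
simulateComponentTable <- function(seed, nPerGroup = 36, trialsPerLevel = 20,
                                   montage = mont3(),
                                   effects = groupEffectSpec()) {
  sp <- cohortSpec(nPerGroup = nPerGroup, trialsPerLevel = trialsPerLevel,
                   montage = montage, seed = seed)
  tp <- componentTemplates(montage)
  evs <- list()
  for (g in c("ASD", "TD")) {
    for (i in seq_len(nPerGroup)) {
      ev <- subjectEvokedQuick(sp, tp, effects, i, g)
      evs[[ev[[1]]@subjectMeta$id]] <- ev
    }
  }
  buildComponentTable(evs, electrodes = montage$channel)
}

# synthetic subject-level component table drawn directly from a normal model
# (for statistics tests that do not need the EEG chain)
normalComponentTable <- function(n = 12, delta = 0, sd = 3, seed = 1,
                                 electrode = "F3", component = "N200") {
  set.seed(seed)
  rows <- expand.grid(subject = sprintf("S%02d", 1:(2 * n)),
                      level = paste0("L", 1:5), stringsAsFactors = FALSE)
  rows$group <- ifelse(as.integer(sub("S", "", rows$subject)) <= n,
                       "ASD", "TD")
  rows$age <- runif(2 * n, 1.2, 5.2)[as.integer(sub("S", "", rows$subject))]
  rows$electrode <- electrode
  rows$component <- component
  rows$amplitude_uV <- rnorm(nrow(rows), 0, sd) +
    ifelse(rows$group == "ASD", delta, 0)
  rows$peak_latency_ms <- 275
  rows[, c("subject", "group", "age", "electrode", "component", "level",
           "amplitude_uV", "peak_latency_ms")]
}
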