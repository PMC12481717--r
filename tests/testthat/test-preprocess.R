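test_that("the band-pass matches the squared Butterworth magnitude response", {
  rate <- 1000; n <- 20000; tt <- (0:(n - 1)) / rate
  mid <- 5001:15000
  # independent oracle: |H(f)|^2 of the high-pass/low-pass Butterworth cascade
  gainSq <- function(f, low = 0.01, high = 12, order = 3) {
    (1 / (1 + (f / high)^(2 * order))) *
      ((f / low)^(2 * order) / (1 + (f / low)^(2 * order)))
  }
  for (f0 in c(5, 8)) {
    x <- sin(2 * pi * f0 * tt)
    y <- signalData(bandpassFilter(makeRecording(matrix(x, 1))))[1, mid]
    expect_equal(sd(y) / sd(x[mid]), gainSq(f0), tolerance = 0.01)
  }
  # 50 Hz stop band: output RMS below 1% of input RMS
  x <- sin(2 * pi * 50 * tt)
  y <- signalData(bandpassFilter(makeRecording(matrix(x, 1))))[1, mid]
  expect_lt(sd(y) / sd(x[mid]), 0.01)
  # 5 Hz passband amplitude preserved within 5%
  x <- sin(2 * pi * 5 * tt)
  y <- signalData(bandpassFilter(makeRecording(matrix(x, 1))))[1, mid]
  expect_gt(sd(y) / sd(x[mid]), 0.95)
  # all-zero in, all-zero out; non-finite and bad edges rejected
  expect_equal(max(abs(signalData(bandpassFilter(
    makeRecording(matrix(0, 2, n)))))), 0)
  expect_error(bandpassFilter(makeRecording(matrix(NA_real_, 1, 100))),
               "non-finite")
  expect_error(bandpassFilter(makeRecording(matrix(0, 1, 100)), high = 600),
               "Nyquist")
})

test_that("bad-channel detection recovers planted outliers and stays quiet under the null", {
  m8 <- mont8()
  sp <- cohortSpec(nPerGroup = 1, trialsPerLevel = 4, montage = m8, seed = 11)
  rec <- generateRecording(sp, componentTemplates(m8), groupEffectSpec(),
                           1, "TD")
  # 50x amplified noise on one channel
  set.seed(1)
  bad <- rec
  bad@data["F4", ] <- rnorm(ncol(bad@data), 0, 50 * sd(bad@data["F4", ]))
  expect_identical(detectBadChannels(bad), "F4")
  # flat channel flagged on the low-power side
  flat <- rec
  flat@data["P3", ] <- 0
  expect_true("P3" %in% detectBadChannels(flat))
  # homogeneous noise-only cohort: empty in at least 95% of 20 seeds
  m32 <- standardMontage()
  tp0 <- componentTemplates(m32)
  for (nm in names(tp0)) tp0[[nm]]$baseAmplitude <- 0
  empty <- vapply(1:20, function(s) {
    spn <- cohortSpec(nPerGroup = 1, trialsPerLevel = 2, montage = m32,
                      blinkRate = 0, seed = s)
    length(detectBadChannels(generateRecording(spn, tp0, nullEffects(),
                                               1, "TD"))) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
  expect_error(detectBadChannels(makeRecording(matrix(rnorm(700), 7, 100))),
               "8 channels")
})

test_that("interpolation reconstructs from nearest good neighbours", {
  m8 <- mont8()
  # constructed consistency: bad channel equals the inverse-distance mean of
  # its 4 nearest neighbours -> exact reconstruction
  set.seed(2)
  arr <- array(rnorm(4 * 8 * 100), dim = c(4, 8, 100))
  ep <- makeEpochs(arr, channels = m8$channel)
  d <- tactileERP:::montageDistances(m8)
  nb <- names(sort(d["C3", setdiff(m8$channel, "C3")]))[1:4]
  w <- 1 / d["C3", nb]; w <- w / sum(w)
  truth <- 0
  for (j in 1:4) truth <- truth + w[j] * arr[, match(nb[j], m8$channel), ]
  ep@data[, match("C3", m8$channel), ] <- truth
  fixed <- interpolateChannels(ep, "C3", m8)
  expect_equal(signalData(fixed)[, match("C3", m8$channel), ], truth,
               tolerance = 1e-10)
  expect_identical(fixed@interpolatedChannels, "C3")
  # no bad channels: identity
  expect_identical(signalData(interpolateChannels(ep, character(), m8)),
                   signalData(ep))
  # planted corrupted channel in a noise-free cohort: reconstruction
  # correlates > 0.9 with the clean ground truth (full montage, so the
  # nearest neighbours carry similar component mixtures)
  m32 <- standardMontage()
  sp <- quietSpec(m32, trialsPerLevel = 2, seed = 9)
  rec <- generateRecording(sp, rigidTemplates(m32), nullEffects(), 1, "TD")
  clean <- epochRecording(rec)
  corrupt <- rec
  set.seed(3)
  corrupt@data["C4", ] <- rnorm(ncol(corrupt@data), 0, 200)
  repaired <- interpolateChannels(epochRecording(corrupt), "C4", m32)
  ci <- match("C4", m32$channel)
  expect_gt(cor(as.vector(signalData(repaired)[, ci, ]),
                as.vector(signalData(clean)[, ci, ])), 0.9)
  # degenerate requests fail
  expect_error(interpolateChannels(ep, m8$channel, m8), "good channels")
})

test_that("epoching is aligned, bookkeeps trials and rejects edge events", {
  rate <- 1000
  ev <- data.frame(onset_sample = c(1000L, 3000L), level = c("L1", "L2"))
  x <- matrix(0, 2, 5000)
  x[, 1000] <- 7   # impulse at the first event onset
  rec <- makeRecording(x, events = ev)
  ep <- epochRecording(rec)
  expect_equal(dim(signalData(ep)), c(2, 2, 1500))
  expect_equal(timeMs(ep)[1], -500)
  expect_equal(timeMs(ep)[1500], 999)   # half-open window: +1000 excluded
  expect_equal(signalData(ep)[1, 1, 501], 7)  # onset lands at index 501 (0 ms)
  expect_equal(trialLevels(ep), c("L1", "L2"))
  # an event too close to the edge is named in the error
  bad <- makeRecording(matrix(0, 2, 5000),
                       events = data.frame(onset_sample = c(300L, 3000L),
                                           level = c("L1", "L1")))
  expect_error(epochRecording(bad), "1")
})

test_that("baseline correction forces zero prestimulus mean and is linear", {
  set.seed(4)
  arr <- array(rnorm(3 * 2 * 1500), dim = c(3, 2, 1500))
  ep <- makeEpochs(arr)
  out <- baselineCorrect(ep)
  bl <- apply(signalData(out)[, , timeMs(out) < 0, drop = FALSE],
              c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # idempotence on already-centred data
  out2 <- baselineCorrect(out)
  expect_equal(signalData(out2), signalData(out), tolerance = 1e-12)
  # +7.3 uV on one channel shifts that channel by -7.3
  shifted <- ep
  shifted@data[, 2, ] <- shifted@data[, 2, ] + 7.3
  both <- baselineCorrect(shifted)
  expect_equal(signalData(both)[, 2, ], signalData(out)[, 2, ],
               tolerance = 1e-12)
  expect_error(baselineCorrect(ep, c(0, 0)), "window")
})

test_that("peak-to-peak rejection flags planted blinks, is monotone and reversible", {
  set.seed(5)
  arr <- array(rnorm(20 * 3 * 1500, 0, 5), dim = c(20, 3, 1500))
  blinky <- c(3, 7, 11, 15, 19)
  for (i in blinky)
    arr[i, 1, 700:800] <- arr[i, 1, 700:800] + 500
  ep <- makeEpochs(arr, levels = rep(paste0("L", 1:5), 4))
  out <- rejectArtifactTrials(ep, 200)
  expect_identical(which(!keptMask(out)), as.integer(blinky))
  expect_identical(signalData(out), signalData(ep))   # data untouched
  # +Inf threshold keeps everything
  expect_true(all(keptMask(rejectArtifactTrials(ep, Inf))))
  # monotone: a lower threshold never rescues a rejected trial
  thresholds <- c(400, 200, 100, 20)
  masks <- lapply(thresholds, function(th)
    keptMask(suppressWarnings(rejectArtifactTrials(ep, th))))
  for (k in seq_along(masks)[-1])
    expect_true(all(masks[[k]] <= masks[[k - 1]]))
  # rejecting most trials warns rather than errors
  expect_warning(rejectArtifactTrials(ep, 10), "reject")
  # clean zero-noise epochs: nothing rejected
  quiet <- makeEpochs(array(0, dim = c(4, 2, 100)),
                      levels = rep("L1", 4))
  expect_true(all(keptMask(rejectArtifactTrials(quiet, 200))))
})

test_that("re-running the pipeline on its own output changes component peaks only mildly", {
  m <- mont3()
  tp <- rigidTemplates(m)
  sp <- quietSpec(m, trialsPerLevel = 2, seed = 5)
  rec <- generateRecording(sp, tp, nullEffects(), 1, "TD")
  ev1 <- averageEvoked(preprocessRecording(rec, detectBad = FALSE))
  refiltered <- initialize(rec, data = signalData(bandpassFilter(rec)))
  ev2 <- averageEvoked(preprocessRecording(refiltered, detectBad = FALSE))
  sites <- list(c("FP2", "P200"), c("F3", "N200"), c("C4", "P300"))
  for (s in sites) {
    a1 <- peakWindowAmplitude(ev1$L5, s[1], s[2])$amplitude
    a2 <- peakWindowAmplitude(ev2$L5, s[1], s[2])$amplitude
    expect_lt(abs(a2 - a1) / abs(a1), 0.06)
  }
})
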