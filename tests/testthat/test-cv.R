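test_that("sliding CV reproduces hand-computed values and basic identities", {
  # constant per-level values 1..5 uV: CV = sd(1:5)/mean(1:5) at every window
  ev <- constantLevelEvokeds(1:5)
  s <- slidingCV(ev, "FP2")
  handCV <- sqrt(sum((1:5 - 3)^2) / 4) / 3   # sample SD over |mean|
  expect_equal(unique(round(s@cv, 10)), round(handCV, 10))
  expect_equal(handCV, 0.527, tolerance = 1e-3)
  # default span/width/step: floor((400 - 10)/1) + 1 = 391 windows
  expect_length(s@cv, 391)
  expect_false(any(s@flagged))
  # five identical evokeds: CV identically zero
  s0 <- slidingCV(constantLevelEvokeds(rep(2, 5)), "FP2")
  expect_true(all(s0@cv == 0))
  # scale invariance: multiplying all five evokeds by 3 leaves CV unchanged
  ev3 <- lapply(ev, function(e) initialize(e, data = e@data * 3))
  s3 <- slidingCV(ev3, "FP2")
  expect_equal(s3@cv, s@cv, tolerance = 1e-12)
  # NOT invariant to a common additive offset
  evOff <- lapply(ev, function(e) initialize(e, data = e@data + 10))
  sOff <- slidingCV(evOff, "FP2")
  expect_false(isTRUE(all.equal(sOff@cv, s@cv)))
  expect_error(slidingCV(ev[1:4], "FP2"), "5")
  expect_error(slidingCV(ev, "FP2", span = c(0, 900)), "span")
})

test_that("the window-count formula holds across width/step settings", {
  ev <- constantLevelEvokeds(1:5)
  for (w in c(10, 20, 50)) {
    for (st in c(1, 5, w)) {
      s <- slidingCV(ev, "FP2", windowWidth = w, step = st)
      expect_length(s@cv, floor((400 - w) / st) + 1)
    }
  }
})

test_that("non-overlapping windows on piecewise-constant input equal per-block pooled CV", {
  # 40 blocks of 10 ms; each level constant within a block
  set.seed(10)
  vals <- matrix(abs(rnorm(5 * 40, 10, 2)), 5, 40)
  ev <- list()
  for (l in 1:5) {
    x <- rep(vals[l, ], each = 10)
    ev[[paste0("L", l)]] <- makeEvoked(matrix(x, 1, 400), timeMs = 0:399,
                                       level = paste0("L", l),
                                       channels = "FP2")
  }
  s <- slidingCV(ev, "FP2", windowWidth = 10, step = 10)
  blockCV <- apply(vals, 2, function(v) sd(v) / abs(mean(v)))
  expect_length(s@cv, 40)
  expect_equal(s@cv, blockCV, tolerance = 1e-12)
})

test_that("near-zero window means are epsilon-guarded and excluded from totals", {
  ev <- constantLevelEvokeds(c(-2, -1, 0, 1, 2))   # across-level mean 0
  s <- slidingCV(ev, "FP2")
  expect_true(all(s@flagged))
  expect_true(all(is.finite(s@cv)))
  expect_equal(s@cv[1], sd(c(-2, -1, 0, 1, 2)) / 0.1)
  # the pooled variant remains available behind its flag
  sp <- slidingCV(constantLevelEvokeds(1:5), "FP2", pooled = TRUE)
  expect_equal(sp@cv[1], sd(rep(1:5, each = 10)) / 3, tolerance = 1e-12)
  # totalCV falls back to all windows only when everything is flagged
  mixed <- constantLevelEvokeds(1:5)
  sm <- slidingCV(mixed, "FP2")
  expect_equal(totalCV(sm), mean(sm@cv))
})

test_that("total CV averages the series and responds to latency dispersion", {
  ev <- constantLevelEvokeds(1:5)
  s <- slidingCV(ev, "FP2")
  expect_equal(totalCV(s), s@cv[1])     # constant series: total = the value
  expect_equal(totalCV(s, span = c(100, 200)),
               mean(s@cv[s@windowCentersMs >= 100 & s@windowCentersMs <= 200]))
  s0 <- slidingCV(constantLevelEvokeds(rep(4, 5)), "FP2")
  expect_equal(totalCV(s0), 0)
  expect_error(totalCV(s, span = c(800, 900)), "span")
  # generator ground truth: a latency-dispersed group shows a higher total
  # CV at the prefrontal electrode in most seeded runs
  m <- mont3()
  tp <- componentTemplates(m)
  for (nm in names(tp)) tp[[nm]]$latencyJitterSd <- 3 * tp[[nm]]$latencyJitterSd
  higher <- vapply(1:12, function(s) {
    sp <- cohortSpec(nPerGroup = 1, trialsPerLevel = 5, montage = m,
                     noiseSd = 5, pinkFraction = 0, spatialCorr = FALSE,
                     blinkRate = 0, subjectAmpSd = 0, seed = s)
    effDisp <- groupEffectSpec(amplitudeDelta = numeric(0),
                               dispersionFactor = 2.5, ageSlope = 0)
    evT <- subjectEvokedQuick(sp, tp, effDisp, 1, "TD")
    evA <- subjectEvokedQuick(sp, tp, effDisp, 1, "ASD")
    totalCV(slidingCV(evA[paste0("L", 1:5)], "FP2")) >
      totalCV(slidingCV(evT[paste0("L", 1:5)], "FP2"))
  }, logical(1))
  expect_gte(mean(higher), 0.75)
})

test_that("group CV comparisons calibrate under the null and find planted dispersion", {
  mkTotals <- function(seed, bump = 0) {
    set.seed(seed)
    el <- c("FP2", "F3", "C4")
    d <- expand.grid(subject = sprintf("S%02d", 1:24), electrode = el,
                     stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= 12, "ASD", "TD")
    d$age <- runif(nrow(d), 1, 5)
    d$total_cv <- abs(rnorm(nrow(d), 1, 0.2)) +
      ifelse(d$group == "ASD" & d$electrode == "FP2", bump, 0)
    d
  }
  # identical groups: the family-wise false-positive rate over the three
  # electrodes stays compatible with the nominal 5% level
  nullOk <- vapply(1:100, function(s)
    all(compareCVGroups(mkTotals(s))$p_adjusted > 0.05), logical(1))
  expect_gte(mean(nullOk), 0.90)
  expect_gt(stats::binom.test(sum(!nullOk), length(nullOk),
                              0.05)$p.value, 0.01)
  # planted dispersion at FP2: minimal adjusted p lands there
  best <- vapply(1:25, function(s) {
    r <- compareCVGroups(mkTotals(s + 900, bump = 0.6))
    r$electrode[which.min(r$p_adjusted)] == "FP2"
  }, logical(1))
  expect_gte(mean(best), 0.8)
  # permuting the group labels destroys the significance
  perm <- vapply(1:25, function(s) {
    d <- mkTotals(s + 2000, bump = 0.6)
    set.seed(s)
    d$group <- sample(d$group)
    min(compareCVGroups(d)$p_adjusted)
  }, numeric(1))
  expect_gt(median(perm), 0.2)
  # paired variant requires equal n and runs
  r <- compareCVGroups(mkTotals(1), paired = TRUE)
  expect_true(all(c("t", "p_adjusted") %in% names(r)))
  expect_error(compareCVGroups(mkTotals(1)[1:9, ]), "n >= 3")
})
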