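test_that("Type III ANCOVA matches the nested least-squares oracle", {
  for (seed in 1:4) {
    d <- normalComponentTable(n = 6, delta = 3, sd = 2, seed = seed)
    # unbalance it: drop a random row block to exercise Type III
    set.seed(seed + 100)
    d <- d[-sample(nrow(d), 4), ]
    fit <- ancovaComponent(d, "F3", "N200", marginalMeans = FALSE)
    orc <- ancovaOracle(d)
    for (eff in names(orc$F)) {
      expect_equal(fit$results$F[fit$results$effect == eff],
                   unname(orc$F[eff]), tolerance = 1e-8, info = eff)
    }
    expect_equal(unique(fit$results$df2), orc$dfe)
  }
})

test_that("Type III and sequential sums of squares coincide on balanced designs", {
  d <- normalComponentTable(n = 8, delta = 2, sd = 1.5, seed = 9)
  d$age <- 3   # constant age would break rank; use a balanced covariate trick
  d$age <- rep(seq(1.5, 5, length.out = 16), times = 5)
  fit <- ancovaComponent(d, "F3", "N200", covariate = FALSE,
                         marginalMeans = FALSE)
  a1 <- anova(stats::lm(amplitude_uV ~ group * level, data = d))
  expect_equal(fit$results$F[fit$results$effect == "Group"],
               a1$`F value`[1], tolerance = 1e-8)
  expect_equal(fit$results$F[fit$results$effect == "Level"],
               a1$`F value`[2], tolerance = 1e-8)
  expect_equal(fit$results$F[fit$results$effect == "Group:Level"],
               a1$`F value`[3], tolerance = 1e-8)
})

test_that("the group-effect p-value is uniform under the null", {
  ps <- vapply(1:200, function(s) {
    d <- normalComponentTable(n = 8, delta = 0, sd = 2, seed = s)
    fit <- ancovaComponent(d, "F3", "N200", marginalMeans = FALSE)
    fit$results$p[fit$results$effect == "Group"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("constant age drops the covariate with a warning", {
  d <- normalComponentTable(n = 5, seed = 2)
  d$age <- 3
  expect_warning(fit <- ancovaComponent(d, "F3", "N200",
                                        marginalMeans = FALSE), "covariate")
  expect_false("Age" %in% fit$results$effect)
})

test_that("LSD post-hocs use the pooled error and stay unadjusted", {
  d <- normalComponentTable(n = 10, delta = 4, sd = 2, seed = 3)
  fit <- ancovaComponent(d, "F3", "N200")
  # 2-level factor: LSD t^2 equals the omnibus F
  lsd <- lsdPosthoc(fit$fit, "group")
  expect_equal(lsd$t^2, fit$results$F[fit$results$effect == "Group"],
               tolerance = 1e-8)
  expect_identical(lsd$p, lsd$p_adjusted)
  # level factor: all 10 pairwise contrasts
  lsdL <- lsdPosthoc(fit$fit, "level")
  expect_equal(nrow(lsdL), choose(5, 2))
  # identical cell means: p essentially 1
  dEq <- normalComponentTable(n = 10, delta = 0, sd = 1, seed = 4)
  dEq$amplitude_uV <- rep(5, nrow(dEq))
  dEq$amplitude_uV <- dEq$amplitude_uV + rep(c(1e-9, -1e-9), length.out = nrow(dEq))
  fitEq <- stats::lm(amplitude_uV ~ group, data = dEq)
  lsdEq <- lsdPosthoc(fitEq, "group")
  expect_gt(min(lsdEq$p), 0.99)
  # p monotone in |mean gap| at fixed SE: construct 3 cells with ordering
  set.seed(5)
  base <- rnorm(60, 0, 1)
  d3 <- data.frame(g = rep(c("a", "b", "c"), each = 20),
                   y = base + rep(c(0, 1, 3), each = 20))
  fit3 <- stats::lm(y ~ g, data = d3)
  lsd3 <- lsdPosthoc(fit3, "g")
  gaps <- abs(lsd3$estimate)
  expect_equal(order(lsd3$p), order(-gaps))
  expect_error(lsdPosthoc(fitEq, "age"), "levels")
})

test_that("group-difference topomaps are antisymmetric and recover planted sites", {
  # identical groups: zero map
  d <- normalComponentTable(n = 6, delta = 0, sd = 0, seed = 1)
  d$amplitude_uV <- 2
  topo <- groupDifferenceTopomap(d, "N200")
  expect_true(all(abs(topo$value) < 1e-12))
  # label swap negates the map
  d2 <- normalComponentTable(n = 6, delta = 5, sd = 1, seed = 2)
  t1 <- groupDifferenceTopomap(d2, "N200")
  d2s <- d2
  d2s$group <- ifelse(d2$group == "ASD", "TD", "ASD")
  t2 <- groupDifferenceTopomap(d2s, "N200")
  expect_equal(t1$value, -t2$value)
  # planted -10 uV at C4 only: the threshold query returns exactly C4 in
  # at least 90% of 50 seeded runs
  hits <- vapply(1:50, function(s) {
    dd <- do.call(rbind, lapply(c("C4", "F3", "FP2", "Pz"), function(e) {
      x <- normalComponentTable(n = 12, delta = if (e == "C4") -10 else 0,
                                sd = 3, seed = s + 7 * match(e, c("C4", "F3", "FP2", "Pz")),
                                electrode = e, component = "P300")
      x
    }))
    # query threshold strictly below the planted magnitude so that the
    # sampling noise of the group means cannot straddle the cut
    identical(topoExceeding(groupDifferenceTopomap(dd, "P300"), 8), "C4")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(groupDifferenceTopomap(transform(d, electrode = "XX"), "N200"),
               "montage")
})

test_that("per-electrode level ANOVA calibrates under the null and flags planted gains", {
  mkTab <- function(seed, gainElectrode = NULL) {
    set.seed(seed)
    rows <- expand.grid(subject = sprintf("S%02d", 1:10),
                        level = paste0("L", 1:5),
                        electrode = c("FC6", "F3", "C4", "Pz"),
                        stringsAsFactors = FALSE)
    rows$group <- "TD"; rows$age <- 3; rows$component <- "P200"
    rows$peak_latency_ms <- 175
    gain <- ifelse(rows$electrode %in% gainElectrode,
                   3 * as.integer(sub("L", "", rows$level)), 0)
    rows$amplitude_uV <- rnorm(nrow(rows), 0, 2) + gain
    rows
  }
  # null: false-positive rate near alpha over 100 seeds x 4 electrodes
  ps <- unlist(lapply(1:100, function(s)
    levelAnovaTopomap(mkTab(s), "TD")$value))
  fpr <- mean(ps < 0.05)
  ci <- binom.test(sum(ps < 0.05), length(ps), 0.05)$conf.int
  expect_true(fpr >= 0.02 && fpr <= 0.09)
  expect_true(ci[1] <= 0.05 && ci[2] >= 0.02)
  # planted monotone gain at FC6: minimal p at FC6 in >= 90% of seeds
  best <- vapply(1:20, function(s) {
    tp <- levelAnovaTopomap(mkTab(s + 500, "FC6"), "TD")
    tp$electrode[which.min(tp$value)] == "FC6"
  }, logical(1))
  expect_gte(mean(best), 0.9)
  # n = 1 per level is degenerate
  one <- mkTab(1)
  one <- one[one$subject == "S01", ]
  expect_error(levelAnovaTopomap(one, "TD"), "residual")
})

test_that("noncentral-F power analytics reproduce the worked examples", {
  # headline effect: f = 1.71, alpha = 0.05, n = 36/group -> power > 0.99
  expect_gt(powerOneway(1.71, 0.05, 36, 2)$power, 0.99)
  # f = 0.82 with n = 9/group achieves at least 80% power
  expect_gte(powerOneway(0.82, 0.05, 9, 2)$power, 0.80)
  # null identity: f = 0 gives power exactly alpha
  expect_equal(powerOneway(0, 0.05, 20, 3)$power, 0.05, tolerance = 1e-12)
  # k = 2 agreement with the two-sample t-test power (d = 2f)
  for (f in c(0.3, 0.6, 1.0)) {
    pt <- stats::power.t.test(n = 15, delta = 2 * f, sd = 1,
                              sig.level = 0.05)$power
    expect_equal(powerOneway(f, 0.05, 15, 2)$power, pt, tolerance = 1e-3)
  }
  # solve_n inverts the power function
  n80 <- solveN(0.82, 0.05, 0.8, 2)
  expect_lte(n80, 9)
  expect_gte(powerOneway(0.82, 0.05, n80, 2)$power, 0.8)
  expect_lt(powerOneway(0.82, 0.05, n80 - 1, 2)$power, 0.8)
  expect_error(solveN(0, 0.05, 0.8, 2), "unreachable")
})

test_that("BH-FDR adjustment follows the step-up rule", {
  # hand-applied step-up on a 4-vector: p_(i) * m / i, cummin from the top
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdrAdjust(numeric(0)), numeric(0))
  set.seed(8)
  p <- runif(40)
  adj <- fdrAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))   # order-preserving
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})
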