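#' Two-factor ANCOVA with age covariate (Type III sums of squares)
#'
#' For one (electrode, component) cell of the component table, fits
#' \code{amplitude ~ group + level + group:level + age} with sum-to-zero
#' contrasts and Type III sums of squares, and returns one row per effect with
#' the F statistic, degrees of freedom, p-value and partial eta squared
#' (SS_effect / (SS_effect + SS_error)). The age regression slope (microvolts
#' per year) is reported alongside. If age is constant the covariate is
#' dropped with a warning.
#'
#' @param table component table from [buildComponentTable()].
#' @param electrode,component the cell to analyse.
#' @param covariate include the age covariate (default TRUE).
#' @param marginalMeans also compute age-adjusted marginal means via emmeans
#'   (default TRUE; skip for speed in large simulation loops).
#' @return list with \code{results} (data.frame: effect, F, df1, df2, p,
#'   eta_sq_partial, beta_age), \code{fit} (the lm object) and
#'   \code{marginalMeans} (age-adjusted group x level means from emmeans, or
#'   NULL).
#' @export
ancovaComponent <- function(table, electrode, component, covariate = TRUE,
                            marginalMeans = TRUE) {
  d <- table[table$electrode == electrode & table$component == component, ,
             drop = FALSE]
  if (!nrow(d)) stop("no rows for ", electrode, "/", component)
  if (min(base::table(d$group)) < 2) stop("need n >= 2 per group")
  d$group <- factor(d$group)
  d$level <- factor(d$level, levels = LEVEL_LABELS)
  if (covariate && stats::sd(d$age) < .Machine$double.eps^0.5) {
    warning("age covariate constant; dropped from the model")
    covariate <- FALSE
  }
  form <- if (covariate) amplitude_uV ~ group * level + age
          else amplitude_uV ~ group * level
  fit <- stats::lm(form, data = d,
                   contrasts = list(group = "contr.sum", level = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  ssErr <- a3[["Sum Sq"]][rownames(a3) == "Residuals"]
  dfErr <- a3[["Df"]][rownames(a3) == "Residuals"]
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  eff <- rownames(a3)[keep]
  betaAge <- if (covariate) unname(stats::coef(fit)["age"]) else NA_real_
  results <- data.frame(
    effect = unname(c(group = "Group", level = "Level", age = "Age",
                      "group:level" = "Group:Level")[eff]),
    F = a3[["F value"]][keep],
    df1 = a3[["Df"]][keep],
    df2 = dfErr,
    p = a3[["Pr(>F)"]][keep],
    eta_sq_partial = a3[["Sum Sq"]][keep] /
      (a3[["Sum Sq"]][keep] + ssErr),
    beta_age = betaAge,
    stringsAsFactors = FALSE)
  emm <- if (marginalMeans)
    suppressMessages(emmeans::emmeans(fit, ~ group * level)) else NULL
  list(results = results, fit = fit, marginalMeans = emm)
}

#' Fisher's LSD post-hoc comparisons
#'
#' All pairwise t-tests of (age-adjusted) marginal means over one factor,
#' using the model's pooled error term and error degrees of freedom, with no
#' multiplicity adjustment (the LSD definition); \code{p_adjusted} therefore
#' equals \code{p}.
#'
#' @param fit an lm fit (e.g. from [ancovaComponent()]'s \code{fit}).
#' @param factor factor name, e.g. \code{"group"} or \code{"level"}.
#' @return data.frame: contrast, estimate, SE, df, t, p, p_adjusted.
#' @export
lsdPosthoc <- function(fit, factor) {
  fv <- fit$model[[factor]]
  if (is.null(fv) || nlevels(droplevels(as.factor(fv))) < 2)
    stop("factor must have at least 2 levels in the fit")
  emm <- suppressMessages(emmeans::emmeans(fit, stats::reformulate(factor)))
  pr <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             df = pr$df, t = pr$t.ratio, p = pr$p.value,
             p_adjusted = pr$p.value, stringsAsFactors = FALSE)
}

#' Group-difference topographic map
#'
#' Per-electrode difference of group mean component amplitude (ASD minus TD),
#' averaged over the requested stimulus levels.
#'
#' @param table component table (must contain both groups).
#' @param component component to map.
#' @param levels levels to average over (default all five).
#' @param montage montage supplying plotting positions.
#' @return data.frame (class \code{TopoMap}): electrode, value (microvolts),
#'   x, y.
#' @export
groupDifferenceTopomap <- function(table, component, levels = LEVEL_LABELS,
                                   montage = standardMontage()) {
  d <- table[table$component == component & table$level %in% levels, ,
             drop = FALSE]
  if (length(unique(d$group)) < 2) stop("both groups must be present")
  if (!all(d$electrode %in% montage$channel))
    stop("electrode missing from montage: ",
         paste(setdiff(unique(d$electrode), montage$channel), collapse = ","))
  agg <- stats::aggregate(amplitude_uV ~ electrode + group, d, mean)
  el <- sort(unique(agg$electrode))
  val <- vapply(el, function(e) {
    a <- agg$amplitude_uV[agg$electrode == e & agg$group == "ASD"]
    t <- agg$amplitude_uV[agg$electrode == e & agg$group == "TD"]
    if (!length(a) || !length(t)) NA_real_ else a - t
  }, numeric(1))
  out <- data.frame(electrode = el, value = unname(val),
                    x = montage$x[match(el, montage$channel)],
                    y = montage$y[match(el, montage$channel)],
                    stringsAsFactors = FALSE)
  class(out) <- c("TopoMap", class(out))
  out
}

#' Electrodes whose absolute map value exceeds a threshold
#'
#' Companion query for [groupDifferenceTopomap()]: the sites with the largest
#' group differences (default threshold 10 microvolts).
#'
#' @param topo a TopoMap data.frame.
#' @param threshold microvolts (default 10).
#' @return character vector of electrode names.
#' @export
topoExceeding <- function(topo, threshold = 10) {
  topo$electrode[!is.na(topo$value) & abs(topo$value) > threshold]
}

#' Per-electrode one-way level ANOVA topographic map
#'
#' Within one group, a one-way ANOVA of component amplitude across the five
#' stimulus levels at every electrode; the per-electrode p-values (and eta
#' squared) form the map.
#'
#' @param table component table.
#' @param group group to analyse ("ASD" or "TD").
#' @param component component to analyse (default the single component present).
#' @param montage montage supplying positions.
#' @return data.frame (class \code{TopoMap}): electrode, value (p), eta_sq,
#'   F, x, y.
#' @export
levelAnovaTopomap <- function(table, group, component = NULL,
                              montage = standardMontage()) {
  d <- table[table$group == group, , drop = FALSE]
  if (is.null(component)) {
    component <- unique(d$component)
    if (length(component) != 1)
      stop("table has multiple components; pass `component`")
  }
  d <- d[d$component == component, , drop = FALSE]
  if (!nrow(d)) stop("no rows for group ", group)
  el <- sort(unique(d$electrode))
  rows <- lapply(el, function(e) {
    de <- d[d$electrode == e, , drop = FALSE]
    cnt <- base::table(factor(de$level, levels = LEVEL_LABELS))
    if (any(cnt == 0)) stop("empty level at electrode ", e)
    if (all(cnt == 1)) stop("n=1 per level: no residual degrees of freedom")
    fit <- stats::aov(amplitude_uV ~ factor(level), data = de)
    s <- summary(fit)[[1]]
    data.frame(electrode = e, value = s[["Pr(>F)"]][1],
               eta_sq = s[["Sum Sq"]][1] / sum(s[["Sum Sq"]]),
               F = s[["F value"]][1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$x <- montage$x[match(out$electrode, montage$channel)]
  out$y <- montage$y[match(out$electrode, montage$channel)]
  class(out) <- c("TopoMap", class(out))
  out
}

#' Power of the one-way fixed-effects ANOVA F test
#'
#' Computed from the noncentral F distribution with noncentrality
#' \eqn{\lambda = f^2 N} (Cohen's f, total N), numerator df \eqn{k-1} and
#' denominator df \eqn{N-k}.
#'
#' @param effectF Cohen's f (>= 0).
#' @param alpha significance level.
#' @param nPerGroup subjects per group.
#' @param kGroups number of groups (>= 2).
#' @return list (class \code{PowerResult}): effect_f, alpha, n_per_group,
#'   k_groups, power.
#' @examples
#' powerOneway(1.71, 0.05, 36, 2)$power   # > 0.99
#' @export
powerOneway <- function(effectF, alpha, nPerGroup, kGroups = 2) {
  stopifnot(effectF >= 0, alpha > 0, alpha < 1, kGroups >= 2, nPerGroup >= 2)
  N <- nPerGroup * kGroups
  df1 <- kGroups - 1
  df2 <- N - kGroups
  lambda <- effectF^2 * N
  crit <- stats::qf(1 - alpha, df1, df2)
  structure(list(effect_f = effectF, alpha = alpha, n_per_group = nPerGroup,
                 k_groups = kGroups,
                 power = stats::pf(crit, df1, df2, ncp = lambda,
                                   lower.tail = FALSE)),
            class = "PowerResult")
}

#' Smallest per-group sample size achieving a target power
#'
#' @param effectF Cohen's f (> 0).
#' @param alpha significance level.
#' @param targetPower required power.
#' @param kGroups number of groups.
#' @param nMax search cap.
#' @return smallest integer n per group with power >= targetPower.
#' @export
solveN <- function(effectF, alpha, targetPower, kGroups = 2, nMax = 10000) {
  if (effectF <= 0 && targetPower > alpha)
    stop("unreachable power: zero effect size")
  for (n in 2:nMax) {
    if (powerOneway(effectF, alpha, n, kGroups)$power >= targetPower)
      return(n)
  }
  stop("target power not reached by n = ", nMax)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; order-preserving and never smaller than the raw
#' p-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
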