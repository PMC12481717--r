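#' Sliding-window across-level coefficient of variation
#'
#' At one electrode, slides a window (default 10 ms wide, 1 ms step) over the
#' post-stimulus analysis span (default 0-400 ms, covering the five ERP
#' components) and, at each position, computes the coefficient of variation
#' CV = SD / |mean| of the evoked amplitudes across the five stimulus levels
#' at each point within the window, averaged over the window's time points.
#' (\code{pooled = TRUE} instead pools all 5 levels x window samples into one
#' set per window.) The standard deviation is the sample (n-1) SD. Windows
#' whose mean magnitude falls below \code{epsilon} at any point are guarded by
#' the SD/epsilon bound and flagged.
#'
#' @param evokeds list of exactly 5 per-level \linkS4class{Evoked} objects on a
#'   common time base covering the span.
#' @param electrode channel name.
#' @param windowWidth window width, ms (default 10).
#' @param step step length, ms (default 1).
#' @param span analysis span (start, end) ms post-stimulus (default c(0, 400)).
#' @param epsilon mean-magnitude guard, microvolts (default 0.1).
#' @param pooled pool all levels x samples into one set per window instead of
#'   the per-point variant (default FALSE).
#' @return a \linkS4class{CVSeries}. With the defaults the series has
#'   \code{floor((400 - 10)/1) + 1 = 391} windows.
#' @examples
#' # constant per-level amplitudes (1,2,3,4,5) uV: CV = sd(1:5)/3 ~ 0.527
#' @export
slidingCV <- function(evokeds, electrode, windowWidth = 10, step = 1,
                      span = c(0, 400), epsilon = 0.1, pooled = FALSE) {
  if (length(evokeds) != 5)
    stop("need exactly 5 per-level evoked responses")
  t <- evokeds[[1]]@timeMs
  for (ev in evokeds) {
    if (!identical(ev@timeMs, t)) stop("evokeds must share one time base")
    if (!electrode %in% ev@channelNames) stop("electrode not present: ", electrode)
  }
  if (span[1] < min(t) || span[2] > max(t) + 1)
    stop("span outside the evoked time range")
  amp <- t(vapply(evokeds, function(ev)
    ev@data[match(electrode, ev@channelNames), ], numeric(length(t))))
  starts <- seq(span[1], span[2] - windowWidth, by = step)
  cv <- numeric(length(starts))
  flagged <- logical(length(starts))
  for (i in seq_along(starts)) {
    sel <- t >= starts[i] & t < starts[i] + windowWidth
    w <- amp[, sel, drop = FALSE]
    if (pooled) {
      s <- stats::sd(as.vector(w))
      m <- abs(mean(w))
      flagged[i] <- m < epsilon
      cv[i] <- s / max(m, epsilon)
    } else {
      s <- apply(w, 2, stats::sd)
      m <- abs(colMeans(w))
      cv[i] <- mean(s / pmax(m, epsilon))
      flagged[i] <- any(m < epsilon)
    }
  }
  meta <- evokeds[[1]]@subjectMeta
  new("CVSeries", subject = as.character(meta$id %||% "?"),
      electrode = electrode,
      windowCentersMs = starts + windowWidth / 2,
      cv = cv, flagged = flagged, windowWidth = windowWidth, step = step,
      span = as.numeric(span))
}

#' Total CV over a span
#'
#' Mean of the sliding-window CV values whose window centers fall inside the
#' requested span (default the full series). Flagged windows (epsilon-guarded
#' denominators) are excluded by default.
#'
#' @param series a \linkS4class{CVSeries}.
#' @param span (start, end) ms; default the series' own span.
#' @param includeFlagged include epsilon-guarded windows (default FALSE).
#' @return scalar total CV.
#' @export
totalCV <- function(series, span = series@span, includeFlagged = FALSE) {
  sel <- series@windowCentersMs >= span[1] & series@windowCentersMs <= span[2]
  if (!any(sel)) stop("empty span")
  if (!includeFlagged) {
    ok <- sel & !series@flagged
    if (any(ok)) sel <- ok   # fall back to all windows if everything flagged
  }
  mean(series@cv[sel])
}

#' Group comparison of per-subject total CV, per electrode
#'
#' For each electrode, tests the per-subject total CV between the two groups —
#' Welch's two-sample t-test by default (the groups are independent), or a
#' rank-matched paired t-test (subjects sorted by age within group, paired by
#' rank) — and adjusts p-values across electrodes with Benjamini-Hochberg FDR.
#'
#' @param totals data.frame with columns \code{subject, group, electrode,
#'   total_cv} (and \code{age} for the paired variant).
#' @param electrodes electrodes to test (default all present).
#' @param paired use the rank-matched paired variant (default FALSE = Welch).
#' @return data.frame: electrode, t, df, p, p_adjusted, mean_ASD, mean_TD.
#' @export
compareCVGroups <- function(totals, electrodes = sort(unique(totals$electrode)),
                            paired = FALSE) {
  rows <- lapply(electrodes, function(e) {
    d <- totals[totals$electrode == e, , drop = FALSE]
    a <- d[d$group == "ASD", , drop = FALSE]
    b <- d[d$group == "TD", , drop = FALSE]
    if (nrow(a) < 3 || nrow(b) < 3) stop("need n >= 3 per group at ", e)
    if (paired) {
      if (nrow(a) != nrow(b)) stop("paired variant needs equal n per group")
      av <- a$total_cv[order(a$age)]
      bv <- b$total_cv[order(b$age)]
      tt <- stats::t.test(av, bv, paired = TRUE)
    } else {
      tt <- stats::t.test(a$total_cv, b$total_cv)
    }
    data.frame(electrode = e, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_ASD = mean(a$total_cv), mean_TD = mean(b$total_cv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdrAdjust(out$p)
  out
}

#' Per-subject total CV table for a cohort
#'
#' Convenience: computes [slidingCV()] and [totalCV()] for every subject and
#' electrode.
#'
#' @param cohortEvoked named list (per subject) of per-level evoked lists.
#' @param electrodes electrodes to analyse.
#' @param span span passed to [totalCV()] (default the series span).
#' @param ... passed to [slidingCV()].
#' @return data.frame: subject, group, age, electrode, total_cv.
#' @export
cohortTotalCV <- function(cohortEvoked, electrodes, span = NULL, ...) {
  rows <- list()
  for (subj in names(cohortEvoked)) {
    evs <- cohortEvoked[[subj]][LEVEL_LABELS]
    meta <- evs[[1]]@subjectMeta
    for (e in electrodes) {
      s <- slidingCV(evs, e, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, group = meta$group, age = meta$age, electrode = e,
        total_cv = totalCV(s, span = if (is.null(span)) s@span else span),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
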