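#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA decomposition of an n subjects x k
#' conditions matrix: with MSR the between-subject (rows) mean square, MSC the
#' between-condition (columns) mean square and MSE the residual mean square,
#'
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' @param m numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells, at least 2 rows and 2 columns.
#' @param thresholds reliability band cut-points passed to
#'   [bandReliability()].
#' @return list (class \code{ICCResult}): icc, MSR, MSC, MSE, k, n, band.
#' @examples
#' m <- outer(c(1, 2, 3, 4), rep(1, 3))   # identical conditions
#' iccAbsoluteAgreement(m)$icc            # 1
#' @export
iccAbsoluteAgreement <- function(m, thresholds = c(0.5, 0.75, 0.9)) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("measurement matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST < .Machine$double.eps) stop("zero total variance: ICC undefined")
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  structure(list(icc = icc, MSR = MSR, MSC = MSC, MSE = MSE,
                 k = k, n = n,
                 band = bandReliability(icc, thresholds)),
            class = "ICCResult")
}

#' Reliability band for an ICC value
#'
#' Default four-band scheme with closed-left intervals: below 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, 0.9 and above excellent.
#'
#' @param icc ICC value.
#' @param thresholds strictly increasing cut-points (default c(0.5, 0.75, 0.9)).
#' @param labels band labels, length \code{length(thresholds) + 1}.
#' @return band label.
#' @export
bandReliability <- function(icc, thresholds = c(0.5, 0.75, 0.9),
                            labels = c("poor", "moderate", "good", "excellent")) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (length(labels) != length(thresholds) + 1)
    stop("need one more label than thresholds")
  labels[findInterval(icc, thresholds) + 1L]
}

#' ICC reliability report for ERP and CV features
#'
#' Builds, per group, the measurement matrices the reliability analysis needs
#' and computes ICC(2,1) for each feature. ERP features use subjects x 5
#' stimulus levels (one matrix per electrode/component); CV features use
#' subjects x electrodes (total CV per electrode as the conditions).
#'
#' @param componentTable component table from [buildComponentTable()] (or NULL).
#' @param cvTotals total-CV table from [cohortTotalCV()] (or NULL).
#' @param group group to report on.
#' @param erpFeatures data.frame with columns \code{electrode, component}
#'   selecting ERP features (default: all combinations present).
#' @return data.frame: feature, group, icc, MSR, MSC, MSE, k, n, band.
#' @export
featureReliabilityReport <- function(componentTable = NULL, cvTotals = NULL,
                                     group, erpFeatures = NULL) {
  rows <- list()
  addRow <- function(feature, m) {
    if (nrow(m) < 2) stop("group with n < 2 subjects: ICC undefined")
    r <- iccAbsoluteAgreement(m)
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, group = group, icc = r$icc, MSR = r$MSR,
      MSC = r$MSC, MSE = r$MSE, k = r$k, n = r$n, band = r$band,
      stringsAsFactors = FALSE)
  }
  if (!is.null(componentTable)) {
    d <- componentTable[componentTable$group == group, , drop = FALSE]
    if (is.null(erpFeatures))
      erpFeatures <- unique(d[, c("electrode", "component")])
    for (i in seq_len(nrow(erpFeatures))) {
      e <- erpFeatures$electrode[i]; cp <- erpFeatures$component[i]
      de <- d[d$electrode == e & d$component == cp, , drop = FALSE]
      m <- stats::reshape(de[, c("subject", "level", "amplitude_uV")],
                          idvar = "subject", timevar = "level",
                          direction = "wide")
      mm <- as.matrix(m[, -1, drop = FALSE])
      if (any(!is.finite(mm))) {
        message("dropping incomplete ERP matrix for ", e, "/", cp)
        next
      }
      addRow(paste0("ERP:", e, ":", cp), mm)
    }
  }
  if (!is.null(cvTotals)) {
    d <- cvTotals[cvTotals$group == group, , drop = FALSE]
    if (nrow(d)) {
      m <- stats::reshape(d[, c("subject", "electrode", "total_cv")],
                          idvar = "subject", timevar = "electrode",
                          direction = "wide")
      mm <- as.matrix(m[, -1, drop = FALSE])
      if (ncol(mm) >= 2 && all(is.finite(mm)))
        addRow("CV:levels", mm)
      else if (any(!is.finite(mm)))
        message("dropping incomplete CV matrix")
    }
  }
  if (!length(rows)) stop("no complete measurement matrices for group ", group)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
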