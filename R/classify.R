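#' Assemble a subject-level feature matrix
#'
#' Feature specifiers are strings: \code{"ELECTRODE:COMPONENT:LEVEL"} (e.g.
#' \code{"F8:P300:L2"}) selects a component amplitude from the component
#' table; \code{"CV:ELECTRODE"} selects the subject's total CV at that
#' electrode from the CV totals table (computed over the configured span,
#' 200-400 ms post-stimulus in the classification analysis). Standardization
#' is deliberately *not* applied here: it happens inside cross-validation on
#' training folds only.
#'
#' @param componentTable component table (or NULL if no ERP features).
#' @param cvTotals total-CV table from [cohortTotalCV()] (or NULL).
#' @param features character vector of feature specifiers.
#' @return list (class \code{FeatureMatrix}): \code{x} (subjects x features
#'   matrix), \code{y} (factor TD/ASD), \code{subjects}, \code{featureNames}.
#' @export
buildFeatures <- function(componentTable = NULL, cvTotals = NULL, features) {
  if (!length(features)) stop("no features requested")
  subjects <- unique(c(componentTable$subject, cvTotals$subject))
  if (!length(subjects)) stop("no subjects available")
  meta <- rbind(
    if (!is.null(componentTable))
      unique(componentTable[, c("subject", "group")]),
    if (!is.null(cvTotals)) unique(cvTotals[, c("subject", "group")]))
  meta <- unique(meta)
  x <- matrix(NA_real_, length(subjects), length(features),
              dimnames = list(subjects, features))
  for (f in features) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (parts[1] == "CV") {
      if (is.null(cvTotals)) stop("CV feature requested but no CV table: ", f)
      d <- cvTotals[cvTotals$electrode == parts[2], , drop = FALSE]
      if (!nrow(d))
        stop("feature ", f, " unavailable; electrodes present: ",
             paste(sort(unique(cvTotals$electrode)), collapse = ","))
      x[d$subject, f] <- d$total_cv
    } else {
      if (length(parts) != 3)
        stop("bad feature specifier (want ELECTRODE:COMPONENT:LEVEL): ", f)
      if (is.null(componentTable)) stop("ERP feature requested but no table: ", f)
      d <- componentTable[componentTable$electrode == parts[1] &
                            componentTable$component == parts[2] &
                            componentTable$level == parts[3], , drop = FALSE]
      if (!nrow(d))
        stop("feature ", f, " unavailable; electrodes present: ",
             paste(sort(unique(componentTable$electrode)), collapse = ","))
      if (anyDuplicated(d$subject)) stop("duplicate rows for feature ", f)
      x[d$subject, f] <- d$amplitude_uV
    }
  }
  if (any(is.na(x)))
    stop("incomplete feature matrix: ",
         sum(!stats::complete.cases(x)), " subjects with missing values")
  y <- factor(meta$group[match(subjects, meta$subject)], levels = c("TD", "ASD"))
  if (any(is.na(y))) stop("subjects with unknown group label")
  structure(list(x = x, y = y, subjects = subjects, featureNames = features),
            class = "FeatureMatrix")
}

# Stratified fold ids: within each class, a seeded permutation dealt round-
# robin over folds, so every fold's class counts differ by at most one.
stratifiedFolds <- function(y, nFolds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

fitPredictScore <- function(classifier, xtr, ytr, xte, hidden, seed) {
  if (classifier == "SVM") {
    fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1,
                      scale = FALSE, decision.values = TRUE)
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient the decision value so that larger = more ASD-like
    score <- if (grepl("^ASD", colnames(attr(pred, "decision.values"))[1]))
      dv else -dv
    list(class = pred, score = score)
  } else if (classifier == "LDA") {
    fit <- MASS::lda(xtr, ytr)
    pred <- stats::predict(fit, xte)
    list(class = pred$class, score = pred$posterior[, "ASD"])
  } else if (classifier == "ANN") {
    fit <- withSeed(seed,
      nnet::nnet(xtr, stats::model.matrix(~ ytr - 1)[, "ytrASD", drop = FALSE],
                 size = hidden, decay = 0.01, maxit = 300,
                 entropy = TRUE, trace = FALSE))
    score <- drop(stats::predict(fit, xte))
    cls <- factor(ifelse(score > 0.5, "ASD", "TD"), levels = levels(ytr))
    list(class = cls, score = score)
  } else stop("unknown classifier: ", classifier)
}

#' Stratified k-fold evaluation of a group classifier
#'
#' Evaluates SVM (radial kernel), LDA, or a three-layer neural network (one
#' hidden layer of \code{hidden} logistic units) under stratified k-fold
#' cross-validation. Features are z-scored with training-fold statistics only;
#' metrics are pooled over folds from the concatenated confusion matrix, and
#' the AUC is computed from the pooled continuous scores (decision values for
#' SVM, class posterior for LDA, output probability for the network). "ASD" is
#' the positive class for sensitivity/specificity.
#'
#' @param features a \code{FeatureMatrix} from [buildFeatures()].
#' @param classifier one of "SVM", "LDA", "ANN".
#' @param nFolds folds (default 10); must not exceed the smaller class count.
#' @param seed integer seed controlling fold assignment and network init.
#' @param hidden hidden units for the ANN (default 16).
#' @return list (class \code{CVReport}): classifier, accuracy, sensitivity,
#'   specificity, auc, confusion, per_fold (data.frame), n_folds, seed.
#' @export
evaluateClassifier <- function(features, classifier = c("SVM", "LDA", "ANN"),
                               nFolds = 10, seed = 1L, hidden = 16) {
  classifier <- match.arg(classifier)
  x <- features$x; y <- features$y
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (nFolds > min(base::table(y)))
    stop("nFolds exceeds the smaller class count")
  fold <- stratifiedFolds(y, nFolds, deriveSeed(seed, paste0("folds:", classifier)))
  predCls <- factor(rep(NA_character_, length(y)), levels = levels(y))
  score <- numeric(length(y))
  perFold <- vector("list", nFolds)
  for (k in seq_len(nFolds)) {
    tr <- fold != k; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg < .Machine$double.eps] <- 1
    xtr <- scale(x[tr, , drop = FALSE], mu, sg)
    xte <- scale(x[te, , drop = FALSE], mu, sg)
    res <- fitPredictScore(classifier, xtr, y[tr], xte, hidden,
                           deriveSeed(seed, paste0("fit:", classifier, ":", k)))
    predCls[te] <- res$class
    score[te] <- res$score
    perFold[[k]] <- data.frame(
      fold = k, n_test = sum(te),
      n_test_ASD = sum(y[te] == "ASD"),
      accuracy = mean(res$class == y[te]), stringsAsFactors = FALSE)
  }
  tp <- sum(predCls == "ASD" & y == "ASD")
  tn <- sum(predCls == "TD" & y == "TD")
  fp <- sum(predCls == "ASD" & y == "TD")
  fn <- sum(predCls == "TD" & y == "ASD")
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                        levels = c("TD", "ASD"),
                                        direction = "<", quiet = TRUE)))
  structure(list(classifier = classifier,
                 accuracy = (tp + tn) / length(y),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = auc,
                 confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                                    dimnames = list(predicted = c("TD", "ASD"),
                                                    truth = c("TD", "ASD"))),
                 per_fold = do.call(rbind, perFold),
                 n_folds = nFolds, seed = seed,
                 hyperparameters = list(svm_cost = 1, svm_gamma = "1/(p*var)",
                                        ann_hidden = hidden, ann_decay = 0.01)),
            class = "CVReport")
}

#' Sweep feature sets x classifiers
#'
#' Evaluates every combination of named feature set and classifier and returns
#' a grid sorted by accuracy (best first).
#'
#' @param componentTable component table.
#' @param cvTotals CV totals table.
#' @param sets named list of feature-specifier vectors.
#' @param classifiers classifiers to run (default all three).
#' @param nFolds,seed passed to [evaluateClassifier()].
#' @return data.frame: feature_set, classifier, accuracy, sensitivity,
#'   specificity, auc, seed.
#' @export
featureSetSweep <- function(componentTable = NULL, cvTotals = NULL, sets,
                            classifiers = c("SVM", "LDA", "ANN"),
                            nFolds = 10, seed = 1L) {
  rows <- list()
  for (sn in names(sets)) {
    fm <- buildFeatures(componentTable, cvTotals, sets[[sn]])
    for (cl in classifiers) {
      r <- evaluateClassifier(fm, cl, nFolds, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = sn, classifier = cl, accuracy = r$accuracy,
        sensitivity = r$sensitivity, specificity = r$specificity,
        auc = r$auc, seed = seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$accuracy), , drop = FALSE]
}
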