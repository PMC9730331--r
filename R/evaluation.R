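#' Classifier specification
#'
#' The three classifiers used for diagnostic validation: linear
#' discriminant analysis, linear SVM and Gaussian (RBF) SVM, each at
#' fixed, logged defaults.
#'
#' @param kind one of `"lda"`, `"svm-linear"`, `"svm-gaussian"`.
#' @param sigma Gaussian kernel width; `NULL` (default) uses the median
#'   pairwise Euclidean distance of the training features. The kernel is
#'   `exp(-||x - y||^2 / (2 sigma^2))`.
#' @param cost SVM cost (box constraint), default 1.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "svm-linear", "svm-gaussian"),
                            sigma = NULL, cost = 1) {
  kind <- match.arg(kind)
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  structure(list(kind = kind, sigma = sigma, cost = cost),
            class = "classifier_spec")
}

feature_matrix <- function(table) {
  lab <- label_column(table)
  x <- table[, setdiff(names(table), lab), drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  as.matrix(x[, num, drop = FALSE])
}

label_column <- function(table) {
  for (cand in c("score", "label", "class"))
    if (cand %in% names(table)) return(cand)
  stop("feature table needs a `score`, `label` or `class` column")
}

median_heuristic_sigma <- function(x) {
  d <- stats::dist(x)
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Train a classifier and predict on a test set
#'
#' Fits the requested classifier on the training table and returns
#' predicted labels plus per-class decision scores for the test table.
#' LDA scores are class posteriors; SVM scores are one-vs-rest decision
#' values (one binary machine per class, same kernel and cost). A
#' singular pooled covariance in LDA is handled by `MASS::lda`'s
#' tolerance with a small jitter fallback.
#'
#' @param train,test data.frames with numeric feature columns and a
#'   `score` (or `label`/`class`) column in `train`.
#' @param spec a [classifier_spec()].
#' @return list with `predicted` (factor over the training class levels)
#'   and `scores` (matrix, test rows x classes).
#' @export
train_classify <- function(train, test, spec = classifier_spec()) {
  lab <- label_column(train)
  ytr <- factor(train[[lab]])
  if (nlevels(ytr) < 2) stop("training data must contain >= 2 classes")
  xtr <- feature_matrix(train)
  xte <- if (label_column_safe(test)) feature_matrix(test) else
    as.matrix(test[, vapply(test, is.numeric, logical(1)), drop = FALSE])
  if (ncol(xte) != ncol(xtr)) stop("train/test feature dimensions differ")
  classes <- levels(ytr)

  if (spec$kind == "lda") {
    fit <- tryCatch(MASS::lda(xtr, grouping = ytr),
                    error = function(e) MASS::lda(
                      xtr + matrix(stats::rnorm(length(xtr), 0, 1e-8),
                                   nrow(xtr)), grouping = ytr))
    pr <- stats::predict(fit, xte)
    sc <- pr$posterior[, classes, drop = FALSE]
    pred <- factor(as.character(pr$class), levels = classes)
  } else {
    kernel <- if (spec$kind == "svm-linear") "linear" else "radial"
    gamma <- if (kernel == "radial") {
      sg <- if (is.null(spec$sigma)) median_heuristic_sigma(xtr) else
        spec$sigma
      1 / (2 * sg^2)
    } else 1 / ncol(xtr)
    fit <- e1071::svm(xtr, ytr, kernel = kernel, cost = spec$cost,
                      gamma = gamma, scale = FALSE)
    pred <- factor(as.character(stats::predict(fit, xte)),
                   levels = classes)
    sc <- vapply(classes, function(cl) {
      yb <- factor(ifelse(ytr == cl, "pos", "neg"),
                   levels = c("neg", "pos"))
      fb <- e1071::svm(xtr, yb, kernel = kernel, cost = spec$cost,
                       gamma = gamma, scale = FALSE)
      dv <- attr(stats::predict(fb, xte, decision.values = TRUE),
                 "decision.values")
      # orient so larger = more positive
      if (grepl("^neg/", colnames(dv)[1])) -dv[, 1] else dv[, 1]
    }, numeric(nrow(xte)))
    sc <- matrix(sc, nrow = nrow(xte),
                 dimnames = list(NULL, classes))
  }
  list(predicted = pred, scores = sc, classes = classes)
}

label_column_safe <- function(table) {
  any(c("score", "label", "class") %in% names(table))
}

#' Empirical ROC curve and AUC
#'
#' Ranks observations by decision score and traces the ROC curve; tied
#' scores are collapsed into single curve vertices, so the trapezoidal
#' area equals the rank-average Mann-Whitney statistic
#' `U / (n_pos * n_neg)`.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param labels logical (or 2-level factor/0-1) positives.
#' @return list with `fpr`, `tpr` (curve vertices from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))        # tie groups
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

macro_ovr_auc <- function(scores, y) {
  classes <- colnames(scores)
  mean(vapply(classes, function(cl)
    roc_curve(scores[, cl], y == cl)$auc, numeric(1)))
}

confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes),
        dnn = c("reference", "predicted"))
}

# macro-averaged one-vs-rest sensitivity and specificity (percent)
macro_sens_spec <- function(cm) {
  sens <- spec <- numeric(nrow(cm))
  tot <- sum(cm)
  for (i in seq_len(nrow(cm))) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp; tn <- tot - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  c(sensitivity = 100 * mean(sens, na.rm = TRUE),
    specificity = 100 * mean(spec, na.rm = TRUE))
}

#' Stratified k-fold cross-validated evaluation
#'
#' Rows are sorted canonically (by features, then label) before the
#' seed-derived stratified fold assignment, so results are invariant to
#' the input row order. Within each class, fold labels are a random
#' permutation of a balanced sequence, keeping per-fold class proportions
#' within one sample of the global ones. Sensitivity, specificity and
#' accuracy are macro-averaged one-vs-rest and reported as mean +/- SD
#' over folds (percent); the AUC is the macro-averaged one-vs-rest area
#' computed from the pooled out-of-fold decision scores.
#'
#' @param table feature data.frame with a label column (see
#'   [train_classify()]).
#' @param spec a [classifier_spec()].
#' @param folds number of folds (default 5); every class must have at
#'   least this many members.
#' @param seed integer seed for the fold assignment.
#' @return object of class `eval_report`: `accuracy`, `sensitivity`,
#'   `specificity` (each `c(mean, sd)` in percent), `auc`,
#'   `confusion` (aggregated over folds), `per_class_rate` (percent),
#'   `folds`, `classifier`.
#' @export
cross_validate <- function(table, spec = classifier_spec(), folds = 5L,
                           seed = 1L) {
  lab <- label_column(table)
  y <- factor(table[[lab]])
  if (nlevels(y) < 2) stop("need >= 2 classes")
  counts <- table(y)
  small <- names(counts)[counts < folds]
  if (length(small))
    stop("class ", paste(small, collapse = ", "),
         " has fewer members than folds")
  x <- feature_matrix(table)
  ord <- do.call(order, c(as.data.frame(x), list(as.character(y))))
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  classes <- levels(y)
  acc <- sens <- spc <- numeric(folds)
  pooled_scores <- matrix(NA_real_, length(y), length(classes),
                          dimnames = list(NULL, classes))
  pooled_pred <- factor(rep(NA, length(y)), levels = classes)
  df <- as.data.frame(x)
  df[[lab]] <- y
  for (f in seq_len(folds)) {
    te <- fold_id == f
    res <- train_classify(df[!te, , drop = FALSE],
                          df[te, , drop = FALSE], spec)
    cm <- confusion_matrix(y[te], res$predicted, classes)
    acc[f] <- 100 * sum(diag(cm)) / sum(cm)
    ss <- macro_sens_spec(cm)
    sens[f] <- ss["sensitivity"]; spc[f] <- ss["specificity"]
    pooled_scores[te, ] <- res$scores
    pooled_pred[te] <- res$predicted
  }
  cm_all <- confusion_matrix(y, pooled_pred, classes)
  per_class <- 100 * diag(cm_all) / rowSums(cm_all)
  auc <- if (length(classes) == 2)
    roc_curve(pooled_scores[, 2], y == classes[2])$auc
  else macro_ovr_auc(pooled_scores, y)
  structure(list(
    accuracy = c(mean = mean(acc), sd = stats::sd(acc)),
    sensitivity = c(mean = mean(sens), sd = stats::sd(sens)),
    specificity = c(mean = mean(spc), sd = stats::sd(spc)),
    auc = auc, confusion = cm_all, per_class_rate = per_class,
    folds = folds, classifier = spec$kind),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s, %d-fold stratified CV):\n", x$classifier,
              x$folds))
  cat(sprintf("  accuracy    %.2f +/- %.2f %%\n", x$accuracy[1],
              x$accuracy[2]))
  cat(sprintf("  sensitivity %.2f +/- %.2f %% (macro OVR)\n",
              x$sensitivity[1], x$sensitivity[2]))
  cat(sprintf("  specificity %.2f +/- %.2f %% (macro OVR)\n",
              x$specificity[1], x$specificity[2]))
  cat(sprintf("  AUC         %.3f (pooled out-of-fold%s)\n", x$auc,
              if (nrow(x$confusion) > 2) ", macro OVR" else ""))
  invisible(x)
}

#' Agreement between model and reference scores
#'
#' Pearson product-moment correlation, confusion matrix and per-class
#' detection rates of model-assigned scores against a reference
#' assessment.
#'
#' @param model_scores,reference_scores equal-length vectors (>= 3) of
#'   ordinal scores with nonzero variance.
#' @return list with `r`, `confusion` (reference in rows), and
#'   `detection_rate` (percent correct per reference class).
#' @export
agreement <- function(model_scores, reference_scores) {
  if (length(model_scores) != length(reference_scores) ||
      length(model_scores) < 3)
    stop("need equal-length vectors of length >= 3")
  a <- as.numeric(as.character(model_scores))
  b <- as.numeric(as.character(reference_scores))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance")
  classes <- sort(unique(c(a, b)))
  cm <- confusion_matrix(b, a, as.character(classes))
  rate <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  list(r = stats::cor(a, b), confusion = cm, detection_rate = rate)
}

#' Collapse PI-RADS scores to the low/high dichotomy
#'
#' Scores 2-3 map to `"low"`, 4-5 to `"high"`.
#'
#' @param table a feature table with a `score` column.
#' @return the table with `score` replaced by a `low`/`high` factor.
#' @export
binarize_scores <- function(table) {
  lab <- label_column(table)
  s <- as.integer(as.character(table[[lab]]))
  table[[lab]] <- factor(ifelse(s >= 4, "high", "low"),
                         levels = c("low", "high"))
  table
}
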