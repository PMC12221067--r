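#' Confusion counts
#'
#' Standard binary confusion counts with class 1 (TLE) as the positive
#' class.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return A `confusion_counts` list: TP, TN, FP, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion: length mismatch (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("confusion: labels must be binary 0/1")
  }
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' The nine reported metrics: accuracy, precision, sensitivity (recall),
#' specificity, F1, MCC, NPV, FPR and FNR. Ratios with a zero denominator
#' are reported as `NA` with a warning — never silently 0 or 1 — so
#' degenerate counts cannot corrupt aggregates. The identities
#' FPR = 1 - specificity and FNR = 1 - sensitivity hold exactly.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return A one-row tibble of class `eval_metrics` with the nine metrics.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("classification_metrics: zero total count")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("classification_metrics: ", what,
              " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(TP, TP + FP, "precision")
  sensitivity <- ratio(TP, TP + FN, "sensitivity")
  specificity <- ratio(TN, TN + FP, "specificity")
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) {
    warning("classification_metrics: F1 undefined; reported as NA")
    NA_real_
  } else 2 * precision * sensitivity / (precision + sensitivity)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("classification_metrics: MCC undefined; reported as NA")
    NA_real_
  } else (TP * TN - FP * FN) / mcc_den
  out <- tibble::tibble(
    accuracy = (TP + TN) / n,
    precision = precision,
    sensitivity = sensitivity,
    specificity = specificity,
    f1 = f1,
    mcc = mcc,
    npv = ratio(TN, TN + FN, "NPV"),
    fpr = if (is.na(specificity)) NA_real_ else 1 - specificity,
    fnr = if (is.na(sensitivity)) NA_real_ else 1 - sensitivity
  )
  class(out) <- c("eval_metrics", class(out))
  out
}

#' ROC curve and AUC
#'
#' Builds the ROC from every distinct score threshold (equal scores are
#' grouped, which makes label-independent scores trace the chance diagonal
#' and give AUC 0.5) and integrates by the trapezoid rule. The AUC equals
#' the concordant-pair (Mann-Whitney) statistic and is invariant under
#' strictly increasing transforms of the scores.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores real-valued scores, higher = more positive.
#' @return List with `roc` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2) {
    stop("roc_auc: both classes must be present")
  }
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & y_true == 0) / N, tpr = sum(pred & y_true == 1) / P)
  }, numeric(2))
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, pts["fpr", ]),
    tpr = c(0, pts["tpr", ]))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report
#'
#' Confusion counts, the nine metrics, and (when scores are supplied) the
#' ROC points and AUC.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param scores optional positive-class scores for the ROC.
#' @return An `eval_report` list: `counts`, `metrics`, `roc`, `auc`.
#' @export
eval_report <- function(y_true, y_pred, scores = NULL) {
  counts <- confusion(y_true, y_pred)
  metrics <- classification_metrics(counts)
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores) && length(unique(y_true)) == 2) {
    r <- roc_auc(y_true, scores)
    roc <- r$roc
    auc <- r$auc
  }
  structure(list(counts = counts, metrics = metrics, roc = roc, auc = auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> TP =", x$counts$TP, "TN =", x$counts$TN,
      "FP =", x$counts$FP, "FN =", x$counts$FN, "\n")
  m <- x$metrics
  cat("  accuracy ", signif(m$accuracy, 4), " | sensitivity ",
      signif(m$sensitivity, 4), " | specificity ",
      signif(m$specificity, 4), sep = "")
  if (!is.na(x$auc)) cat(" | AUC ", signif(x$auc, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Metric names in the JSON mirror the standard report column headers
#' (Accuracy, Precision, Sensitivity, Specificity, F1-Score, MCC, NPV,
#' FPR, FNR) for cross-referencing.
#'
#' @param report an [eval_report()] (or the summary from
#'   [kfold_evaluate()]).
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  m <- report$metrics
  obj <- list(
    counts = report$counts[c("TP", "TN", "FP", "FN")],
    metrics = list(
      "Accuracy" = m$accuracy, "Precision" = m$precision,
      "Sensitivity" = m$sensitivity, "Specificity" = m$specificity,
      "F1-Score" = m$f1, "MCC" = m$mcc, "NPV" = m$npv,
      "FPR" = m$fpr, "FNR" = m$fnr),
    auc = report$auc)
  if (!is.null(report$roc)) obj$roc <- as.list(report$roc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Stratified k-fold evaluation
#'
#' Splits the dataset into k stratified folds (fixed seed), trains a fresh
#' model per fold via `model_factory`, evaluates on the held-out fold, and
#' reports per-fold metrics plus their mean and standard deviation in the
#' per-fold table layout (one row per fold, one column per metric).
#'
#' @param dataset list with `x` (list of inputs) and `y` (0/1 labels) —
#'   or a labelled [feature_table()], in which case each row is a sample.
#' @param model_factory `function(train_x, train_y) -> model`, where the
#'   returned model is called as `predict_fn(model, test_x)`.
#' @param predict_fn `function(model, x_list) -> matrix of class
#'   probabilities` (n x 2) or a vector of predicted labels.
#' @param k number of folds (>= 2); every class needs >= k members.
#' @param seed fold assignment seed.
#' @return An object of class `kfold_eval`: `folds` (tibble with fold,
#'   the nine metrics, auc), `summary` (mean/sd rows), `reports` (list of
#'   [eval_report()]s).
#' @export
kfold_evaluate <- function(dataset, model_factory, predict_fn, k = 5,
                           seed = 1L) {
  if (k < 2) stop("kfold_evaluate: k must be >= 2")
  if (inherits(dataset, "feature_table") || is.data.frame(dataset)) {
    X <- ft_values(dataset)
    y <- ft_labels(dataset)
    xs <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  } else {
    xs <- dataset$x
    y <- as.integer(dataset$y)
  }
  folds <- stratified_folds(y, k, seed)
  reports <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    model <- model_factory(xs[!te], y[!te])
    pred <- predict_fn(model, xs[te])
    if (is.matrix(pred)) {
      scores <- pred[, 2]
      lab <- as.integer(max.col(pred, ties.method = "first") == 2)
    } else {
      scores <- NULL
      lab <- as.integer(pred)
    }
    rep <- suppressWarnings(eval_report(y[te], lab, scores))
    reports[[f]] <- rep
    rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), rep$metrics,
                                  tibble::tibble(auc = rep$auc))
  }
  folds_tbl <- dplyr::bind_rows(rows)
  mcols <- setdiff(names(folds_tbl), "fold")
  summary <- tibble::tibble(
    statistic = c("mean", "sd"),
    !!!stats::setNames(lapply(mcols, function(cn) {
      c(mean(folds_tbl[[cn]], na.rm = TRUE),
        stats::sd(folds_tbl[[cn]], na.rm = TRUE))
    }), mcols))
  structure(list(folds = folds_tbl, summary = summary, reports = reports,
                 fold_assignment = folds),
            class = "kfold_eval")
}

#' @export
print.kfold_eval <- function(x, ...) {
  cat("<kfold_eval> k =", nrow(x$folds), "\n")
  print(x$folds)
  invisible(x)
}
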