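# Confusion matrix, one-vs-rest classification metrics, ROC AUC and the
# stratified train/test evaluation harness.

#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes; the trace counts
#' correct predictions.
#'
#' @param truth,predicted Equal-length, non-empty label vectors/factors.
#' @param levels Class order; defaults to the union of observed labels
#'   (sorted), or [hb_classes()] when all labels belong to it.
#' @return Integer `k x k` matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L)
    stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  if (is.null(levels)) {
    obs <- sort(unique(c(truth, predicted)))
    levels <- if (all(obs %in% hb_classes())) hb_classes() else obs
  }
  if (!all(c(truth, predicted) %in% levels))
    stop("labels outside `levels`", call. = FALSE)
  cm <- table(factor(truth, levels), factor(predicted, levels))
  cm <- unclass(matrix(as.integer(cm), nrow(cm),
                       dimnames = list(truth = levels,
                                       predicted = levels)))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Reduces each class one-vs-rest to (TP, FP, TN, FN) and reports, per
#' class: accuracy `(TP+TN)/total`, precision (= PPV) `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1, and the false
#' discovery rate `FDR = FP/(TP+FP)` (so PPV + FDR = 1 whenever the class
#' is ever predicted). Macro values are unweighted class means; overall
#' accuracy is trace/total. Ratios with a zero denominator are reported as
#' `NaN` with a warning, never silently as 0.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return Object of class `metrics_report`: list with `per_class` (data
#'   frame), `macro` (named vector), `overall_accuracy` and `n`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    stop("`cm` must be a square nonnegative count matrix", call. = FALSE)
  total <- sum(cm)
  if (total < 1) stop("`cm` must contain at least one sample",
                      call. = FALSE)
  k <- nrow(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(k))
  ratio <- function(num, den, what, class) {
    if (den == 0) {
      warning(sprintf("%s undefined for class \"%s\" (zero denominator)",
                      what, class), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  per <- data.frame(class = classes, tp = NA_integer_, fp = NA_integer_,
                    tn = NA_integer_, fn = NA_integer_,
                    accuracy = NA_real_, precision = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, ppv = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    prec <- ratio(tp, tp + fp, "precision", classes[i])
    sens <- ratio(tp, tp + fn, "sensitivity", classes[i])
    per[i, c("tp", "fp", "tn", "fn")] <- c(tp, fp, tn, fn)
    per$accuracy[i] <- (tp + tn) / total
    per$precision[i] <- prec
    per$ppv[i] <- prec
    per$fdr[i] <- if (tp + fp == 0) NaN else fp / (tp + fp)
    per$sensitivity[i] <- sens
    per$specificity[i] <- ratio(tn, tn + fp, "specificity", classes[i])
    per$f1[i] <- if (!is.finite(prec) || !is.finite(sens) ||
                     prec + sens == 0) {
      if (!is.finite(prec) || !is.finite(sens)) NaN else 0
    } else 2 * prec * sens / (prec + sens)
  }
  macro <- colMeans(per[, c("accuracy", "precision", "sensitivity",
                            "specificity", "f1")])
  structure(list(per_class = per, macro = macro,
                 overall_accuracy = sum(diag(cm)) / total,
                 n = total, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  cat(sprintf("  overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  tab <- x$per_class
  num <- c("accuracy", "precision", "sensitivity", "specificity", "f1",
           "ppv", "fdr")
  tab[num] <- lapply(tab[num], function(v) round(100 * v, 1))
  print(tab[, c("class", "accuracy", "precision", "sensitivity",
                "specificity", "f1", "ppv", "fdr")], row.names = FALSE)
  cat("  macro: ",
      paste(sprintf("%s=%.1f%%", names(x$macro), 100 * x$macro),
            collapse = " "), "\n")
  invisible(x)
}

#' One-vs-rest ROC AUC by the rank formulation
#'
#' For each class, the area under the one-vs-rest ROC of its predicted
#' probability, computed as the Mann-Whitney rank statistic; tied scores
#' contribute 1/2. Equals trapezoidal integration of the empirical ROC.
#'
#' @param truth Label vector; every class in `colnames(prob)` (or the
#'   observed classes) must be represented.
#' @param prob Numeric `n x k` matrix of class probabilities with class
#'   names as column names.
#' @return Named numeric vector of per-class AUCs.
#' @export
roc_auc_ovr <- function(truth, prob) {
  truth <- as.character(truth)
  prob <- as.matrix(prob)
  if (length(truth) != nrow(prob))
    stop("`truth` and `prob` sizes differ", call. = FALSE)
  classes <- colnames(prob)
  if (is.null(classes))
    stop("`prob` must have class names as column names", call. = FALSE)
  if (length(unique(truth)) < 2L)
    stop("degenerate truth: needs at least two classes", call. = FALSE)
  out <- numeric(length(classes))
  names(out) <- classes
  for (cls in classes) {
    pos <- truth == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
      stop("class not represented in `truth`: ", cls, call. = FALSE)
    r <- rank(prob[, cls])
    out[cls] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Train and evaluate with a stratified 90/10 split
#'
#' Splits the labeled feature table stratified by class (per-class training
#' count `round(train_frac * n_c)`), fits [pallor_mlp()] on the training
#' portion, and reports *both* resubstitution metrics (evaluated on the
#' training data, the optimistic convention) and held-out metrics on the
#' reserved split, clearly distinguished. Deterministic given `seed`.
#'
#' @param features Data frame with a `label` column and the seven feature
#'   columns (see [extract_dataset_features()]).
#' @param train_frac Training fraction of each class.
#' @param seed Integer seed driving the split and the fit.
#' @param ... Passed to [pallor_mlp()] (e.g. `hidden_units`, `max_iter`).
#' @return Object of class `pallor_eval`: list with `model`, `split`
#'   (train/test indices and sizes), and `resubstitution` / `holdout`,
#'   each holding `confusion`, `metrics` and `auc`.
#' @export
evaluate_split <- function(features, train_frac = 0.9, seed = 1L, ...) {
  if (!is.data.frame(features) || is.null(features$label))
    stop("`features` must be a data frame with a `label` column",
         call. = FALSE)
  lab <- factor(as.character(features$label))
  counts <- table(lab)
  if (any(counts < 2L))
    stop("every class needs at least 2 samples to split", call. = FALSE)
  cols <- intersect(feature_names(), names(features))
  if (length(cols) == 0L)
    stop("no feature columns found", call. = FALSE)
  X <- as.matrix(features[, cols, drop = FALSE])

  idx_train <- with_seed(seed, {
    unlist(lapply(levels(lab), function(cl) {
      idx <- which(lab == cl)
      n_tr <- max(1L, min(length(idx) - 1L,
                          as.integer(round(train_frac * length(idx)))))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(X)), idx_train)

  model <- pallor_mlp(X[idx_train, , drop = FALSE], lab[idx_train],
                      seed = seed, ...)
  eval_on <- function(idx) {
    p <- predict(model, X[idx, , drop = FALSE], type = "prob")
    cl <- factor(model$classes[max.col(p, ties.method = "first")],
                 levels = model$classes)
    cm <- confusion_matrix(lab[idx], cl, levels = model$classes)
    list(confusion = cm,
         metrics = classification_metrics(cm),
         auc = roc_auc_ovr(lab[idx], p))
  }
  structure(list(
    model = model,
    split = list(train = idx_train, test = idx_test,
                 n_train = length(idx_train), n_test = length(idx_test)),
    resubstitution = eval_on(idx_train),
    holdout = eval_on(idx_test),
    seed = as.integer(seed)
  ), class = "pallor_eval")
}

#' @export
print.pallor_eval <- function(x, ...) {
  cat(sprintf("Stratified split evaluation: %d train / %d test\n",
              x$split$n_train, x$split$n_test))
  cat("-- resubstitution (training data) --\n")
  print(x$resubstitution$metrics)
  cat("  AUC:",
      paste(sprintf("%s=%.3f", names(x$resubstitution$auc),
                    x$resubstitution$auc), collapse = " "), "\n")
  cat("-- held-out 10% --\n")
  print(x$holdout$metrics)
  cat("  AUC:",
      paste(sprintf("%s=%.3f", names(x$holdout$auc), x$holdout$auc),
            collapse = " "), "\n")
  invisible(x)
}
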