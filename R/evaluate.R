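# Stratified cross-validation and the multiclass metric suite:
# per-class precision/recall, accuracy (trace/total), Cohen's kappa.

#' Confusion matrix from paired labels
#'
#' Rows are reference (actual) labels, columns are predictions.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param levels Class order for rows and columns.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_from_predictions <- function(actual, predicted,
                                       levels = risk_levels()) {
  if (length(actual) != length(predicted) || length(actual) == 0)
    stop("actual and predicted must be non-empty and of equal length")
  cm <- table(factor(actual, levels = levels),
              factor(predicted, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(actual = levels, predicted = levels))
  structure(m, class = c("confusion_matrix", class(m)))
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class precision and recall
#'
#' One-vs-rest: precision is the diagonal cell over its column sum, recall
#' over its row sum. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param cm Confusion matrix.
#' @param cls Class name; omit for all classes.
#' @return For one class, `c(precision =, recall =)`; otherwise a data.frame
#'   with one row per class.
#' @export
precision_recall <- function(cm, cls = NULL) {
  cm <- as.matrix(cm)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  prec[colSums(cm) == 0] <- NA_real_
  rec[rowSums(cm) == 0] <- NA_real_
  if (!is.null(cls)) {
    if (!cls %in% rownames(cm)) stop("unknown class: ", cls)
    return(c(precision = unname(prec[cls]), recall = unname(rec[cls])))
  }
  data.frame(class = rownames(cm), precision = unname(prec),
             recall = unname(rec), row.names = NULL)
}

#' Overall accuracy
#'
#' Multiclass accuracy is the trace over the grand total (equivalent to the
#' one-vs-rest TP+TN aggregate form).
#'
#' @param cm Confusion matrix with positive total.
#' @return Proportion correct in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` where `po` is the
#' observed accuracy and `pe` the expected agreement under independent
#' margins. Degenerate matrices with `pe = 1` yield `NA`.
#'
#' @param cm Confusion matrix with positive total.
#' @return Kappa value (at most 1), or `NA` when undefined.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Full metric report for a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return List with `per_class` (precision/recall data.frame), `accuracy`,
#'   `kappa`, and the agreement components `po`, `pe`.
#' @export
metric_report <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  list(per_class = precision_recall(cm), accuracy = accuracy(cm),
       kappa = cohen_kappa(cm), po = accuracy(cm), pe = pe)
}

# stratified fold assignment: within each class, records are shuffled and
# dealt round-robin, so per-class fold sizes differ by at most one
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Cross-validated SMOTE + C4.5 evaluation
#'
#' Stratified k-fold cross-validation of the balanced C4.5 classifier.
#' With `paper_mode = TRUE` the imbalance gate and SMOTE run once on the full
#' table before folding (synthetic records then join every training fold);
#' the default applies SMOTE inside each training fold only, so no synthetic
#' neighbor information crosses fold boundaries. Synthetic records never
#' enter a test fold in either mode.
#'
#' @param table Labeled cohort data.frame.
#' @param tree_cfg A [tree_config()].
#' @param balance_cfg A [balance_config()], or `NULL` to skip balancing.
#' @param folds Number of folds (>= 2); reduced with a warning when the
#'   rarest class has fewer records.
#' @param seed RNG seed for fold assignment and balancing.
#' @param paper_mode Apply SMOTE before folding instead of per fold.
#' @param prune Prune each fold's tree before prediction.
#' @return List with the pooled out-of-fold `confusion` matrix, the metric
#'   `report`, the fold count used, and the effective record count.
#' @export
cross_validate <- function(table, tree_cfg = tree_config(),
                           balance_cfg = balance_config(),
                           folds = 10L, seed = 1L, paper_mode = FALSE,
                           prune = TRUE) {
  if (folds < 2) stop("folds must be at least 2")
  validate_cohort(table, require_risk = TRUE)
  counts <- class_counts(table)
  min_cls <- min(counts[counts > 0])
  if (min_cls < folds) {
    folds <- max(2L, as.integer(min_cls))
    warning("rarest class smaller than fold count; using ", folds, " folds")
  }
  table$.synthetic <- NULL
  synthetic_pool <- NULL
  if (paper_mode && !is.null(balance_cfg)) {
    balance_cfg$seed <- seed
    balanced <- smote_nominal(table, balance_cfg)
    synthetic_pool <- balanced$table[balanced$table$.synthetic, , drop = FALSE]
    table <- balanced$table[!balanced$table$.synthetic, , drop = FALSE]
  }
  fold_of <- stratified_folds(table$risk, folds, seed)
  actual <- character(0)
  predicted <- character(0)
  for (k in seq_len(folds)) {
    train <- table[fold_of != k, , drop = FALSE]
    test <- table[fold_of == k, , drop = FALSE]
    if (paper_mode && !is.null(synthetic_pool)) {
      train <- rbind(train, synthetic_pool)
    } else if (!is.null(balance_cfg)) {
      fold_cfg <- balance_cfg
      fold_cfg$seed <- seed + k
      train <- smote_nominal(train, fold_cfg)$table
    }
    tree <- grow_tree(train, tree_cfg, prune = prune)
    actual <- c(actual, test$risk)
    predicted <- c(predicted, predict(tree, test))
  }
  cm <- confusion_from_predictions(actual, predicted)
  list(confusion = cm, report = metric_report(cm), folds = folds,
       n = nrow(table))
}
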