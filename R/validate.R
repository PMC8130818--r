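#' 3x3 confusion matrix with fixed class order
#'
#' Rows index the gold label, columns the predicted label, both in the fixed
#' order positive, neutral, negative.
#'
#' @param gold,predicted label vectors in [sentiment_levels()].
#' @return integer 3x3 matrix.
#' @export
confusion_matrix3 <- function(gold, predicted) {
  lv <- sentiment_levels()
  bad <- setdiff(unique(c(gold, predicted)), c(lv, NA))
  if (length(bad)) stop("unknown sentiment label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(gold, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(m), 3, 3, dimnames = list(gold = lv, predicted = lv))
  m
}

# one-vs-rest sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) per class
class_metrics <- function(cm) {
  lv <- rownames(cm)
  total <- sum(cm)
  sens <- numeric(length(lv)); spec <- numeric(length(lv))
  for (k in seq_along(lv)) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  list(sensitivity = stats::setNames(sens, lv),
       specificity = stats::setNames(spec, lv))
}

#' Validate a scored corpus against its gold labels
#'
#' Builds the 3x3 confusion matrix (gold in rows, predictions in columns,
#' fixed class order positive/neutral/negative) and the per-class one-vs-rest
#' sensitivity and specificity, plus accuracy and macro-averaged recall (the
#' tuning objective).
#'
#' @param scored scored corpus in which every row has a `gold_label`.
#' @param predicted_column which label column to validate (default
#'   `"final_label"`; use `"lexicon_label"` or `"contextual_label"` to
#'   validate a single channel).
#' @return object of class `sentiment_confusion`: list with `matrix`,
#'   `sensitivity`, `specificity`, `accuracy`, `macro_recall`, `n`.
#' @export
validate_scored <- function(scored, predicted_column = "final_label") {
  if (!predicted_column %in% names(scored))
    stop("validate_scored: no column '", predicted_column, "'")
  keep <- !is.na(scored[[predicted_column]])
  scored <- scored[keep, , drop = FALSE]
  if (any(is.na(scored$gold_label)))
    stop("validate_scored: every scored post must carry a gold_label")
  cm <- confusion_matrix3(scored$gold_label, scored[[predicted_column]])
  met <- class_metrics(cm)
  out <- list(matrix = cm,
              sensitivity = met$sensitivity,
              specificity = met$specificity,
              accuracy = sum(diag(cm)) / sum(cm),
              macro_recall = mean(met$sensitivity, na.rm = TRUE),
              n = sum(cm))
  class(out) <- "sentiment_confusion"
  out
}

#' @export
print.sentiment_confusion <- function(x, digits = 3, ...) {
  cat(sprintf("Confusion matrix (n = %d; gold in rows)\n", x$n))
  print(x$matrix)
  tab <- rbind(sensitivity = x$sensitivity, specificity = x$specificity)
  cat("\nOne-vs-rest per class:\n")
  print(round(tab, digits))
  cat(sprintf("\naccuracy = %.*f, macro recall = %.*f\n",
              digits, x$accuracy, digits, x$macro_recall))
  invisible(x)
}

#' Write / read a confusion matrix as 3x3 delimited text
#'
#' @param confusion a `sentiment_confusion` or bare 3x3 matrix.
#' @param path output file.
#' @return `path` invisibly (`write_confusion`); an integer matrix
#'   (`read_confusion`).
#' @export
write_confusion <- function(confusion, path) {
  m <- if (inherits(confusion, "sentiment_confusion")) confusion$matrix else confusion
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gold = rownames(df), predicted = colnames(df))
  m
}
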