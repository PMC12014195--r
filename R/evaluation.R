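# Scoring predicted FST classes against ground truth. Ground truth in the
# intended workflow comes from ITA readings of a colorimeter converted with
# ita_to_fst(); predictions come from classify_image(). The FST scale is
# ordinal, so alongside exact agreement we report tolerance accuracy: the
# share of predictions within +/- t classes of truth (clinically, +/-1 is
# the accepted margin).

#' Confusion matrix over the six FST classes
#'
#' Rows are truth, columns are prediction (fixed orientation, documented).
#'
#' @param data A data frame with columns `true_fst` and `predicted_fst`
#'   (integers 1..6); an `image_id` column, if present, must be unique.
#' @return A 6 x 6 integer matrix with dimnames `truth`/`predicted`.
#' @export
confusion_matrix <- function(data) {
  data <- validate_predictions(data)
  m <- table(factor(data$true_fst, levels = 1:6),
             factor(data$predicted_fst, levels = 1:6))
  m <- matrix(as.integer(m), 6L, 6L,
              dimnames = list(truth = 1:6, predicted = 1:6))
  m
}

validate_predictions <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("no prediction records", call. = FALSE)
  for (col in c("true_fst", "predicted_fst")) {
    if (is.null(data[[col]])) {
      stop("predictions need a '", col, "' column", call. = FALSE)
    }
    v <- data[[col]]
    if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 1 | v > 6)) {
      stop("'", col, "' must contain integer FST classes in 1..6",
           call. = FALSE)
    }
    data[[col]] <- as.integer(v)
  }
  if (!is.null(data$image_id) && anyDuplicated(data$image_id)) {
    stop("image_id values must be unique", call. = FALSE)
  }
  data
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy is `trace/sum`. Per-class precision is `diag/colsum` (0 when the
#' class was never predicted), recall is `diag/rowsum`, and F1 their harmonic
#' mean. With `average = "macro"` (default) the per-class values are averaged
#' unweighted over the classes present in truth (classes absent from truth
#' are excluded, avoiding undefined recall on small cohorts);
#' `average = "micro"` pools counts, which for single-label classification
#' makes precision, recall and F1 all equal accuracy.
#'
#' @param confusion A 6 x 6 count matrix, rows = truth.
#' @param average `"macro"` or `"micro"`.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(confusion, average = c("macro", "micro")) {
  average <- match.arg(average)
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m))
  if (sum(m) == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- sum(diag(m)) / sum(m)
  if (average == "micro") {
    return(tibble::tibble(accuracy = acc, precision = acc, recall = acc,
                          f1 = acc))
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  present <- which(rs > 0)
  prec <- ifelse(cs == 0, 0, diag(m) / cs)
  rec <- ifelse(rs == 0, 0, diag(m) / rs)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  tibble::tibble(accuracy = acc,
                 precision = mean(prec[present]),
                 recall = mean(rec[present]),
                 f1 = mean(f1[present]))
}

#' Tolerance accuracy of ordinal FST predictions
#'
#' Fraction of records with `|predicted - true| <= tolerance`. At
#' `tolerance = 0` this equals exact accuracy; it is non-decreasing in the
#' tolerance and reaches 1 at tolerance 5.
#'
#' @inheritParams confusion_matrix
#' @param tolerance Non-negative integer band width.
#' @return A single number in `[0, 1]`.
#' @export
tolerance_accuracy <- function(data, tolerance = 1L) {
  if (length(tolerance) != 1L || is.na(tolerance) || tolerance < 0) {
    stop("tolerance must be a non-negative integer", call. = FALSE)
  }
  data <- validate_predictions(data)
  mean(abs(data$predicted_fst - data$true_fst) <= tolerance)
}

#' Full evaluation of FST predictions against ground truth
#'
#' Bundles the confusion matrix, exact metrics and tolerance accuracy into
#' one report object with [tidy()], [glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams confusion_matrix
#' @param tolerance Tolerance band for the tolerance accuracy (default 1).
#' @param average Averaging mode for [classification_metrics()].
#' @return An object of class `fst_evaluation`.
#' @export
evaluate_predictions <- function(data, tolerance = 1L, average = "macro") {
  data <- validate_predictions(data)
  confusion <- confusion_matrix(data)
  metrics <- classification_metrics(confusion, average = average)
  structure(
    list(confusion = confusion,
         metrics = metrics,
         tolerance = as.integer(tolerance),
         tolerance_accuracy = tolerance_accuracy(data, tolerance),
         n = nrow(data), average = average),
    class = "fst_evaluation"
  )
}

#' @export
print.fst_evaluation <- function(x, ...) {
  cat("<fst_evaluation> n = ", x$n, "\n", sep = "")
  cat(sprintf("  accuracy %.3f | precision %.3f | recall %.3f | f1 %.3f (%s)\n",
              x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
              x$metrics$f1, x$average))
  cat(sprintf("  tolerance +/-%d accuracy %.3f\n", x$tolerance,
              x$tolerance_accuracy))
  invisible(x)
}

#' Confusion matrix of an evaluation in long form
#'
#' @param x An `fst_evaluation` object.
#' @param ... Unused.
#' @return Tibble with columns `true_fst`, `predicted_fst`, `n`.
#' @method tidy fst_evaluation
#' @export
tidy.fst_evaluation <- function(x, ...) {
  tibble::tibble(
    true_fst = rep(1:6, times = 6),
    predicted_fst = rep(1:6, each = 6),
    n = as.integer(x$confusion)
  )
}

#' One-row summary of an evaluation
#'
#' @param x An `fst_evaluation` object.
#' @param ... Unused.
#' @return One-row tibble with the four metrics, `tolerance_accuracy`,
#'   `tolerance` and `n`.
#' @method glance fst_evaluation
#' @export
glance.fst_evaluation <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(tolerance_accuracy = x$tolerance_accuracy,
                                  tolerance = x$tolerance, n = x$n))
}
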