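#' One-vs-rest confusion counts
#'
#' Per-class TP/FP/FN/TN tallies treating each class in turn as positive.
#' For every class the four counts sum to the number of samples, and the
#' TP counts sum to the number of correct predictions.
#'
#' @param y_true,y_pred Integer class indices in `1..n`.
#' @param n Number of categories.
#' @return A `critens_confusion` object: tibble with columns `class`,
#'   `tp`, `fp`, `fn`, `tn` and attribute `total`.
#' @export
confusion_counts <- function(y_true, y_pred, n) {
  stopifnot(length(y_true) == length(y_pred), n >= 1)
  if (length(y_true) > 0 &&
      (any(y_true < 1 | y_true > n) || any(y_pred < 1 | y_pred > n)))
    stop("label outside 1..n")
  total <- length(y_true)
  tab <- table(factor(y_true, levels = seq_len(n)),
               factor(y_pred, levels = seq_len(n)))
  tp <- as.integer(diag(tab))
  fp <- as.integer(colSums(tab)) - tp
  fn <- as.integer(rowSums(tab)) - tp
  out <- tibble::tibble(class = seq_len(n), tp = tp, fp = fp, fn = fn,
                        tn = total - tp - fp - fn)
  attr(out, "total") <- total
  class(out) <- c("critens_confusion", class(out))
  out
}

#' Accuracy, macro precision/recall/F1 from confusion counts
#'
#' Accuracy is the fraction of correct predictions (`sum TP / total`,
#' the multiclass reading of the one-vs-rest accuracy formula). Per-class
#' precision `TP/(TP+FP)` and recall `TP/(TP+FN)` are macro-averaged over
#' all `n` schema classes; macro F1 is `(1/n) * sum 2PR/(P+R)` with the
#' per-class values. A class with an undefined quantity (zero denominator)
#' scores 0 for it — the standard convention under severe imbalance, which
#' means classes absent from both truth and prediction pull the macro
#' scores down.
#'
#' @param counts A [confusion_counts()] result.
#' @return List with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, and a `per_class` tibble.
#' @export
compute_metrics <- function(counts) {
  total <- attr(counts, "total")
  if (is.null(total) || total == 0) stop("empty confusion counts")
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(accuracy = sum(counts$tp) / total,
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1),
       per_class = tibble::tibble(class = counts$class, precision = precision,
                                  recall = recall, f1 = f1))
}

#' Evaluate predictions on a corpus split
#'
#' @param y_true,y_pred Integer class indices.
#' @param n Number of categories.
#' @return The [compute_metrics()] report.
#' @export
evaluate_predictions <- function(y_true, y_pred, n) {
  compute_metrics(confusion_counts(y_true, y_pred, n))
}

#' Paired t-test between two models' per-class scores
#'
#' Two-sided paired t-test on the differences of matched score vectors
#' (e.g. per-class F1 of two models over the same categories). If the
#' differences have (numerically) zero variance the statistic degenerates:
#' identical vectors give `t = 0, p = 1`; a constant non-zero shift gives
#' `t = +/-Inf, p = 0` (guarded at standard deviation `< 1e-12`).
#'
#' @param scores_a,scores_b Equal-length numeric score vectors (length
#'   >= 2).
#' @return List with `statistic` and `p_value`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("score vectors differ in length")
  if (length(scores_a) < 2) stop("need at least 2 paired scores")
  d <- scores_a - scores_b
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}
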