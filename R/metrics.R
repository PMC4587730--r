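#' Binary classification performance measures
#'
#' Accuracy, precision, recall and the Matthews correlation coefficient
#' (MCC) from the four binary confusion counts:
#' \deqn{Accu = \frac{tp+tn}{tp+fn+fp+tn},\quad
#'       Prec = \frac{tp}{tp+fp},\quad
#'       Rec  = \frac{tp}{tp+fn},}
#' \deqn{MCC = \frac{tp\,tn - fp\,fn}
#'   {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}.}
#'
#' A metric whose denominator is zero is returned as `NA`; the MCC with a
#' zero denominator is returned as 0 by convention and the row is flagged
#' `degenerate`.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `mcc`,
#'   `degenerate`.
#' @examples
#' binary_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
#' binary_metrics(tp = 0, tn = 0, fp = 5, fn = 5) # mcc = -1
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("tp, tn, fp, fn must be non-negative integers")
  }
  n <- tp + tn + fp + fn
  accuracy <- if (n > 0) (tp + tn) / n else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble(accuracy = accuracy, precision = precision, recall = recall,
         mcc = mcc, degenerate = degenerate)
}

#' Confusion matrix of true vs predicted labels
#'
#' Entry (i, j) counts items of true class i predicted as class j.
#'
#' @param y_true,y_pred Equal-length label vectors (values in `classes`).
#' @param classes Ordered class vocabulary.
#' @return A K x K integer matrix with `classes` dimnames.
#' @examples
#' confusion(c("a", "b", "b"), c("a", "b", "a"), classes = c("a", "b"))
#' @export
confusion <- function(y_true, y_pred, classes) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) {
    abort(sprintf("label(s) outside the class vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  m <- table(true = ft, predicted = fp)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Multi-class performance measures from a confusion matrix
#'
#' Computes the overall accuracy (proportion of correctly classified
#' instances, trace/N), the averaged per-class binary accuracy, the
#' generalized multi-class MCC over all entries of the confusion matrix,
#' and per-class precision/recall/MCC from one-vs-rest binarization.
#'
#' The multi-class MCC is the correlation-style generalization
#' \deqn{MCC = \frac{N\,\mathrm{tr}(C) - \sum_k t_k p_k}
#'   {\sqrt{N^2 - \sum_k p_k^2}\,\sqrt{N^2 - \sum_k t_k^2}}}
#' with \eqn{t_k} the true-class row sums and \eqn{p_k} the predicted-class
#' column sums; it equals the term-by-term sum form over all matrix entries
#' and ranges from -1 (complete misclassification) through 0 (random
#' assignment) to 1 (perfect classification). A zero denominator (all mass
#' in one row or column) yields 0 with `degenerate = TRUE`.
#'
#' Two accuracy summaries are reported because the field uses both: the
#' headline `accuracy_overall` is trace/N; `accuracy_macro_binary` is the
#' mean over classes of the one-vs-rest binary accuracies, which counts
#' each item K times (once per binarization) and is systematically higher.
#'
#' @param C K x K confusion matrix (see [confusion()]).
#' @return A list with `accuracy_overall`, `accuracy_macro_binary`,
#'   `mcc_multiclass`, `degenerate` and a `per_class` tibble.
#' @examples
#' C <- diag(10L, 7L)
#' multiclass_metrics(C)$mcc_multiclass # 1
#' @export
multiclass_metrics <- function(C) {
  C <- unclass(as.matrix(C))
  if (nrow(C) != ncol(C) || nrow(C) < 2L) abort("C must be a K x K matrix, K >= 2")
  if (any(C < 0)) abort("confusion matrix entries must be non-negative")
  N <- sum(C)
  if (N == 0) abort("confusion matrix is all-zero")
  K <- nrow(C)
  classes <- rownames(C) %||% as.character(seq_len(K))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  tr <- sum(diag(C))
  num <- N * tr - sum(t_k * p_k)
  den <- sqrt(N^2 - sum(p_k^2)) * sqrt(N^2 - sum(t_k^2))
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else num / den
  per_class <- purrr::map_dfr(seq_len(K), function(i) {
    tp <- C[i, i]
    fn <- t_k[i] - tp
    fp <- p_k[i] - tp
    tn <- N - tp - fn - fp
    dplyr::bind_cols(tibble(class = classes[i]),
                     binary_metrics(tp, tn, fp, fn))
  })
  list(
    accuracy_overall = tr / N,
    accuracy_macro_binary = mean(per_class$accuracy),
    mcc_multiclass = mcc,
    degenerate = degenerate,
    per_class = per_class
  )
}
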