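#' Classification metrics from predictions and scores
#'
#' Computes accuracy, sensitivity, specificity, AUC and F1. For two classes
#' the positive class defaults to the higher (severer) class index; for more
#' than two classes, sensitivity, specificity and F1 are macro one-vs-rest
#' averages and AUC is the macro one-vs-rest AUC of the softmax scores.
#'
#' @param y_true Integer labels 1..C.
#' @param y_pred Integer predictions 1..C.
#' @param scores N x C matrix of class probabilities (rows sum to 1).
#' @param C Number of classes.
#' @param positive Positive class index for the binary case (default `C`).
#' @return List with `acc`, `sen`, `spe`, `auc`, `f1`, the per-class
#'   `recall` vector, and the `confusion` matrix (rows = true class).
#' @export
compute_metrics <- function(y_true, y_pred, scores, C, positive = NULL) {
  n <- length(y_true)
  assert_that(n >= 1, "empty input")
  assert_that(length(y_pred) == n, "y_true and y_pred lengths differ")
  assert_that(is.matrix(scores) && nrow(scores) == n && ncol(scores) == C,
              "scores must be an N x C matrix")
  assert_that(max(abs(rowSums(scores) - 1)) < 1e-6, "score rows must sum to 1")

  confusion <- table(factor(y_true, levels = seq_len(C)),
                     factor(y_pred, levels = seq_len(C)))
  confusion <- unclass(confusion)
  acc <- mean(y_true == y_pred)
  recall <- vapply(seq_len(C), function(c) {
    nc <- sum(y_true == c)
    if (nc == 0) NA_real_ else sum(y_true == c & y_pred == c) / nc
  }, numeric(1))

  ovr <- function(c) {
    tp <- sum(y_true == c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    fp <- sum(y_true != c & y_pred == c)
    tn <- sum(y_true != c & y_pred != c)
    sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    auc <- if (length(unique(y_true == c)) == 2) {
      as.numeric(pROC::auc(pROC::roc(response = y_true == c,
                                     predictor = scores[, c],
                                     quiet = TRUE, direction = "<",
                                     levels = c(FALSE, TRUE))))
    } else NA_real_
    c(sen = sen, spe = spe, f1 = f1, auc = auc)
  }

  if (C == 2) {
    pos <- positive %||% 2L
    m <- ovr(pos)
  } else {
    per <- vapply(seq_len(C), ovr, numeric(4))
    m <- rowMeans(per, na.rm = TRUE)
  }
  list(acc = acc, sen = unname(m["sen"]), spe = unname(m["spe"]),
       auc = unname(m["auc"]), f1 = unname(m["f1"]),
       recall = recall, confusion = confusion)
}
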