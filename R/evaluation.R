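#' Three-class confusion matrix
#'
#' Rows are the true class, columns the predicted class, in the fixed order
#' phage, chromosome, plasmid. Predicted labels carrying the `"uncertain "`
#' prefix are either excluded (`uncertain = "drop"`, mirroring evaluation on
#' the confidently labelled subset) or stripped to their class
#' (`uncertain = "strip"`).
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels (six categories
#'   allowed).
#' @param uncertain `"drop"` or `"strip"`.
#' @return 3 x 3 integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix3 <- function(truth, predicted, uncertain = c("drop", "strip")) {
  uncertain <- match.arg(uncertain)
  stopifnot(length(truth) == length(predicted))
  is_unc <- startsWith(predicted, "uncertain ")
  if (uncertain == "drop") {
    truth <- truth[!is_unc]
    predicted <- predicted[!is_unc]
  } else {
    predicted <- sub("^uncertain ", "", predicted)
  }
  bad <- unique(c(setdiff(truth, CLASSES), setdiff(predicted, CLASSES)))
  if (length(bad)) stop("labels outside the three classes: ",
                        paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = CLASSES),
             factor(predicted, levels = CLASSES))
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("truth", "predicted")
  m
}

# ROC curve by explicit threshold sweep over tie-grouped scores, then
# trapezoidal area. Ties therefore receive the diagonal (0.5) credit.
roc_auc <- function(scores, positive) {
  npos <- sum(positive)
  nneg <- sum(!positive)
  if (npos == 0 || nneg == 0)
    stop("AUC needs both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  last <- cumsum(rle(s)$lengths)      # one operating point per distinct score
  tpr <- c(0, cumsum(p)[last] / npos)
  fpr <- c(0, cumsum(!p)[last] / nneg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' One-vs-rest TPR, FPR and AUC for one class
#'
#' TPR = TP / (TP + FN) and FPR = FP / (TN + FP) are computed from the
#' argmax labels of the score triples; the AUC ranks the positive class's
#' score against all other fragments (trapezoidal ROC, ties receiving half
#' credit).
#'
#' @param truth character vector of true labels.
#' @param scores `n x 3` matrix of (phage, chromosome, plasmid) scores.
#' @param positive_class the class treated as positive.
#' @return list with `class`, `TPR`, `FPR`, `AUC` (fractions in `[0, 1]`).
#' @export
one_vs_rest_metrics <- function(truth, scores, positive_class) {
  positive_class <- match.arg(positive_class, CLASSES)
  stopifnot(nrow(scores) == length(truth), ncol(scores) == 3)
  pos <- truth == positive_class
  if (!any(pos) || all(pos))
    stop("both positive and negative fragments are required")
  pred <- CLASSES[apply(scores, 1L, which.max)]
  tp <- sum(pos & pred == positive_class)
  fn <- sum(pos & pred != positive_class)
  fp <- sum(!pos & pred == positive_class)
  tn <- sum(!pos & pred != positive_class)
  k <- match(positive_class, CLASSES)
  list(class = positive_class,
       TPR = tp / (tp + fn),
       FPR = fp / (tn + fp),
       AUC = roc_auc(scores[, k], pos))
}

#' Metrics under a sweep of uncertainty thresholds
#'
#' For each threshold, fragments whose maximum score falls below it are
#' labelled uncertain; `uncertain_rate` is their fraction and the remaining
#' metrics (overall accuracy, one-vs-rest TPR/FPR for `positive_class`) are
#' computed on the certain subset only. Rows where every fragment is
#' uncertain carry `NA` metrics.
#'
#' @param truth character vector of true labels.
#' @param scores `n x 3` score matrix.
#' @param thresholds numeric vector in `[0, 1]`.
#' @param positive_class class for the TPR/FPR columns (default phage).
#' @return data frame with columns `threshold`, `uncertain_rate`,
#'   `accuracy`, `TPR`, `FPR`.
#' @export
threshold_sweep <- function(truth, scores, thresholds,
                            positive_class = "phage") {
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be in [0, 1]")
  positive_class <- match.arg(positive_class, CLASSES)
  rows <- lapply(thresholds, function(th) {
    lab <- label_with_threshold(scores, th)
    unc <- startsWith(lab, "uncertain ")
    rate <- mean(unc)
    if (all(unc)) {
      return(data.frame(threshold = th, uncertain_rate = rate,
                        accuracy = NA_real_, TPR = NA_real_, FPR = NA_real_))
    }
    t2 <- truth[!unc]
    s2 <- scores[!unc, , drop = FALSE]
    acc <- mean(CLASSES[apply(s2, 1L, which.max)] == t2)
    pos <- t2 == positive_class
    pred_pos <- CLASSES[apply(s2, 1L, which.max)] == positive_class
    tpr <- if (any(pos)) sum(pos & pred_pos) / sum(pos) else NA_real_
    fpr <- if (any(!pos)) sum(!pos & pred_pos) / sum(!pos) else NA_real_
    data.frame(threshold = th, uncertain_rate = rate, accuracy = acc,
               TPR = tpr, FPR = fpr)
  })
  do.call(rbind, rows)
}

#' Lifestyle and transmissibility score transforms
#'
#' Two normalised contrasts of a score triple:
#' `life_score = (phage - chromosome) / phage` and
#' `trans_score = (plasmid - chromosome) / plasmid`. A low life score marks
#' phages whose composition has drifted toward the host (temperate-like); a
#' low trans score marks host-adapted (non-transmissible-like) plasmids.
#' Zero denominators yield `NA` with the corresponding `*_defined` flag set
#' to `FALSE` rather than an error.
#'
#' @param scores numeric vector of 3 scores or an `n x 3` matrix.
#' @return data frame with columns `life_score`, `trans_score`,
#'   `life_defined`, `trans_defined`.
#' @export
derived_scores <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(ncol(scores) == 3)
  ph <- scores[, 1]; ch <- scores[, 2]; pl <- scores[, 3]
  life_ok <- ph != 0
  trans_ok <- pl != 0
  data.frame(
    life_score = ifelse(life_ok, (ph - ch) / ph, NA_real_),
    trans_score = ifelse(trans_ok, (pl - ch) / pl, NA_real_),
    life_defined = life_ok,
    trans_defined = trans_ok
  )
}

#' Write evaluation artifacts to plain-text files
#'
#' @param cm 3 x 3 confusion matrix.
#' @param metrics list of per-class metric lists from
#'   [one_vs_rest_metrics()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(cm, metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cm, file.path(dir, "confusion_matrix.txt"),
                     sep = "\t", quote = FALSE, col.names = NA)
  mt <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(class = m$class, TPR = m$TPR, FPR = m$FPR, AUC = m$AUC)
  }))
  utils::write.table(mt, file.path(dir, "class_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
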