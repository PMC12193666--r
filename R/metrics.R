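#' Build a 2x2 confusion matrix
#'
#' Either cross-tabulate binary truth and prediction vectors, or supply the
#' four cell counts directly. The positive class is 1 (methylated).
#'
#' @param truth,predicted Integer 0/1 vectors of equal length.
#' @return An object of class `"meth_confusion"`: a named list with integer
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  confusion_counts(tp = sum(truth == 1 & predicted == 1),
                   tn = sum(truth == 0 & predicted == 0),
                   fp = sum(truth == 0 & predicted == 1),
                   fn = sum(truth == 1 & predicted == 0))
}

#' @rdname confusion_matrix
#' @param tp,tn,fp,fn Nonnegative cell counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(cells < 0)) stop("confusion-matrix cells must be nonnegative",
                           call. = FALSE)
  cells <- as.list(cells)
  structure(lapply(cells, function(v) as.integer(round(v))),
            class = "meth_confusion")
}

#' @export
print.meth_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Threshold classification metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (recall), specificity, Matthews correlation
#' coefficient, precision and F1:
#' \deqn{ACC = (TP+TN)/N,\quad SE = TP/(TP+FN),\quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' \deqn{Precision = TP/(TP+FP),\quad F1 = TP/(TP + \tfrac12(FP+FN))}
#' A metric whose denominator is zero is reported as 0 and its name recorded
#' in the `zero_denominator` attribute, so degenerate confusion matrices in
#' small experiments do not abort an evaluation.
#'
#' @param cm A [confusion_matrix()] / [confusion_counts()] object.
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `precision`, `f1`, plus attribute
#'   `zero_denominator` (character vector of flagged metrics).
#' @examples
#' compute_metrics(confusion_counts(tp = 2030, tn = 2546, fp = 74, fn = 449))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "meth_confusion"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  n <- tp + tn + fp + fn
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  flagged <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  mcc_den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  out <- tibble::tibble(
    accuracy    = (tp + tn) / n,
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    mcc         = safe(tp * tn - fp * fn, sqrt(mcc_den2), "mcc"),
    precision   = safe(tp, tp + fp, "precision"),
    f1          = safe(tp, tp + 0.5 * (fp + fn), "f1")
  )
  attr(out, "zero_denominator") <- flagged
  out
}

#' ROC curve and area under it
#'
#' The AUROC equals the probability that a randomly chosen positive receives
#' a higher score than a randomly chosen negative, with ties counted one
#' half. The curve walks thresholds from high to low, grouping tied scores,
#' so the trapezoidal area under the exported points equals the pairwise
#' definition exactly.
#'
#' @param truth Integer 0/1 vector (1 = positive class); both classes must
#'   be present.
#' @param scores Finite numeric scores, higher = more positive.
#' @return `roc_curve()`: an object of class `"meth_roc"` — a list with
#'   `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`. `auroc()` returns
#'   the area alone.
#' @export
roc_curve <- function(truth, scores) {
  check_scores(truth, scores)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); fp <- cumsum(n_g - tp_g)
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  pts <- tibble::tibble(
    threshold = c(Inf, as.numeric(tapply(s, grp, `[`, 1))),
    fpr = c(0, as.numeric(fp) / n_neg),
    tpr = c(0, as.numeric(tp) / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "meth_roc")
}

#' @rdname roc_curve
#' @export
auroc <- function(truth, scores) {
  check_scores(truth, scores)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve and area under it
#'
#' Walks thresholds from high to low (tied scores grouped) and integrates the
#' precision-recall step curve: area = sum of precision times recall
#' increment at each threshold, the average-precision convention.
#'
#' @inheritParams roc_curve
#' @return `pr_curve()`: an object of class `"meth_pr"` — a list with
#'   `points` (tibble `threshold`, `recall`, `precision`) and `auc`.
#'   `auprc()` returns the area alone.
#' @export
pr_curve <- function(truth, scores) {
  check_scores(truth, scores)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); pred_pos <- cumsum(n_g)
  n_pos <- sum(truth == 1)
  recall <- tp / n_pos
  precision <- tp / pred_pos
  auc <- sum(diff(c(0, recall)) * precision)
  pts <- tibble::tibble(
    threshold = as.numeric(tapply(s, grp, `[`, 1)),
    recall = as.numeric(recall),
    precision = as.numeric(precision)
  )
  structure(list(points = pts, auc = auc), class = "meth_pr")
}

#' @rdname pr_curve
#' @export
auprc <- function(truth, scores) pr_curve(truth, scores)$auc

check_scores <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(truth)) < 2) {
    stop("both classes must be present to compute a ranking curve",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Chi-square test of independence on a 2x2 agreement table
#'
#' Tests whether observed labels and predicted labels are associated.
#' Expected cells come from the row/column marginals under independence;
#' the statistic is \eqn{\chi^2 = \sum (O_{ij}-E_{ij})^2/E_{ij}} with
#' \eqn{df = (rows-1)(cols-1) = 1} and p-value from the upper tail of the
#' chi-square distribution. No continuity correction is applied. For a 2x2
#' table the statistic satisfies the identity \eqn{\chi^2 = N \cdot MCC^2}.
#'
#' @param cm A [confusion_matrix()] object (observed vs predicted).
#' @return One-row tibble with columns `chi2`, `df`, `p_value`.
#' @export
chi_square_test <- function(cm) {
  stopifnot(inherits(cm, "meth_confusion"))
  obs <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    stop("chi-square test undefined: a marginal total is zero ",
         "(an expected cell would be 0)", call. = FALSE)
  }
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - expected)^2 / expected)
  tibble::tibble(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cohen's kappa on a 2x2 agreement table
#'
#' Chance-corrected agreement between observed and predicted labels:
#' \eqn{\kappa = (P_o - P_e)/(1 - P_e)} where \eqn{P_o} is the observed
#' agreement (accuracy) and \eqn{P_e} the chance agreement from the marginal
#' proportions, summed over both classes. A degenerate table with
#' \eqn{P_e = 1} (all mass in one row and one column) leaves kappa undefined;
#' it is returned as `NA` with the `kappa_undefined` attribute set.
#'
#' @param cm A [confusion_matrix()] object.
#' @return One-row tibble with columns `kappa`, `po`, `pe`.
#' @examples
#' cohens_kappa(confusion_counts(tp = 2030, tn = 2546, fp = 74, fn = 449))
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "meth_confusion"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  n <- tp + tn + fp + fn
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((tn + fn) / n) * ((tn + fp) / n)
  out <- tibble::tibble(
    kappa = if (pe >= 1) NA_real_ else (po - pe) / (1 - pe),
    po = po, pe = pe
  )
  attr(out, "kappa_undefined") <- pe >= 1
  out
}

#' Plot ROC / precision-recall curves
#'
#' @param object A `"meth_roc"` or `"meth_pr"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUROC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.meth_roc
#' @export
autoplot.meth_pr <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Precision-recall curve (AUPRC = %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
print.meth_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUROC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
print.meth_pr <- function(x, ...) {
  cat("Precision-recall curve:", nrow(x$points), "points, AUPRC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}
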