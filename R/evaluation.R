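# Coerce a truth/prediction column to logical "is interacting".
as_interacting <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0)
  x <- as.character(x)
  ok <- x %in% c("interacting", "non-interacting")
  if (!all(ok)) {
    abort(sprintf("labels must be 'interacting'/'non-interacting', got '%s'",
                  x[!ok][1]))
  }
  x == "interacting"
}

label_levels <- c("interacting", "non-interacting")

mcc_counts <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Rank-based (Mann-Whitney) ROC area with tie correction: midranks make
# tied scores contribute 1/2, matching the trapezoidal ROC area.
rank_auc <- function(truth, scores) {
  pos <- as_interacting(truth)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for a set of scored protein pairs
#'
#' Computes the seven evaluation measures -- TPR, FPR, precision, accuracy,
#' F-score, MCC and AUC -- from hard predictions (thresholded probabilities)
#' and the rank-based ROC area of the scores. Ratios with empty denominators
#' (e.g. precision with no positive predictions) are reported as 0 and named
#' in the `flags` column rather than aborting the run.
#'
#' @param data Data frame with a truth column, a probability/score column
#'   and optionally a hard-prediction column.
#' @param truth,prob,estimate Column names (character) for the true label,
#'   the interacting-class score, and the predicted label. When `estimate`
#'   is `NULL`, predictions are `prob >= threshold`.
#' @param threshold Decision threshold used when `estimate` is absent.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `tpr`, `fpr`,
#'   `precision`, `accuracy`, `f_score`, `mcc`, `auc`, `flags`.
#' @export
#' @examples
#' compute_metrics(tibble::tibble(
#'   truth = c(1, 1, 0, 0), prob = c(.9, .4, .6, .1)))
compute_metrics <- function(data, truth = "truth", prob = "prob",
                            estimate = NULL, threshold = 0.5) {
  y <- as_interacting(data[[truth]])
  p <- data[[prob]]
  yhat <- if (is.null(estimate)) p >= threshold else
    as_interacting(data[[estimate]])
  tp <- sum(y & yhat); tn <- sum(!y & !yhat)
  fp <- sum(!y & yhat); fn <- sum(y & !yhat)
  flags <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  tpr <- ratio(tp, tp + fn, "tpr")
  fpr <- ratio(fp, fp + tn, "fpr")
  prec <- ratio(tp, tp + fp, "precision")
  acc <- ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  f <- ratio(2 * tpr * prec, tpr + prec, "f_score")
  auc <- rank_auc(y, p)
  if (is.na(auc)) flags <- c(flags, "auc")
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         tpr = tpr, fpr = fpr, precision = prec, accuracy = acc,
         f_score = f, mcc = mcc_counts(tp, tn, fp, fn),
         auc = auc, flags = paste(flags, collapse = ","))
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `folds` disjoint folds, preserving the
#' class ratio within one instance per class.
#'
#' @param labels Vector of class labels.
#' @param folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(labels, folds, seed = 1L) {
  y <- as_interacting(labels)
  if (min(table(y)) < folds) {
    abort(sprintf("smallest class has %d instances; cannot stratify into %d folds",
                  min(table(y)), folds))
  }
  out <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Paired t-test between two metric series
#'
#' Two-sided paired t-test on per-fold metric values obtained under identical
#' fold assignments. Zero-variance differences (e.g. identical series) give
#' p = 1 with a flag instead of an error.
#'
#' @param a,b Equal-length numeric vectors of paired per-fold metrics.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble: `estimate` (mean difference a - b), `statistic`,
#'   `p_value`, `significant`, `flag`.
#' @export
paired_metric_test <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (sd(d) == 0) {
    return(tibble(estimate = mean(d), statistic = NA_real_, p_value = 1,
                  significant = FALSE, flag = "zero-variance differences"))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p_value = tt$p.value, significant = tt$p.value < alpha, flag = "")
}
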