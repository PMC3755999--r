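#' Log joint-density difference between the two group models
#'
#' For each subject, `joint_log_density(bn_ad) - joint_log_density(bn_nc)`:
#' positive values favour AD membership. Each model applies its own stored
#' standardization, so models fitted on one cohort can score another.
#'
#' @param bn_nc,bn_ad Fitted `gaussian_bn` models over the same ROIs.
#' @param table Volume table (or data.frame with the ROI columns).
#' @return Numeric vector, one score per row.
#' @export
log_density_difference <- function(bn_nc, bn_ad, table) {
  if (!setequal(bn_nc$structure$nodes, bn_ad$structure$nodes)) {
    stop("the two models are fitted on different ROI sets")
  }
  joint_log_density(bn_ad, table) - joint_log_density(bn_nc, table)
}

#' Classify subjects by joint-density comparison
#'
#' A subject is labelled `"AD"` when its log-density difference exceeds the
#' threshold and `"NC"` otherwise; exact ties go to `"NC"`. With threshold
#' 0 this is the Bayes rule under equal class priors. Unequal priors can be
#' expressed through `priors`, which shifts the effective threshold by
#' `log(prior_nc / prior_ad)`.
#'
#' @param bn_nc,bn_ad Fitted `gaussian_bn` models.
#' @param table Volume table of subjects to classify.
#' @param threshold Decision threshold on the log-density difference.
#' @param priors Optional length-2 named numeric vector of class priors
#'   (names `NC`, `AD`), normalized internally.
#' @return Character vector of `"NC"` / `"AD"` labels.
#' @export
classify_subjects <- function(bn_nc, bn_ad, table, threshold = 0,
                              priors = NULL) {
  scores <- log_density_difference(bn_nc, bn_ad, table)
  if (!is.null(priors)) {
    stopifnot(all(c("NC", "AD") %in% names(priors)), all(priors > 0))
    threshold <- threshold + log(priors[["NC"]] / priors[["AD"]])
  }
  ifelse(scores > threshold, "AD", "NC")
}

#' Confusion counts, rates and ROC curve of a classification
#'
#' AD is the positive class. The operating point uses `threshold`
#' (sensitivity = TP/(TP+FN) among AD, specificity = TN/(TN+FP) among NC,
#' accuracy = correct/total); the ROC curve is built by sweeping the
#' decision threshold over all observed scores, giving a step function
#' from (0,0) to (1,1), and the area under it is computed by the
#' rank-sum (Mann-Whitney) identity with ties counted one half.
#'
#' @param truth Character vector of true `"NC"`/`"AD"` labels.
#' @param scores Numeric log-density differences (higher favours AD).
#' @param threshold Operating-point threshold (default 0).
#' @return Object of class `classification_report`: confusion counts
#'   (`n_true_positive` etc.), `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `threshold`, and `roc_points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
evaluate_classifier <- function(truth, scores, threshold = 0) {
  if (length(truth) != length(scores)) {
    stop("'truth' and 'scores' must have equal length")
  }
  bad <- setdiff(unique(truth), c("NC", "AD"))
  if (length(bad)) stop("labels must be 'NC' or 'AD'; found: ",
                        paste(bad, collapse = ", "))
  pos <- truth == "AD"
  pred_pos <- scores > threshold
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)

  # ROC: thresholds at +Inf (nothing positive) down through each score
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) {
      if (sum(!pos) == 0L) return(0) ; sum(!pos & scores >= t) / sum(!pos)
    }, numeric(1)),
    tpr = vapply(thr, function(t) {
      if (sum(pos) == 0L) return(0) ; sum(pos & scores >= t) / sum(pos)
    }, numeric(1))
  )
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_

  structure(
    list(n_true_positive = tp, n_true_negative = tn,
         n_false_positive = fp, n_false_negative = fn,
         accuracy = (tp + tn) / length(truth),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         auc = auc, threshold = threshold, roc_points = roc),
    class = "classification_report"
  )
}

#' Write a classification report as JSON
#'
#' @param report A `classification_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "Classification (positive = AD): accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity, x$auc))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d  (threshold %g)\n",
              x$n_true_positive, x$n_false_negative,
              x$n_true_negative, x$n_false_positive, x$threshold))
  invisible(x)
}
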