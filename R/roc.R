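#' ROC curve for a prognostic score
#'
#' Builds the empirical ROC of a scalar score against binary outcome labels.
#' Candidate thresholds are the midpoints between adjacent distinct scores
#' plus `-Inf`/`+Inf` sentinels; a subject is called positive when its score
#' is greater than or equal to the threshold (higher score = positive
#' class). The area under the curve is computed by the trapezoid rule, which
#' gives tied scores one-half credit and equals the mid-rank Mann-Whitney
#' statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric vector of per-subject scores (e.g. post-3-hour
#'   FHR), optionally named by subject id.
#' @param labels character vector of class labels aligned with `scores`, or
#'   a data frame with columns `subject_id` and `label` (as returned by
#'   [assign_outcomes()]) matched to `scores` by name.
#' @param positive_class label treated as positive (default `"good"`:
#'   a higher forebrain-to-hindbrain ratio predicts a good outcome).
#' @return An object of class `roc_result`: descending `thresholds` with
#'   aligned `sensitivity` and `specificity`, `auc`, counts, and the inputs.
#' @examples
#' r <- roc_curve(c(2, 3, 0, 1), c("good", "good", "poor", "poor"))
#' r$auc  # 1
#' @export
roc_curve <- function(scores, labels, positive_class = "good") {
  if (is.data.frame(labels)) {
    if (is.null(names(scores)))
      stop("scores must be named by subject_id to match a label table")
    m <- match(names(scores), labels$subject_id)
    if (anyNA(m))
      stop("no outcome label for subject(s): ",
           paste(names(scores)[is.na(m)], collapse = ", "))
    labels <- labels$label[m]
  }
  labels <- as.character(labels)
  if (length(labels) != length(scores))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  is_pos <- labels == positive_class
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present (positive class '", positive_class,
         "': ", n_pos, " of ", length(labels), ")")
  s <- sort(unique(scores))
  thresholds <- c(Inf, rev(if (length(s) > 1)
    (s[-1] + s[-length(s)]) / 2 else numeric()), -Inf)
  sens <- vapply(thresholds, function(t) mean(scores[is_pos] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!is_pos] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 positive_class = positive_class,
                 direction = "greater-is-positive",
                 scores = scores, labels = labels,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: positive class '", x$positive_class, "' (", x$n_pos, " vs ",
      x$n_neg, "), higher score = positive\n", sep = "")
  cat("  AUC (trapezoid):", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The threshold maximizing the Youden index `J = sensitivity +
#' specificity - 1`. Ties are broken toward the largest cutoff, favoring
#' specificity for a positive (good-outcome) call. By default the reported
#' cutoff is the midpoint between adjacent observed scores; the
#' `"observed"` convention instead reports the smallest observed score that
#' is called positive at the optimum.
#'
#' @param roc a `roc_result`.
#' @param convention `"midpoint"` or `"observed"`.
#' @return List with `cutoff`, `j`, `sensitivity`, `specificity`,
#'   `convention`.
#' @examples
#' r <- roc_curve(c(1.74, 0.85), c("good", "poor"))
#' youden_cutoff(r)$cutoff  # 1.295, midpoint of the two scores
#' @export
youden_cutoff <- function(roc, convention = c("midpoint", "observed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- max(j)
  ## thresholds are stored descending; the first maximum is the largest cutoff
  i <- which(j == best)[1]
  cutoff <- roc$thresholds[i]
  if (convention == "observed" && is.finite(cutoff)) {
    called <- roc$scores[roc$scores >= cutoff]
    if (length(called)) cutoff <- min(called)
  }
  list(cutoff = cutoff, j = best,
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i],
       convention = convention)
}

#' Classify scores against a cutoff
#'
#' Scores greater than or equal to the cutoff are called positive
#' (boundary convention `>=`, consistent with [roc_curve()]).
#'
#' @param scores numeric vector, optionally named by subject id.
#' @param cutoff finite scalar threshold.
#' @param labels optional true labels (vector or [assign_outcomes()] table)
#'   for a confusion matrix and operating characteristics.
#' @param positive_class,negative_class class names used for calls.
#' @return List with `predicted` (character vector), and when `labels` are
#'   supplied: `confusion` (2x2 table, rows = predicted), `sensitivity`,
#'   `specificity` for the positive class, plus both-orientation operating
#'   characteristics in `by_class`.
#' @examples
#' classify(c(1.74, 0.85), cutoff = 1.22)$predicted  # "good" "poor"
#' @export
classify <- function(scores, cutoff, labels = NULL,
                     positive_class = "good", negative_class = "poor") {
  .assert_number(cutoff, "cutoff")
  predicted <- ifelse(scores >= cutoff, positive_class, negative_class)
  names(predicted) <- names(scores)
  out <- list(predicted = predicted, cutoff = cutoff,
              positive_class = positive_class)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      m <- match(names(scores), labels$subject_id)
      if (anyNA(m)) stop("no outcome label for some scored subjects")
      labels <- labels$label[m]
    }
    labels <- as.character(labels)
    classes <- c(positive_class, negative_class)
    confusion <- table(predicted = factor(predicted, classes),
                       truth = factor(labels, classes))
    tp <- confusion[positive_class, positive_class]
    tn <- confusion[negative_class, negative_class]
    fp <- confusion[positive_class, negative_class]
    fn <- confusion[negative_class, positive_class]
    out$confusion <- confusion
    out$sensitivity <- tp / (tp + fn)
    out$specificity <- tn / (tn + fp)
    ## the complementary orientation: treating the negative class as the
    ## condition of interest
    out$by_class <- data.frame(
      positive_class = classes,
      sensitivity = c(tp / (tp + fn), tn / (tn + fp)),
      specificity = c(tn / (tn + fp), tp / (tp + fn)))
  }
  out
}
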