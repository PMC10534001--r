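#' Two-by-two confusion matrix with SSc as the positive class
#'
#' @param truth,predicted Label vectors.
#' @param positive Positive-class label (default `"SSc"`).
#' @return Object of class `ppg_confusion`: integer counts `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "SSc") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  structure(list(tp = sum(truth == positive & predicted == positive),
                 fn = sum(truth == positive & predicted != positive),
                 fp = sum(truth != positive & predicted == positive),
                 tn = sum(truth != positive & predicted != positive),
                 positive = positive),
            class = "ppg_confusion")
}

#' @rdname confusion_matrix
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fn, fp, tn, positive = "SSc") {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
            class = "ppg_confusion")
}

#' @export
print.ppg_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Sum per-fold confusion matrices into a combined matrix
#'
#' The combined matrix over all cross-validation test folds is the basis for
#' the reported diagnostic metrics.
#'
#' @param cms List of `ppg_confusion` objects (at least one).
#' @return A `ppg_confusion` with elementwise-summed counts.
#' @export
combine_confusions <- function(cms) {
  if (length(cms) == 0) stop("need at least one confusion matrix")
  out <- cms[[1]]
  for (cm in cms[-1]) {
    out$tp <- out$tp + cm$tp
    out$fn <- out$fn + cm$fn
    out$fp <- out$fp + cm$fp
    out$tn <- out$tn + cm$tn
  }
  out
}

#' Majority vote over one participant's image predictions
#'
#' The participant's label is the class receiving more image-level
#' predictions. An exact tie goes to the positive (SSc) class - the
#' sensitivity-preserving direction, since missing a true SSc case costs
#' more than a false referral.
#'
#' @param predictions Character vector of image-level predicted labels for
#'   one participant (non-empty).
#' @param positive Positive-class label (default `"SSc"`).
#' @return Single predicted label.
#' @export
majority_vote <- function(predictions, positive = "SSc") {
  predictions <- as.character(predictions)
  if (length(predictions) == 0) stop("no image predictions to vote over")
  n_pos <- sum(predictions == positive)
  n_neg <- length(predictions) - n_pos
  if (n_pos >= n_neg) positive else names(sort(table(
    predictions[predictions != positive]), decreasing = TRUE))[1]
}

#' Aggregate image predictions to participant-level votes
#'
#' @param image_predictions Data frame with `participant_id`, `truth`,
#'   `predicted` (one row per image).
#' @param positive Positive-class label.
#' @return Data frame: `participant_id`, `truth`, `predicted` (one row per
#'   participant).
#' @export
participant_votes <- function(image_predictions, positive = "SSc") {
  sp <- split(image_predictions, image_predictions$participant_id)
  out <- lapply(sp, function(d)
    data.frame(participant_id = d$participant_id[1], truth = d$truth[1],
               predicted = majority_vote(d$predicted, positive),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Inverts the binomial tail probabilities through beta-distribution
#' quantiles; the lower bound is 0 when there are no successes and the upper
#' bound 100 when every trial succeeds. Coverage is conservative (at least
#' the nominal level).
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials > 0`.
#' @param alpha Two-sided error rate (default 0.05 for a 95 percent
#'   interval).
#' @return Numeric `(low, high)` in percent.
#' @export
#' @examples
#' exact_ci(15, 20)  # 50.9 - 91.3
exact_ci <- function(successes, trials, alpha = 0.05) {
  if (trials <= 0 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials with trials > 0")
  low <- if (successes == 0) 0
         else stats::qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1
          else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = 100 * low, high = 100 * high)
}

#' Round half away from zero
#'
#' Decimal rounding matching how the diagnostic tables are printed
#' (0.05 rounds up), unlike R's round-half-even default.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic-test metrics with exact 95 percent confidence intervals
#'
#' Accuracy `100 (tp + tn) / total`, sensitivity `100 tp / (tp + fn)` and
#' specificity `100 tn / (fp + tn)`, each with its Clopper-Pearson interval
#' on the underlying (successes, trials) pair. Values are stored at full
#' precision; the print method reports one decimal place, half-up.
#'
#' @param cm A `ppg_confusion`.
#' @param alpha Two-sided error rate for the intervals.
#' @return Object of class `ppg_metrics`: list of `accuracy`,
#'   `sensitivity`, `specificity`, each `(value, low, high)` in percent,
#'   plus the source counts.
#' @export
#' @examples
#' m <- metrics(confusion_counts(15, 5, 7, 44))
#' round_half_up(m$accuracy["value"])  # 83.1
metrics <- function(cm, alpha = 0.05) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (cm$tp + cm$fn == 0) stop("no positive-class cases")
  if (cm$fp + cm$tn == 0) stop("no negative-class cases")
  triple <- function(s, n) {
    ci <- exact_ci(s, n, alpha)
    c(value = 100 * s / n, low = unname(ci["low"]),
      high = unname(ci["high"]))
  }
  structure(list(accuracy = triple(cm$tp + cm$tn, total),
                 sensitivity = triple(cm$tp, cm$tp + cm$fn),
                 specificity = triple(cm$tn, cm$fp + cm$tn),
                 cm = cm),
            class = "ppg_metrics")
}

#' @export
print.ppg_metrics <- function(x, ...) {
  for (nm in c("accuracy", "sensitivity", "specificity")) {
    v <- round_half_up(x[[nm]], 1)
    cat(sprintf("%-12s %5.1f (%.1f-%.1f)\n", nm, v["value"], v["low"],
                v["high"]))
  }
  invisible(x)
}

#' Export crosshair-plot data (sensitivity versus false positive rate)
#'
#' Converts named metric sets into the meta-analysis crosshair
#' representation: test sensitivity against the false positive rate
#' `FPR = 100 - specificity`, with the interval endpoints transposed
#' accordingly (the upper specificity bound becomes the lower FPR bound).
#'
#' @param metric_sets Named list of `ppg_metrics` (one per classifier).
#' @param file Optional CSV path to write.
#' @return Data frame: `classifier`, `sensitivity`, `sens_low`,
#'   `sens_high`, `fpr`, `fpr_low`, `fpr_high` (percent).
#' @export
crosshair_export <- function(metric_sets, file = NULL) {
  if (length(metric_sets) == 0) stop("need at least one metric set")
  rows <- lapply(names(metric_sets), function(nm) {
    m <- metric_sets[[nm]]
    data.frame(classifier = nm,
               sensitivity = m$sensitivity[["value"]],
               sens_low = m$sensitivity[["low"]],
               sens_high = m$sensitivity[["high"]],
               fpr = 100 - m$specificity[["value"]],
               fpr_low = 100 - m$specificity[["high"]],
               fpr_high = 100 - m$specificity[["low"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Evaluate image-level predictions at both reporting granularities
#'
#' Produces the image-based combined confusion matrix and metrics, and the
#' participant-based (majority-vote) matrix and metrics.
#'
#' @param image_predictions Data frame from [run_cv_images()].
#' @param positive Positive-class label.
#' @return List with `image` and `participant` elements, each holding `cm`
#'   and `metrics`.
#' @export
evaluate_predictions <- function(image_predictions, positive = "SSc") {
  cm_img <- confusion_matrix(image_predictions$truth,
                             image_predictions$predicted, positive)
  votes <- participant_votes(image_predictions, positive)
  cm_part <- confusion_matrix(votes$truth, votes$predicted, positive)
  list(image = list(cm = cm_img, metrics = metrics(cm_img)),
       participant = list(cm = cm_part, metrics = metrics(cm_part),
                          votes = votes))
}
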