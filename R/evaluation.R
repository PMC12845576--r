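#' Self-action prediction accuracy
#'
#' Proportion of trials on which the model's chosen action equals the
#' observed self action.
#'
#' @param predicted,observed Equal-length binary vectors.
#' @return Proportion in \[0, 1\].
#' @export
self_accuracy <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  mean(predicted == observed)
}

#' Partner-action prediction accuracy
#'
#' Predicted probabilities are thresholded at 0.5 (a probability of
#' exactly 0.5 predicts a touch) and compared with the observed partner
#' actions.
#'
#' @param probs Predicted touch probabilities in \[0, 1\].
#' @param observed Observed binary partner actions, same length.
#' @param threshold Decision threshold, default 0.5; predictions at or
#'   above it count as touch.
#' @return Proportion in \[0, 1\].
#' @export
partner_accuracy <- function(probs, observed, threshold = 0.5) {
  stopifnot(length(probs) == length(observed), length(probs) >= 1,
            all(probs >= 0 & probs <= 1))
  mean(as.integer(probs >= threshold) == observed)
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean `2 p r / (p + r)`; 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @examples
#' f1_score(0.964, 0.465)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Rank-based AUC (probability a positive outscores a negative)
#'
#' Mann-Whitney form: ties contribute 1/2. Requires both classes present.
#'
#' @param scores Numeric prediction scores.
#' @param observed Binary labels, same length.
#' @return AUC in \[0, 1\], or `NA` if only one class is observed.
#' @export
auc_score <- function(scores, observed) {
  stopifnot(length(scores) == length(observed))
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification report
#'
#' Precision, recall, F1, Matthews correlation coefficient and (when
#' scores are supplied) AUC for partner-action prediction, with the
#' partner touching (a_p = 1) as the positive class. Undefined quantities
#' — precision with no predicted positives, recall with no observed
#' positives, MCC/AUC with a single observed class — are reported as `NA`
#' rather than 0; F1 is 0 when precision and recall are both 0.
#'
#' @param predicted Binary predictions.
#' @param observed Binary labels, same length.
#' @param scores Optional numeric scores for the AUC (e.g. predicted
#'   probabilities); `NULL` leaves `auc` as `NA`.
#' @return A list: `precision`, `recall`, `f1`, `mcc`, `auc`, and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_report <- function(predicted, observed, scores = NULL) {
  stopifnot(length(predicted) == length(observed),
            all(predicted %in% c(0, 1)), all(observed %in% c(0, 1)))
  tp <- sum(predicted == 1 & observed == 1)
  fp <- sum(predicted == 1 & observed == 0)
  tn <- sum(predicted == 0 & observed == 0)
  fn <- sum(predicted == 0 & observed == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else f1_score(precision, recall)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  single_class <- (tp + fn == 0) || (tn + fp == 0)
  mcc <- if (single_class || denom == 0) NA_real_
         else (tp * tn - fp * fn) / sqrt(denom)
  auc <- if (is.null(scores)) NA_real_ else auc_score(scores, observed)
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc,
       auc = auc, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Post hoc power of a z-test
#'
#' Power of a z-test for a noncentrality parameter `mu` with noncentral
#' distribution standard deviation `sigma`: for the two-tailed test,
#' `pnorm(|mu|/sigma - z_crit) + pnorm(-|mu|/sigma - z_crit)` with
#' `z_crit = qnorm(1 - alpha/2)`. Equals `alpha` when `mu = 0`.
#'
#' @param effect Noncentrality parameter (e.g. an estimated effect).
#' @param se Standard deviation of the noncentral distribution; positive.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param two_tailed Logical, default TRUE.
#' @return Power in \[0, 1\].
#' @examples
#' ztest_power(0.668, 0.057)  # essentially 1
#' @export
ztest_power <- function(effect, se, alpha = 0.05, two_tailed = TRUE) {
  stopifnot(is.numeric(se), se > 0, alpha > 0, alpha < 1)
  z <- abs(effect) / se
  if (two_tailed) {
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(z - zc) + stats::pnorm(-z - zc)
  } else {
    stats::pnorm(z - stats::qnorm(1 - alpha))
  }
}

#' Trial-wise trajectory summaries over a collection of traces
#'
#' Averages partner-prediction accuracy, self-prediction accuracy and
#' minimum free energy at each trial position across sessions, the
#' summaries plotted as learning curves. With `hard_only = TRUE` (the
#' default when traces carry a `difficulty` column) only Hard-object
#' trials enter, re-indexed 1..k within each session, so a 24-trial
#' session with 12 Hard objects yields 12 positions.
#'
#' @param traces A single `"model_trace"` or a list of them, sharing
#'   trial indexing.
#' @param hard_only Restrict to `difficulty == 1` trials.
#' @return A data.frame with one row per trial position: `position`,
#'   `n_sessions`, `partner_acc`, `self_acc`, `fe_min_mean`.
#' @export
trajectory_summary <- function(traces, hard_only = FALSE) {
  if (inherits(traces, "model_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  pieces <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "model_trace"))
    if (hard_only) {
      if (!"difficulty" %in% names(tr))
        stop("hard_only requires a `difficulty` column in the trace",
             call. = FALSE)
      tr <- tr[tr$difficulty == 1, , drop = FALSE]
    }
    tr$position <- seq_len(nrow(tr))
    tr
  })
  all <- do.call(rbind, lapply(pieces, function(tr)
    tr[, c("position", "partner_correct", "self_correct", "fe_min")]))
  agg <- do.call(data.frame, stats::aggregate(
    all[, c("partner_correct", "self_correct", "fe_min")],
    by = list(position = all$position), FUN = mean))
  names(agg) <- c("position", "partner_acc", "self_acc", "fe_min_mean")
  counts <- as.data.frame(table(position = all$position))
  agg$n_sessions <- counts$Freq[match(agg$position, counts$position)]
  agg[, c("position", "n_sessions", "partner_acc", "self_acc",
          "fe_min_mean")]
}

#' Plot learning-curve summaries
#'
#' Draws the per-trial mean partner/self prediction accuracy and, in a
#' second panel, the mean minimum free energy produced by
#' [trajectory_summary()].
#'
#' @param summary A data.frame from [trajectory_summary()].
#' @param main Title prefix.
#' @return Invisibly, `summary`.
#' @export
plot_trajectories <- function(summary, main = "Learning trajectories") {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(summary$position,
                    cbind(summary$partner_acc, summary$self_acc),
                    type = "b", pch = c(1, 2), lty = 1,
                    col = c("steelblue", "darkorange"),
                    xlab = "Trial position", ylab = "Prediction accuracy",
                    ylim = c(0, 1), main = main)
  graphics::legend("bottomright", legend = c("partner", "self"),
                   col = c("steelblue", "darkorange"), pch = c(1, 2),
                   lty = 1, bty = "n")
  graphics::plot(summary$position, summary$fe_min_mean, type = "b",
                 xlab = "Trial position", ylab = "Mean minimum free energy",
                 main = "Free energy")
  invisible(summary)
}

#' Evaluate a model trace
#'
#' Aggregates a trace (or list of traces) into an evaluation report:
#' partner and self prediction accuracy, the classification metrics of
#' the thresholded partner prediction, and the free-energy trajectory.
#'
#' @param traces A `"model_trace"` or list of them.
#' @param hard_only Restrict metrics to Hard-object trials.
#' @return A list with `acc_partner`, `acc_self`, `precision`, `recall`,
#'   `f1`, `auc`, `mcc`, `n_trials`, and `trajectory` (the
#'   [trajectory_summary()] table).
#' @export
evaluate_trace <- function(traces, hard_only = FALSE) {
  if (inherits(traces, "model_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    if (hard_only) tr <- tr[tr$difficulty == 1, , drop = FALSE]
    as.data.frame(tr)[, c("predicted_partner_prob", "predicted_self_action",
                          "a_s", "a_p")]
  }))
  pred_p <- as.integer(rows$predicted_partner_prob >= 0.5)
  rep <- classification_report(pred_p, rows$a_p,
                               scores = rows$predicted_partner_prob)
  c(list(acc_partner = partner_accuracy(rows$predicted_partner_prob,
                                        rows$a_p),
         acc_self = self_accuracy(rows$predicted_self_action, rows$a_s),
         n_trials = nrow(rows)),
    rep[c("precision", "recall", "f1", "auc", "mcc")],
    list(trajectory = trajectory_summary(traces, hard_only = hard_only)))
}
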