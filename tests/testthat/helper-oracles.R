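# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

# DTW by explicit path recursion straight from the definition: the cost of
# the best boundary-anchored warping path with steps (i-1,j), (i,j-1),
# (i-1,j-1). Exponential-time; only for short series.
dtw_oracle <- function(x, y) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(x[1] - y[1]))
    if (i < 1 || j < 1) return(Inf)
    abs(x[i] - y[j]) + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
  }
  rec(length(x), length(y))
}

# Beta posterior mean by brute-force counting over an observed sequence.
counting_posterior_mean <- function(a_s, a_p, cond, prior_alpha = 1,
                                    prior_beta = 1) {
  k1 <- sum(a_s == cond & a_p == 1)
  n <- sum(a_s == cond)
  (k1 + prior_alpha) / (n + prior_alpha + prior_beta)
}

# AUC by trapezoidal integration of the empirical ROC curve.
auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(h) mean(scores[labels == 1] >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(scores[labels == 0] >= h), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Small random trial table with both actions free.
random_trials <- function(n, p_s = 0.5, p_p = 0.5) {
  data.frame(a_s = stats::rbinom(n, 1, p_s),
             a_p = stats::rbinom(n, 1, p_p))
}
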