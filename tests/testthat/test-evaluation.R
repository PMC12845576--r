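test_that("self accuracy is the exact-match proportion", {
  expect_equal(self_accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(self_accuracy(c(1, 0), c(0, 1)), 0)
  expect_equal(self_accuracy(c(1, 0, 1, 1), c(1, 0, 0, 1)), 0.75)
  expect_error(self_accuracy(integer(0), integer(0)))
})

test_that("partner accuracy thresholds at 0.5 inclusively", {
  expect_equal(partner_accuracy(0.6, 1), 1)
  expect_equal(partner_accuracy(0.5, 1), 1)   # >= , not >
  expect_equal(partner_accuracy(0.5, 0), 0)
  expect_equal(partner_accuracy(c(0.9, 0.2, 0.4, 0.8), c(1, 0, 1, 1)), 0.75)
  # invariant to monotone transforms preserving the threshold side
  set.seed(51)
  p <- runif(50); obs <- rbinom(50, 1, 0.5)
  squash <- 0.5 + (p - 0.5) / 3
  expect_equal(partner_accuracy(p, obs), partner_accuracy(squash, obs))
})

test_that("F1 is the harmonic mean with the zero convention", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0, 0), 0)
  set.seed(52)
  p <- runif(40); r <- runif(40)
  f <- f1_score(p, r)
  expect_equal(f * (p + r), 2 * p * r)
})

test_that("classification report matches oracles and handles degeneracy", {
  # perfect prediction
  perfect <- classification_report(c(1, 0, 1, 0), c(1, 0, 1, 0),
                                   scores = c(0.9, 0.1, 0.8, 0.2))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "mcc", "auc")]),
               c(precision = 1, recall = 1, f1 = 1, mcc = 1, auc = 1))

  # single-class observations: auc and mcc are missing, not zero
  one_class <- classification_report(c(1, 0, 1), c(1, 1, 1),
                                     scores = c(0.9, 0.4, 0.8))
  expect_true(is.na(one_class$mcc))
  expect_true(is.na(one_class$auc))
  no_pos_pred <- classification_report(c(0, 0), c(1, 0))
  expect_true(is.na(no_pos_pred$precision))

  # mcc equals the phi coefficient (correlation of the binary vectors)
  set.seed(53)
  for (i in 1:20) {
    pred <- rbinom(60, 1, 0.5); obs <- rbinom(60, 1, 0.5)
    rep <- classification_report(pred, obs)
    if (!is.na(rep$mcc))
      expect_equal(rep$mcc, suppressWarnings(cor(pred, obs)),
                   tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals trapezoidal ROC integration", {
  set.seed(54)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) next
    scores <- round(runif(n), 2)   # rounding forces ties
    expect_equal(auc_score(scores, obs), auc_trapezoid(scores, obs),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_score(runif(5), rep(1, 5))))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  obs <- rbinom(200, 1, 0.4)
  scores <- runif(200) + 0.3 * obs
  ref <- as.numeric(pROC::auc(pROC::roc(obs, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, obs), ref, tolerance = 1e-12)
})

test_that("z-test power follows the closed form and its limits", {
  expect_equal(ztest_power(0.668, 0.057), 1, tolerance = 1e-4)
  expect_equal(round(ztest_power(0.668, 0.057), 2), 1)
  expect_equal(ztest_power(0, 1), 0.05)                   # null case
  # effect/se at the critical value: power sits essentially at one half
  expect_equal(ztest_power(1.96, 1), 0.5, tolerance = 1e-3)
  # non-decreasing in |effect| / se
  pw <- vapply(seq(0, 3, by = 0.25), ztest_power, numeric(1), se = 1)
  expect_true(all(diff(pw) >= 0))
  expect_equal(ztest_power(-1, 1), ztest_power(1, 1))
  expect_error(ztest_power(1, 0), "se")
})

test_that("trajectory summaries average across sessions by trial position", {
  set.seed(56)
  mk <- function(seed) {
    s <- simulate_session(session_spec("bot_pair", seed = seed),
                          gaze = FALSE)
    run_session(s$trials, config = model_config(gamma0 = 0))
  }
  one <- mk(1)
  single <- trajectory_summary(one)
  expect_equal(single$fe_min_mean, one$fe_min)
  expect_equal(single$partner_acc, as.numeric(one$partner_correct))

  many <- trajectory_summary(list(mk(1), mk(2), mk(3)))
  expect_equal(nrow(many), 24)
  expect_true(all(many$n_sessions == 3))
  expect_true(all(many$partner_acc >= 0 & many$partner_acc <= 1))

  hard <- trajectory_summary(list(mk(1), mk(2), mk(3)), hard_only = TRUE)
  expect_equal(nrow(hard), 12)
  expect_error(trajectory_summary(list()), "length")
})

test_that("trace evaluation aggregates the per-trial record coherently", {
  set.seed(57)
  s <- simulate_session(session_spec("bot_pair", seed = 57), gaze = FALSE)
  tr <- run_session(s$trials, config = model_config(gamma0 = 0))
  ev <- evaluate_trace(tr)
  expect_equal(ev$acc_partner, mean(tr$partner_correct))
  expect_equal(ev$acc_self, mean(tr$self_correct))
  expect_equal(ev$n_trials, 24)
  if (!is.na(ev$f1) && !is.na(ev$precision) && ev$precision + ev$recall > 0)
    expect_equal(ev$f1, f1_score(ev$precision, ev$recall))
  expect_equal(nrow(ev$trajectory), 24)
})
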