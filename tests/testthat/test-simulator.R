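test_that("the default stimulus set realizes the balanced design", {
  st <- build_stimulus_set()
  expect_equal(nrow(st), 24)
  expect_equal(length(unique(paste(st$object_id, st$handle_side))), 24)
  expect_equal(sum(st$difficulty == 1), 12)
  expect_equal(sum(st$category == "Kitchen"), 12)
  # three distinct objects per category x difficulty cell
  cells <- table(st$category, st$difficulty) / 2  # two handle sides each
  expect_true(all(cells == 3))
})

test_that("trial ordering is seeded, permuted and balanced", {
  st <- build_stimulus_set()
  a <- order_trials(st, session_spec("bot_pair", seed = 5))
  b <- order_trials(st, session_spec("bot_pair", seed = 5))
  c <- order_trials(st, session_spec("bot_pair", seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$object_id, c$object_id))
  for (ord in list(a, c)) {
    expect_equal(nrow(ord), 24)
    expect_equal(sum(ord$category == "Kitchen"), 12)
    expect_equal(sum(ord$difficulty == 1), 12)
    expect_equal(ord$trial_index, 1:24)
  }
  unbalanced <- st[st$category == "Kitchen", ]
  expect_error(order_trials(unbalanced, session_spec("bot_pair")),
               "unbalanced")
})

test_that("the bot is correct on Easy and incorrect on Hard by construction", {
  easy_own <- list(category = "Kitchen", difficulty = 0)
  hard_own <- list(category = "Kitchen", difficulty = 1)
  hard_other <- list(category = "Garage", difficulty = 1)
  easy_other <- list(category = "Garage", difficulty = 0)
  expect_equal(bot_policy(easy_own, "Kitchen"), 1L)
  expect_equal(bot_policy(easy_other, "Kitchen"), 0L)
  expect_equal(bot_policy(hard_own, "Kitchen"), 0L)
  expect_equal(bot_policy(hard_other, "Kitchen"), 1L)
})

test_that("the human-like agent applies the rule on Easy and the knob on Hard", {
  easy_own <- list(category = "Kitchen", difficulty = 0)
  easy_other <- list(category = "Garage", difficulty = 0)
  hard <- list(category = "Kitchen", difficulty = 1)
  expect_equal(human_agent(easy_own, "Kitchen", noise = 0), 1L)
  expect_equal(human_agent(easy_other, "Kitchen", noise = 0), 0L)
  set.seed(31)
  draws <- replicate(10000, human_agent(hard, "Kitchen", noise = 0,
                                        hard_touch_prob = 0.6))
  expect_equal(mean(draws), 0.6, tolerance = 0.02)
  expect_error(human_agent(easy_own, "Kitchen", noise = 0.7), "noise")
})

test_that("simulated sessions are reproducible and structurally valid", {
  s1 <- simulate_session(session_spec("bot_pair", seed = 33), gaze = FALSE)
  s2 <- simulate_session(session_spec("bot_pair", seed = 33), gaze = FALSE)
  expect_identical(s1$trials, s2$trials)

  tr <- s1$trials
  expect_equal(nrow(tr), 24)
  expect_true(all(tr$touch_outcome %in% c(1, -1, 0)))
  # only the first touch is recorded: (1,1) can never appear
  expect_true(all(!(tr$a_s == 1 & tr$a_p == 1)))
  expect_true(all(tr$reaction_time >= 0 & tr$reaction_time <= 3))

  # bot intent: always right on Easy, always wrong on Hard
  partner_cat <- s1$spec$partner_category
  own <- as.integer(tr$category == partner_cat)
  expect_equal(tr$partner_intent[tr$difficulty == 0],
               own[tr$difficulty == 0])
  expect_equal(tr$partner_intent[tr$difficulty == 1],
               1L - own[tr$difficulty == 1])
  expect_equal(sum(tr$difficulty == 1), 12)

  pr <- simulate_session(session_spec("practice", seed = 1), gaze = FALSE)
  expect_equal(nrow(pr$trials), 8)
  ind <- simulate_session(session_spec("individual", seed = 1), gaze = FALSE)
  expect_true(all(ind$trials$a_p == 0))
})

test_that("balance invariants hold across many seeds", {
  for (seed in 1:12) {
    tr <- simulate_session(session_spec("human_pair", seed = seed),
                           gaze = FALSE)$trials
    expect_equal(sum(tr$category == "Kitchen"), 12)
    expect_equal(sum(tr$difficulty == 1), 12)
    expect_true(all(!(tr$a_s == 1 & tr$a_p == 1)))
  }
})

test_that("coupled model agents produce valid, reproducible human-pair logs", {
  cfg <- model_config(gamma0 = 0.9)
  s1 <- simulate_session(session_spec("human_pair", seed = 35),
                         agent = "model", agent_config = cfg, gaze = FALSE)
  s2 <- simulate_session(session_spec("human_pair", seed = 35),
                         agent = "model", agent_config = cfg, gaze = FALSE)
  expect_identical(s1$trials, s2$trials)
  tr <- s1$trials
  expect_equal(nrow(tr), 24)
  expect_true(all(tr$touch_outcome %in% c(1, -1, 0)))
  expect_true(all(!(tr$a_s == 1 & tr$a_p == 1)))
  # the coupled log still feeds the model loop
  trace <- run_session(tr, config = cfg)
  expect_true(all(is.finite(trace$fe_min)))
})

test_that("synthesized gaze pairs degenerate and decorrelate as dialled", {
  # full synchrony, no jitter, no lag: the two streams are identical
  p <- synthesize_gaze_pair(1, jitter = 0, time_jitter_sd = 0, seed = 41)
  expect_identical(p$a, p$b)
  al <- clean_and_align(p$a, p$b)
  expect_equal(velocity_dtw(compute_velocity(al$a), compute_velocity(al$b)),
               0, tolerance = 1e-9)

  # independent pairs: zero-lag velocity correlation centred on 0
  r <- vapply(1:60, function(s) {
    p <- synthesize_gaze_pair(0, duration = 2, seed = s)
    al <- clean_and_align(p$a, p$b)
    cross_correlation(compute_velocity(al$a), compute_velocity(al$b))
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.06)

  # requested missingness shows up as NA coordinates
  pm <- synthesize_gaze_pair(0.5, missing_rate = 0.2, seed = 42)
  expect_gt(sum(is.na(pm$b$x)), 10)
  expect_false(anyNA(pm$a$x))
})

test_that("gaze synchrony decreases DTW distance monotonically in rho", {
  mean_dist <- function(rho) {
    mean(vapply(1:25, function(s) {
      p <- synthesize_gaze_pair(rho, duration = 1.5, seed = 1000 + s)
      al <- clean_and_align(p$a, p$b)
      velocity_dtw(compute_velocity(al$a), compute_velocity(al$b))
    }, numeric(1)))
  }
  d <- vapply(c(0.1, 0.5, 0.9), mean_dist, numeric(1))
  expect_gt(d[1], d[2])
  expect_gt(d[2], d[3])
})
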