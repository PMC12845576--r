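#' Build the default stimulus set
#'
#' Twelve abstract objects — three per category (Kitchen/Garage) x
#' difficulty (Easy/Hard) cell — each presented with the handle on the
#' left or the right, giving 24 target stimuli. Object identities are
#' labels (KE1..KE3, KH1..KH3, GE1..GE3, GH1..GH3); only category and
#' difficulty enter any computation.
#'
#' @param seed Ignored; the default set is deterministic. Kept so stimulus
#'   construction and trial ordering share a call signature.
#' @return A data.frame of 24 rows with columns `object_id`, `category`,
#'   `difficulty` (0 = Easy, 1 = Hard), `handle_side`.
#' @export
build_stimulus_set <- function(seed = NULL) {
  cells <- expand.grid(category = c("Kitchen", "Garage"),
                       difficulty = c(0L, 1L),
                       idx = 1:3,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$object_id <- paste0(substr(cells$category, 1, 1),
                            ifelse(cells$difficulty == 1, "H", "E"),
                            cells$idx)
  out <- merge(cells[, c("object_id", "category", "difficulty")],
               data.frame(handle_side = c("left", "right")))
  out <- out[order(out$object_id, out$handle_side), ]
  rownames(out) <- NULL
  out
}

#' Session specification
#'
#' @param session_type One of `"practice"`, `"individual"`, `"bot_pair"`,
#'   `"human_pair"`.
#' @param n_trials Number of trials; defaults to 8 for practice and 24
#'   otherwise.
#' @param self_category Category the self participant is instructed to
#'   touch. Default "Kitchen" (the host role in the bot-pair session).
#' @param partner_category Category assigned to the partner; defaults to
#'   the other category.
#' @param seed Integer seed controlling trial order, agent noise, reaction
#'   times and gaze synthesis.
#' @return An object of class `"session_spec"`.
#' @export
session_spec <- function(session_type = c("bot_pair", "human_pair",
                                          "individual", "practice"),
                         n_trials = NULL, self_category = "Kitchen",
                         partner_category = NULL, seed = 1L) {
  session_type <- match.arg(session_type)
  if (is.null(n_trials))
    n_trials <- if (session_type == "practice") 8L else 24L
  if (is.null(partner_category))
    partner_category <- setdiff(c("Kitchen", "Garage"), self_category)
  stopifnot(self_category %in% c("Kitchen", "Garage"),
            partner_category %in% c("Kitchen", "Garage"))
  structure(list(session_type = session_type, n_trials = as.integer(n_trials),
                 self_category = self_category,
                 partner_category = partner_category, seed = as.integer(seed)),
            class = "session_spec")
}

#' Order stimuli into a balanced trial sequence
#'
#' Seeded random presentation order under the design constraint that each
#' category and each difficulty level appear an equal number of times. For
#' the full 24-stimulus set any permutation satisfies this (the set itself
#' is balanced); for shorter sessions (practice: 8 trials) a balanced
#' subset — equal draws per category x difficulty cell — is sampled first.
#'
#' @param stimuli A stimulus data.frame from [build_stimulus_set()].
#' @param spec A [session_spec()].
#' @return A data.frame of `spec$n_trials` rows with a `trial_index`
#'   column prepended.
#' @export
order_trials <- function(stimuli, spec) {
  stopifnot(inherits(spec, "session_spec"))
  counts <- table(stimuli$category, stimuli$difficulty)
  if (!identical(dim(counts), c(2L, 2L)) ||
      length(unique(as.vector(counts))) != 1)
    stop("stimulus set is unbalanced across category x difficulty cells",
         call. = FALSE)
  if (spec$n_trials %% 4 != 0)
    stop("n_trials must be a multiple of 4 to balance the design",
         call. = FALSE)
  set.seed(spec$seed)
  per_cell <- spec$n_trials / 4
  cells <- split(seq_len(nrow(stimuli)),
                 paste(stimuli$category, stimuli$difficulty))
  picked <- unlist(lapply(cells, function(ix)
    sample(ix, per_cell, replace = per_cell > length(ix))))
  ordered <- stimuli[sample(picked), , drop = FALSE]
  out <- cbind(trial_index = seq_len(nrow(ordered)), ordered)
  rownames(out) <- NULL
  out
}

#' Bot partner policy
#'
#' The bot responds correctly to Easy objects and always incorrectly to
#' Hard objects: on Easy it touches iff the object belongs to its assigned
#' category; on Hard it touches iff the object does not.
#'
#' @param stimulus A one-row stimulus data.frame (or list) with `category`
#'   and `difficulty`.
#' @param assigned_category The bot's assigned category.
#' @return 1 (touch) or 0 (no touch).
#' @export
bot_policy <- function(stimulus, assigned_category) {
  own <- stimulus$category == assigned_category
  if (stimulus$difficulty == 0) as.integer(own) else as.integer(!own)
}

#' Stochastic human-like agent
#'
#' A table-driven stand-in for a participant. On Easy objects it applies
#' the category rule (touch iff own category) and lapses with probability
#' `noise`. On Hard — ambiguous — objects it touches with probability
#' `hard_touch_prob`, the knob controlling how unsettled category
#' judgments are before any convergence.
#'
#' @param stimulus A one-row stimulus with `category` and `difficulty`.
#' @param assigned_category The agent's assigned category.
#' @param noise Lapse probability on Easy objects, in \[0, 0.5\].
#' @param hard_touch_prob Touch probability on Hard objects, in \[0, 1\].
#' @return 1 (touch) or 0 (no touch). Consumes one or zero RNG draws from
#'   the current stream; seed management belongs to the caller.
#' @export
human_agent <- function(stimulus, assigned_category, noise = 0.1,
                        hard_touch_prob = 0.5) {
  stopifnot(noise >= 0, noise <= 0.5,
            hard_touch_prob >= 0, hard_touch_prob <= 1)
  if (stimulus$difficulty == 0) {
    intended <- as.integer(stimulus$category == assigned_category)
    if (noise > 0 && stats::runif(1) < noise) 1L - intended else intended
  } else {
    as.integer(stats::runif(1) < hard_touch_prob)
  }
}

rt_draw <- function(n) pmin(stats::rlnorm(n, meanlog = log(0.9), sdlog = 0.35), 2.9)

#' Simulate one experimental session
#'
#' Generates a complete synthetic session: a balanced, seeded trial order;
#' per-trial self and partner actions from the configured agents (bot
#' partner in `bot_pair`, stochastic human-like partner in `human_pair`,
#' no partner action in `individual`/`practice`); first-touch resolution
#' when both agents intend to touch (each draws a latent reaction time,
#' the earlier touch is recorded, exact ties going to self); and,
#' optionally, paired gaze streams with tunable synchrony.
#'
#' @param spec A [session_spec()].
#' @param noise Easy-object lapse probability of human-like agents.
#' @param hard_touch_prob Hard-object touch probability of human-like
#'   agents (used for the self agent always, and for the partner in
#'   `human_pair`).
#' @param rho Gaze synchrony level in \[0, 1\] passed to
#'   [synthesize_gaze_pair()]; defaults to 0.7 for human pairs and 0.3
#'   for bot pairs, reflecting the stronger gaze coordination of
#'   human-human dyads.
#' @param agent For `human_pair` sessions: `"table"` (default) draws both
#'   actions from the stochastic rule agent; `"model"` couples two
#'   active-inference agents, each holding its own [init_belief()] state,
#'   applying the category rule on Easy objects and choosing its Hard
#'   action by free-energy minimization over its beliefs about the other
#'   — a bidirectional mutual-adaptation sandbox.
#' @param agent_config A [model_config()] used by the `"model"` agents.
#' @param gaze Logical; attach synthetic paired gaze streams (default
#'   TRUE for paired sessions).
#' @param gaze_duration,gaze_rate Object-presentation gaze length in
#'   seconds and nominal sampling rate in Hz.
#' @return A list with `trials` (one `TrialRecord` row per trial:
#'   `trial_index`, `object_id`, `category`, `difficulty`, `handle_side`,
#'   `touch_outcome`, `a_s`, `a_p`, `correct`, `reaction_time`) and
#'   `gaze` (a list with data.frames `a`, `b`, or NULL).
#' @examples
#' s <- simulate_session(session_spec("bot_pair", seed = 7), gaze = FALSE)
#' table(s$trials$difficulty)
#' @export
simulate_session <- function(spec, noise = 0.1, hard_touch_prob = 0.5,
                             rho = NULL, gaze = NULL,
                             gaze_duration = 3, gaze_rate = 80,
                             agent = c("table", "model"),
                             agent_config = model_config()) {
  stopifnot(inherits(spec, "session_spec"))
  agent <- match.arg(agent)
  paired <- spec$session_type %in% c("bot_pair", "human_pair")
  if (is.null(gaze)) gaze <- paired
  if (is.null(rho))
    rho <- if (spec$session_type == "human_pair") 0.7 else 0.3
  trials <- order_trials(build_stimulus_set(), spec)
  n <- nrow(trials)
  # order_trials seeded the stream; everything below continues it
  a_s <- a_p <- correct <- integer(n)
  self_intent <- partner_intent <- integer(n)
  outcome <- integer(n)
  rt <- numeric(n)
  coupled <- spec$session_type == "human_pair" && agent == "model"
  if (coupled) {
    belief_s <- init_belief(agent_config)
    belief_p <- init_belief(agent_config)
    model_action <- function(belief) {
      fer <- free_energy(belief, gamma_t = agent_config$gamma0,
                         config = agent_config)
      select_action(fer, agent_config$tau, agent_config$tie_break)$action
    }
  }
  for (t in seq_len(n)) {
    st <- trials[t, ]
    self_cat <- spec$self_category
    intend_s <- if (spec$session_type == "practice") 1L
                else if (coupled && st$difficulty == 1) model_action(belief_s)
                else human_agent(st, self_cat, noise, hard_touch_prob)
    intend_p <- switch(spec$session_type,
      bot_pair = bot_policy(st, spec$partner_category),
      human_pair = if (coupled && st$difficulty == 1) model_action(belief_p)
                   else human_agent(st, spec$partner_category, noise,
                                    hard_touch_prob),
      0L)
    if (coupled) {
      # each agent observes its own intent and the other's
      belief_s <- update_double_bayes(
        update_single_bayes(belief_s, intend_s, intend_p),
        intend_s, intend_p, agent_config$ema_alpha)
      belief_p <- update_double_bayes(
        update_single_bayes(belief_p, intend_p, intend_s),
        intend_p, intend_s, agent_config$ema_alpha)
    }
    self_intent[t] <- intend_s
    partner_intent[t] <- intend_p
    rts <- rt_draw(2)
    if (intend_s == 1 && intend_p == 1) {
      # only the first touch is recorded; ties go to self
      if (rts[1] <= rts[2]) { outcome[t] <- 1L;  rt[t] <- rts[1] }
      else                  { outcome[t] <- -1L; rt[t] <- rts[2] }
    } else if (intend_s == 1) { outcome[t] <- 1L;  rt[t] <- rts[1] }
    else if (intend_p == 1)   { outcome[t] <- -1L; rt[t] <- rts[2] }
    else                      { outcome[t] <- 0L;  rt[t] <- 3 }
    a_s[t] <- as.integer(outcome[t] == 1)
    a_p[t] <- as.integer(outcome[t] == -1)
    correct[t] <- as.integer(a_s[t] == as.integer(st$category == self_cat))
  }
  trials$touch_outcome <- outcome
  trials$a_s <- a_s
  trials$a_p <- a_p
  trials$correct <- correct
  trials$reaction_time <- rt
  trials$self_intent <- self_intent
  trials$partner_intent <- partner_intent
  gaze_out <- NULL
  if (gaze) {
    per_trial <- lapply(seq_len(n), function(t) {
      pair <- synthesize_gaze_pair(rho = rho, duration = gaze_duration,
                                   rate = gaze_rate)
      pair$a$trial_id <- t; pair$b$trial_id <- t
      pair
    })
    bind <- function(which, id) {
      g <- do.call(rbind, lapply(per_trial, `[[`, which))
      g$participant_id <- id
      g$phase <- "object_presentation"
      g[, c("participant_id", "trial_id", "phase", "t", "x", "y", "z")]
    }
    gaze_out <- list(a = bind("a", "self"), b = bind("b", "partner"))
  }
  list(trials = trials, gaze = gaze_out, spec = spec)
}

smooth_noise <- function(n, window) {
  # low-pass filtered gaussian noise: a smooth random trajectory
  raw <- stats::rnorm(n + window)
  as.numeric(stats::filter(raw, rep(1 / window, window), sides = 1))[-seq_len(window)]
}

#' Synthesize a pair of gaze series with tunable synchrony
#'
#' Emulates paired pupil-position streams: each axis of participant A is a
#' smooth latent trajectory plus sensor jitter; the matching axis of
#' participant B mixes the same latent trajectory (weight `rho`) with an
#' independent smooth trajectory (weight `1 - rho`), optionally lagged.
#' `rho = 1` with zero jitter and lag reproduces A exactly; `rho = 0`
#' makes the two streams independent. Timestamps are jittered around the
#' nominal rate to mimic the variable ~80 Hz sampling of the headset.
#'
#' @param rho Synchrony level in \[0, 1\].
#' @param duration Length in seconds (default 3, one object presentation).
#' @param rate Nominal sampling rate in Hz (default 80).
#' @param lag Temporal lag of B behind A, in seconds (default 0).
#' @param jitter Standard deviation of additive sensor noise (default
#'   0.02 in position units).
#' @param time_jitter_sd Standard deviation of timestamp jitter as a
#'   fraction of the sampling interval (default 0.1).
#' @param missing_rate Fraction of B's samples whose coordinates are set
#'   to NA, to exercise cleaning (default 0).
#' @param seed Optional seed applied before drawing.
#' @return A list of two gaze data.frames `a`, `b` with columns `t`, `x`,
#'   `y`, `z`.
#' @export
synthesize_gaze_pair <- function(rho, duration = 3, rate = 80, lag = 0,
                                 jitter = 0.02, time_jitter_sd = 0.1,
                                 missing_rate = 0, seed = NULL) {
  stopifnot(rho >= 0, rho <= 1, duration > 0, rate > 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / rate
  n <- ceiling(duration * rate)
  window <- max(2L, as.integer(rate / 8))  # ~0.1 s smoothing
  t_nom <- (seq_len(n) - 1) * dt
  jitter_t <- function() {
    tj <- t_nom + stats::rnorm(n, 0, time_jitter_sd * dt)
    sort(tj) - min(tj)
  }
  make_axis <- function() {
    latent <- smooth_noise(n, window)
    indep <- smooth_noise(n, window)
    a <- latent + stats::rnorm(n, 0, jitter)
    b_core <- rho * latent + (1 - rho) * indep
    if (lag != 0) {
      shift <- round(lag * rate)
      b_core <- c(rep(b_core[1], shift), b_core)[seq_len(n)]
    }
    b <- b_core + if (jitter > 0) stats::rnorm(n, 0, jitter) else 0
    if (rho == 1 && jitter == 0 && lag == 0) b <- a
    list(a = a, b = b)
  }
  ax <- make_axis(); ay <- make_axis(); az <- make_axis()
  ta <- jitter_t()
  tb <- if (rho == 1 && jitter == 0 && lag == 0) ta else jitter_t()
  a <- data.frame(t = ta, x = ax$a, y = ay$a, z = az$a)
  b <- data.frame(t = tb, x = ax$b, y = ay$b, z = az$b)
  if (missing_rate > 0) {
    drop <- which(stats::runif(n) < missing_rate)
    b[drop, c("x", "y", "z")] <- NA_real_
  }
  list(a = a, b = b)
}
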