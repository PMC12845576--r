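#' Derive self/partner action indicators from the touch-outcome code
#'
#' Trial logs record a single code per trial: 1 = self touched first,
#' -1 = partner touched first, 0 = no touch. Only the first touch is
#' recorded, so simultaneous touches cannot occur and the derived pair
#' (a_s, a_p) is one of (1,0), (0,1), (0,0).
#'
#' @param touch_outcome Vector of codes in \{1, -1, 0\}.
#' @return A data.frame with integer columns `a_s` and `a_p`.
#' @export
actions_from_outcome <- function(touch_outcome) {
  if (!all(touch_outcome %in% c(1, -1, 0)))
    stop("touch_outcome codes must be 1 (self), -1 (partner) or 0 (none)",
         call. = FALSE)
  data.frame(a_s = as.integer(touch_outcome == 1),
             a_p = as.integer(touch_outcome == -1))
}

#' Run the dyadic active-inference model over one session
#'
#' Iterates the model over a time-ordered trial log. Within each trial the
#' order is predict-then-update: the partner prediction (first-layer
#' posterior mean conditioned on the trial's self action) and the model's
#' own action choice (argmin of free energy under the trial's synchrony
#' weight) are emitted from the beliefs accumulated over earlier trials
#' only; then both belief layers are updated with the trial's observed
#' actions.
#'
#' @param trials A data.frame with one row per trial, time-ordered. Must
#'   contain either integer columns `a_s` and `a_p` or a `touch_outcome`
#'   column from which they are derived. Optional columns `trial_index`,
#'   `difficulty`, `category`, `object_id` are carried into the trace.
#' @param sync Per-trial synchrony weights `gamma_t`, either a numeric
#'   vector of length `nrow(trials)` or a synchrony table (data.frame with
#'   a `gamma_t` column). `NULL` or `NA` entries become 0, disabling the
#'   agreement term for those trials.
#' @param config A [model_config()].
#' @return A `"model_trace"` data.frame, one row per trial, with the
#'   pre-update predictions `p_0`, `p_1` (first layer), `q_0`, `q_1`
#'   (second layer), free energies `g_0`, `g_1`, `fe_min`, policy
#'   probabilities `pi_0`, `pi_1`, `predicted_partner_prob`,
#'   `predicted_self_action`, the observed `a_s`, `a_p`, `gamma_t`, and
#'   the correctness indicators `partner_correct` (thresholded partner
#'   prediction vs observed partner action) and `self_correct` (chosen
#'   action vs observed self action).
#' @examples
#' trials <- data.frame(a_s = c(1, 1, 0, 1), a_p = c(0, 1, 1, 1))
#' run_session(trials, sync = rep(0.5, 4), config = model_config())
#' @export
run_session <- function(trials, sync = NULL, config = model_config()) {
  stopifnot(inherits(config, "model_config"), is.data.frame(trials))
  n <- nrow(trials)
  if (!all(c("a_s", "a_p") %in% names(trials))) {
    if (!"touch_outcome" %in% names(trials))
      stop("trials must contain `a_s`/`a_p` or `touch_outcome`", call. = FALSE)
    trials <- cbind(trials, actions_from_outcome(trials$touch_outcome))
  }
  if ("trial_index" %in% names(trials) && n > 1 &&
      is.unsorted(trials$trial_index, strictly = TRUE))
    stop("trials must be in strictly increasing trial_index order",
         call. = FALSE)
  if (is.data.frame(sync)) {
    if (!"gamma_t" %in% names(sync))
      stop("synchrony table must contain a `gamma_t` column", call. = FALSE)
    sync <- sync$gamma_t
  }
  if (is.null(sync)) sync <- rep(0, n)
  if (length(sync) != n)
    stop(sprintf("sync has length %d but there are %d trials",
                 length(sync), n), call. = FALSE)
  sync[is.na(sync)] <- 0

  belief <- init_belief(config)
  cols <- c("p_0", "p_1", "q_0", "q_1", "g_0", "g_1", "pi_0", "pi_1",
            "predicted_partner_prob", "predicted_self_action", "fe_min")
  out <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (t in seq_len(n)) {
    a_s <- trials$a_s[t]
    a_p <- trials$a_p[t]
    fer <- free_energy(belief, gamma_t = sync[t], config = config)
    sel <- select_action(fer, tau = config$tau, tie_break = config$tie_break)
    out[t, ] <- c(point_estimate(belief, 0), point_estimate(belief, 1),
                  belief$q_0, belief$q_1, fer$g_0, fer$g_1,
                  sel$pi_0, sel$pi_1,
                  point_estimate(belief, a_s), sel$action, fer$fe_min)
    belief <- update_single_bayes(belief, a_s, a_p)
    belief <- update_double_bayes(belief, a_s, a_p, config$ema_alpha)
  }
  trace <- data.frame(
    trial = if ("trial_index" %in% names(trials)) trials$trial_index
            else seq_len(n),
    a_s = trials$a_s, a_p = trials$a_p, gamma_t = sync,
    as.data.frame(out)
  )
  for (extra in c("difficulty", "category", "object_id"))
    if (extra %in% names(trials)) trace[[extra]] <- trials[[extra]]
  if (n > 0) {
    trace$partner_correct <-
      as.integer((trace$predicted_partner_prob >= 0.5) == (trace$a_p == 1))
    trace$self_correct <-
      as.integer(trace$predicted_self_action == trace$a_s)
  } else {
    trace$partner_correct <- integer(0)
    trace$self_correct <- integer(0)
  }
  class(trace) <- c("model_trace", "data.frame")
  attr(trace, "config") <- config
  trace
}

#' @export
print.model_trace <- function(x, ...) {
  cat(sprintf("Model trace: %d trials\n", nrow(x)))
  if (nrow(x) > 0 &&
      all(c("partner_correct", "self_correct", "fe_min") %in% names(x))) {
    cat(sprintf("  partner prediction accuracy: %.3f\n",
                mean(x$partner_correct)))
    cat(sprintf("  self prediction accuracy:    %.3f\n",
                mean(x$self_correct)))
    cat(sprintf("  mean minimum free energy:    %.4f\n", mean(x$fe_min)))
  }
  NextMethod()
}
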