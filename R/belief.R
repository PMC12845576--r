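#' Initialize the dual-layer partner belief
#'
#' The belief over the partner's action is held in two layers. The first
#' ("single Bayes") layer keeps two conjugate Beta-Bernoulli posteriors for
#' P(partner touches | self action), one per self-action condition, as
#' pseudo-counts. The second ("double Bayes") layer keeps an exponential
#' moving average Q(partner touches | self action) per condition, refining
#' the first-layer prediction with recency weighting.
#'
#' @param config A [model_config()].
#' @return An object of class `"dyad_belief"` with fields `alpha_11`,
#'   `beta_11` (counts for the self-touch condition), `alpha_01`, `beta_01`
#'   (self-no-touch condition), and EMA probabilities `q_1`, `q_0`.
#' @examples
#' b <- init_belief(model_config())
#' point_estimate(b, 1)  # 0.5 under the uniform prior
#' @export
init_belief <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  structure(
    list(alpha_11 = config$prior_alpha, beta_11 = config$prior_beta,
         alpha_01 = config$prior_alpha, beta_01 = config$prior_beta,
         q_1 = config$q_init, q_0 = config$q_init),
    class = "dyad_belief"
  )
}

check_binary <- function(x, name) {
  if (!(length(x) == 1L && !is.na(x) && x %in% c(0, 1)))
    stop(sprintf("`%s` must be 0 or 1", name), call. = FALSE)
}

#' First-layer (conjugate counting) belief update
#'
#' After observing a trial's self action `a_s` and partner action `a_p`,
#' exactly one pseudo-count of the conditional matching `a_s` is
#' incremented: the alpha count if the partner touched, the beta count
#' otherwise. The other conditional is untouched.
#'
#' @param belief A `"dyad_belief"`.
#' @param a_s,a_p Observed self and partner actions, each 0 or 1.
#' @return The updated belief.
#' @export
update_single_bayes <- function(belief, a_s, a_p) {
  stopifnot(inherits(belief, "dyad_belief"))
  check_binary(a_s, "a_s")
  check_binary(a_p, "a_p")
  if (a_s == 1) {
    if (a_p == 1) belief$alpha_11 <- belief$alpha_11 + 1
    else          belief$beta_11  <- belief$beta_11 + 1
  } else {
    if (a_p == 1) belief$alpha_01 <- belief$alpha_01 + 1
    else          belief$beta_01  <- belief$beta_01 + 1
  }
  belief
}

#' First-layer point prediction
#'
#' Posterior mean `alpha / (alpha + beta)` of the Beta conditional selected
#' by the self action `a`.
#'
#' @param belief A `"dyad_belief"`.
#' @param a Self-action condition, 0 or 1.
#' @return Probability that the partner touches, in (0, 1).
#' @export
point_estimate <- function(belief, a) {
  stopifnot(inherits(belief, "dyad_belief"))
  check_binary(a, "a")
  if (a == 1) belief$alpha_11 / (belief$alpha_11 + belief$beta_11)
  else        belief$alpha_01 / (belief$alpha_01 + belief$beta_01)
}

#' Second-layer (exponential moving average) belief update
#'
#' Only the EMA conditional matching the observed self action is updated:
#' `q <- ema_alpha * a_p + (1 - ema_alpha) * q`. The other conditional is
#' untouched, so each EMA tracks the partner's behavior within one
#' self-action context.
#'
#' @param belief A `"dyad_belief"`.
#' @param a_s,a_p Observed self and partner actions, each 0 or 1.
#' @param ema_alpha EMA decay in (0, 1]; the weight on the new observation.
#' @return The updated belief.
#' @export
update_double_bayes <- function(belief, a_s, a_p, ema_alpha = 0.8) {
  stopifnot(inherits(belief, "dyad_belief"),
            is.numeric(ema_alpha), ema_alpha > 0, ema_alpha <= 1)
  check_binary(a_s, "a_s")
  check_binary(a_p, "a_p")
  if (a_s == 1) belief$q_1 <- ema_alpha * a_p + (1 - ema_alpha) * belief$q_1
  else          belief$q_0 <- ema_alpha * a_p + (1 - ema_alpha) * belief$q_0
  belief
}

#' Second-layer point prediction
#'
#' @param belief A `"dyad_belief"`.
#' @param a Self-action condition, 0 or 1.
#' @return The EMA probability Q(partner touches | self action = a).
#' @export
ema_estimate <- function(belief, a) {
  stopifnot(inherits(belief, "dyad_belief"))
  check_binary(a, "a")
  if (a == 1) belief$q_1 else belief$q_0
}

#' @export
print.dyad_belief <- function(x, ...) {
  cat("Dual-layer partner belief\n")
  cat(sprintf("  self touch   : Beta(%g, %g), mean %.3f; EMA q = %.3f\n",
              x$alpha_11, x$beta_11, point_estimate(x, 1), x$q_1))
  cat(sprintf("  self no-touch: Beta(%g, %g), mean %.3f; EMA q = %.3f\n",
              x$alpha_01, x$beta_01, point_estimate(x, 0), x$q_0))
  invisible(x)
}
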