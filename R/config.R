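#' Model configuration
#'
#' Bundles the fixed parameters of the dyadic active-inference model: the
#' KL-compression scale, the base reward (agreement) weight, the softmax
#' temperature, the exponential-moving-average decay of the second belief
#' layer, the base gaze-synchrony weight, the numerical clipping constant,
#' and the Beta priors of the first belief layer.
#'
#' @param kappa Scale of the compressed KL term, `kappa * d / (1 + d)`.
#'   Must be positive. Default 0.1.
#' @param lambda0 Base weight of the agreement/risk term. Default 1.
#' @param tau Softmax temperature for the policy probabilities; lower values
#'   make the policy more deterministic. Must be positive. Default 1.
#' @param ema_alpha Decay of the exponential moving average in the second
#'   belief layer; the weight placed on the most recent partner action.
#'   Must lie in (0, 1]. Default 0.8.
#' @param gamma0 Base synchrony weight in \[0, 1\]; the per-trial weight is
#'   `gamma0 * dtw_norm`. The values studied are 0, 0.1, 0.5 and 0.9.
#'   Default 0.5.
#' @param epsilon Clipping constant applied to probabilities before taking
#'   logarithms; must lie in (0, 0.5). Default 1e-12.
#' @param prior_alpha,prior_beta Beta pseudo-count priors of the first
#'   layer, shared by both action conditions. Must be positive. Defaults 1
#'   and 1 (uniform).
#' @param q_init Initial value of both EMA probabilities; defaults to 0.5,
#'   the mean of the uniform Beta prior, so both layers start at maximal
#'   uncertainty.
#' @param tie_break Action chosen when both candidate actions have exactly
#'   equal free energy: `"no_touch"` (action 0, the default) or `"touch"`.
#' @param seed Optional integer seed recorded for provenance; not consumed
#'   by the deterministic model itself.
#'
#' @return An object of class `"model_config"` (a named list).
#' @examples
#' cfg <- model_config(gamma0 = 0.9)
#' cfg$kappa
#' @export
model_config <- function(kappa = 0.1, lambda0 = 1.0, tau = 1.0,
                         ema_alpha = 0.8, gamma0 = 0.5, epsilon = 1e-12,
                         prior_alpha = 1, prior_beta = 1, q_init = 0.5,
                         tie_break = c("no_touch", "touch"), seed = NULL) {
  tie_break <- match.arg(tie_break)
  stopifnot(
    "kappa must be positive" = is.numeric(kappa) && kappa > 0,
    "tau must be positive" = is.numeric(tau) && tau > 0,
    "ema_alpha must be in (0, 1]" =
      is.numeric(ema_alpha) && ema_alpha > 0 && ema_alpha <= 1,
    "gamma0 must be in [0, 1]" =
      is.numeric(gamma0) && gamma0 >= 0 && gamma0 <= 1,
    "epsilon must be in (0, 0.5)" =
      is.numeric(epsilon) && epsilon > 0 && epsilon < 0.5,
    "prior_alpha must be positive" = is.numeric(prior_alpha) && prior_alpha > 0,
    "prior_beta must be positive" = is.numeric(prior_beta) && prior_beta > 0,
    "q_init must be in [0, 1]" = is.numeric(q_init) && q_init >= 0 && q_init <= 1
  )
  structure(
    list(kappa = kappa, lambda0 = lambda0, tau = tau, ema_alpha = ema_alpha,
         gamma0 = gamma0, epsilon = epsilon, prior_alpha = prior_alpha,
         prior_beta = prior_beta, q_init = q_init, tie_break = tie_break,
         seed = seed),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("Dyadic active-inference model configuration\n")
  cat(sprintf("  kappa = %g, lambda0 = %g, tau = %g\n",
              x$kappa, x$lambda0, x$tau))
  cat(sprintf("  ema_alpha = %g, gamma0 = %g, epsilon = %g\n",
              x$ema_alpha, x$gamma0, x$epsilon))
  cat(sprintf("  Beta prior (%g, %g), q_init = %g, tie_break = %s\n",
              x$prior_alpha, x$prior_beta, x$q_init, x$tie_break))
  invisible(x)
}
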