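#' Kullback-Leibler divergence between two Bernoulli distributions
#'
#' `KL(Bern(q) || Bern(p)) = q log(q/p) + (1-q) log((1-q)/(1-p))`, in nats.
#' Both arguments are clipped to `[epsilon, 1 - epsilon]` before the
#' logarithms, so the value is always finite; with the default clipping,
#' degenerate probabilities 0 and 1 behave as their clipped limits.
#'
#' @param q,p Probabilities in \[0, 1\] (vectorized).
#' @param epsilon Clipping constant, default 1e-12.
#' @return Non-negative divergence(s) in nats; 0 iff the clipped arguments
#'   are equal.
#' @examples
#' bernoulli_kl(0.9, 0.5)  # 0.368064
#' @export
bernoulli_kl <- function(q, p, epsilon = 1e-12) {
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE),
            all(p >= 0 & p <= 1, na.rm = TRUE),
            epsilon > 0, epsilon < 0.5)
  qc <- pmin(pmax(q, epsilon), 1 - epsilon)
  pc <- pmin(pmax(p, epsilon), 1 - epsilon)
  qc * log(qc / pc) + (1 - qc) * log((1 - qc) / (1 - pc))
}

#' Per-action free energy
#'
#' For each candidate self action a in \{0, 1\} the objective is
#' `G(a) = kappa * d / (1 + d) + lambda0 * gamma_t * (2 q(a) - 1)` with
#' `d = KL(Bern(q(a)) || Bern(p(a)))`, where `q(a)` is the second-layer
#' (EMA) prediction and `p(a)` the first-layer (Beta posterior mean)
#' prediction. The first term compresses the divergence between the two
#' belief layers into \[0, kappa); the second is the synchrony-weighted
#' agreement/risk term. Lower free energy marks the preferred action.
#'
#' @param belief A `"dyad_belief"`.
#' @param gamma_t Per-trial synchrony weight in \[0, `gamma0`\]; use 0 when
#'   no gaze data is available for the trial.
#' @param config A [model_config()].
#' @return An object of class `"free_energy_result"`: `g_0`, `g_1`,
#'   `kl_term_0`, `kl_term_1`, `reward_term_0`, `reward_term_1`, `fe_min`.
#' @examples
#' b <- init_belief(model_config())
#' free_energy(b, gamma_t = 0, config = model_config())
#' @export
free_energy <- function(belief, gamma_t, config = model_config()) {
  stopifnot(inherits(belief, "dyad_belief"), inherits(config, "model_config"),
            is.numeric(gamma_t), length(gamma_t) == 1L,
            gamma_t >= 0, gamma_t <= 1)
  one_action <- function(a) {
    q <- ema_estimate(belief, a)
    p <- point_estimate(belief, a)
    d <- bernoulli_kl(q, p, config$epsilon)
    kl_term <- config$kappa * d / (1 + d)
    reward_term <- config$lambda0 * gamma_t * (2 * q - 1)
    c(g = kl_term + reward_term, kl = kl_term, reward = reward_term)
  }
  r0 <- one_action(0)
  r1 <- one_action(1)
  structure(
    list(g_0 = unname(r0["g"]), g_1 = unname(r1["g"]),
         kl_term_0 = unname(r0["kl"]), kl_term_1 = unname(r1["kl"]),
         reward_term_0 = unname(r0["reward"]),
         reward_term_1 = unname(r1["reward"]),
         gamma_t = gamma_t,
         fe_min = min(unname(r0["g"]), unname(r1["g"]))),
    class = "free_energy_result"
  )
}

#' Deterministic action selection with softmax policy probabilities
#'
#' The action is the argmin of the free energies (exact ties resolved by
#' `tie_break`); the softmax `pi(a) = exp(-G(a)/tau) / sum_a' exp(-G(a')/tau)`
#' is reported alongside for evaluation, so the lower-energy action always
#' carries the larger probability.
#'
#' @param result A `"free_energy_result"`.
#' @param tau Softmax temperature, positive.
#' @param tie_break `"no_touch"` (default) or `"touch"`: the action taken
#'   when `g_0 == g_1` exactly.
#' @return A list with `action` (0 or 1), `pi_0`, `pi_1`.
#' @examples
#' b <- init_belief(model_config())
#' select_action(free_energy(b, 0, model_config()), tau = 1)
#' @export
select_action <- function(result, tau = 1.0,
                          tie_break = c("no_touch", "touch")) {
  stopifnot(inherits(result, "free_energy_result"),
            is.numeric(tau), tau > 0)
  tie_break <- match.arg(tie_break)
  g <- c(result$g_0, result$g_1)
  # subtract the min before exponentiating for numerical stability
  w <- exp(-(g - min(g)) / tau)
  pi <- w / sum(w)
  action <- if (g[1] < g[2]) 0L
            else if (g[2] < g[1]) 1L
            else if (tie_break == "no_touch") 0L else 1L
  list(action = action, pi_0 = pi[1], pi_1 = pi[2])
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("Free energy: G(0) = %.4f, G(1) = %.4f (gamma_t = %.3f)\n",
              x$g_0, x$g_1, x$gamma_t))
  invisible(x)
}
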