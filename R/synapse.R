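# Postsynaptic current kernels, total synaptic current, external noise
# drive, and the additive asymmetric STDP rule with hard bounds.

#' Alpha-function postsynaptic current kernel
#'
#' A spike at `t_k` triggers the unit-area kernel
#' \deqn{\alpha(t) = \frac{t - t_k}{\tau_{syn}^2} e^{-(t - t_k)/\tau_{syn}}}
#' which is zero at onset and peaks at \eqn{t - t_k = \tau_{syn}} with
#' value \eqn{1/(e\,\tau_{syn})}.
#'
#' @param t evaluation time(s) (ms), `t >= t_k`.
#' @param t_k spike (onset) time (ms).
#' @param tau_syn kernel time constant (ms), positive.
#' @return Kernel value(s) (1/ms).
#' @export
alpha_psc <- function(t, t_k, tau_syn) {
  stopifnot(tau_syn > 0)
  s <- t - t_k
  ifelse(s < 0, 0, s / tau_syn^2 * exp(-s / tau_syn))
}

#' Total synaptic input current
#'
#' \eqn{I_{syn} = \sum_j W_{ij} (v_i - v_{syn,j})\,\alpha_j}, the
#' conductance-like coupling of all active incoming kernels. It enters
#' the membrane equation with a negative sign, so an excitatory class
#' (\eqn{v_{syn} = 0}) depolarizes a cell below 0 mV.
#'
#' @param post_v postsynaptic membrane potential (mV).
#' @param weight synaptic weight(s), non-negative.
#' @param v_syn reversal potential(s) (mV).
#' @param kernel alpha-kernel value(s) (1/ms).
#' @return Summed synaptic current (same sign convention as the membrane
#'   equation's \eqn{I_{syn}} term).
#' @export
synaptic_current <- function(post_v, weight, v_syn, kernel) {
  stopifnot(all(weight >= 0))
  sum(weight * (post_v - v_syn) * kernel)
}

#' External noise drive specification
#'
#' Each neuron receives a unique Poissonian spike train feeding an
#' excitatory alpha-function synapse (inputs from surrounding
#' structures: cortex for the STN at 20 Hz, striatum for the GPe at
#' 40 Hz — twice the STN rate, so GPe firing is roughly twice STN
#' firing), plus a constant applied current (striatal inhibition of the
#' GPe, -7 pA; none for STN).
#'
#' @param kind `"STN"` or `"GPe"`.
#' @return A list of class `"noise_spec"` with fields `f_p` (Hz),
#'   `w_noise`, `tau_noise` (ms), `v_noise` (mV), `I_app` (pA).
#' @export
noise_spec <- function(kind = c("STN", "GPe")) {
  kind <- match.arg(kind)
  structure(list(
    f_p = if (kind == "STN") 20 else 40,
    w_noise = 0.2, tau_noise = 1.0, v_noise = 0.0,
    I_app = if (kind == "GPe") -7.0 else 0.0,
    kind = kind
  ), class = "noise_spec")
}

#' Additive asymmetric STDP rule
#'
#' Pair-based additive spike-timing-dependent plasticity with hard
#' bounds: for a pre/post spike pair with timing difference
#' \eqn{\Delta t = t_{post} - t_{pre}},
#' \deqn{\Delta w = \lambda e^{-|\Delta t|/\tau_+} \;(\Delta t > 0),
#'   \qquad \Delta w = -\lambda\beta e^{-|\Delta t|/\tau_-}
#'   \;(\Delta t \le 0).}
#' With \eqn{\beta\tau_-/\tau_+ = 1.1 \cdot 27.5/12 \approx 2.52 > 1}
#' the rule is net depressing for uncorrelated spiking, which stabilizes
#' the desynchronized attractor; correlated firing potentiates and
#' stabilizes the synchronized attractor.
#'
#' @param tau_plus potentiation time constant (ms, default 12).
#' @param tau_minus depression time constant (ms, default 27.5).
#' @param lam learning rate (default 2e-3).
#' @param beta depression/potentiation ratio (default 1.1).
#' @param w_max hard upper weight bound (default 20e-3); lower bound 0.
#' @return A list of class `"stdp_rule"`.
#' @export
stdp_rule <- function(tau_plus = 12.0, tau_minus = 27.5, lam = 2.0e-3,
                      beta = 1.1, w_max = 20e-3) {
  stopifnot(tau_plus > 0, tau_minus > 0, lam > 0, beta > 0, w_max > 0)
  structure(list(tau_plus = tau_plus, tau_minus = tau_minus, lam = lam,
                 beta = beta, w_max = w_max, w_min = 0),
            class = "stdp_rule")
}

#' STDP weight change for one spike pair
#'
#' @param dt_pair timing difference \eqn{\Delta t = t_{post} - t_{pre}}
#'   (ms); vectorized. Exact coincidence (\eqn{\Delta t = 0}) falls on
#'   the depression branch.
#' @param rule an [stdp_rule()].
#' @return Weight change(s) \eqn{\Delta w} (unclipped).
#' @export
stdp_delta <- function(dt_pair, rule = stdp_rule()) {
  ifelse(dt_pair > 0,
         rule$lam * exp(-abs(dt_pair) / rule$tau_plus),
         -rule$lam * rule$beta * exp(-abs(dt_pair) / rule$tau_minus))
}

#' Apply a weight change under hard bounds
#'
#' @param weight current weight(s) within `[0, w_max]`.
#' @param delta weight change(s).
#' @param rule an [stdp_rule()].
#' @return Updated weight(s), clipped to `[0, w_max]`.
#' @export
apply_stdp <- function(weight, delta, rule = stdp_rule()) {
  pmin(pmax(weight + delta, rule$w_min), rule$w_max)
}
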