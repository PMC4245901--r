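# Single-compartment Terman-Rubin membrane dynamics for STN and GPe
# cells: gating sigmoids, ionic currents, and the full state derivative.
# This R-level implementation is the definitional form of the model; the
# simulation engine (src/engine.cpp) integrates the same equations.

#' Steady-state activation of a gating variable
#'
#' \eqn{X_\infty(v) = 1/(1+\exp(-(v-\theta_X)/\sigma_X))}. Monotone
#' increasing in `v` for positive slope, decreasing for negative slope,
#' with range (0, 1).
#'
#' @param spec a [gating_spec()].
#' @param v membrane potential (mV); vectorized.
#' @return Activation value(s) in (0, 1).
#' @export
gate_inf <- function(spec, v) {
  1 / (1 + exp(-(v - spec$theta) / spec$sigma))
}

#' Voltage-dependent time constant of a gating variable
#'
#' \eqn{\tau_X(v) = \tau^0_X + \tau^1_X/(1+\exp(-(v-\theta^\tau_X)/\sigma^\tau_X))},
#' bounded between \eqn{\tau^0} and \eqn{\tau^0+\tau^1}. Gates with
#' `tau1 = 0` have a voltage-independent time constant `tau0`.
#'
#' @inheritParams gate_inf
#' @return Time constant(s) in ms.
#' @export
gate_tau <- function(spec, v) {
  if (spec$tau1 == 0) return(rep(spec$tau0, length(v)))
  spec$tau0 + spec$tau1 / (1 + exp(-(v - spec$theta_tau) / spec$sigma_tau))
}

#' Steady-state of the STN b-gate as a function of r
#'
#' The STN low-threshold calcium current deinactivates through
#' \eqn{b_\infty(r)}, a sigmoid of the inactivation variable `r`
#' shifted so that \eqn{b_\infty(0) = 0}:
#' \deqn{b_\infty(r) = 1/(1+\exp(-(r-\theta_b)/\sigma_b)) - 1/(1+\exp(\theta_b/\sigma_b))}
#' expressed through [gate_inf()] in the package's sigmoid convention
#' (slope \eqn{\sigma_b = 0.1}, increasing in `r`: strong rebound drive
#' after sustained hyperpolarization).
#'
#' @param r inactivation variable in [0, 1]; vectorized.
#' @param spec the b-gate [gating_spec()] (default STN values
#'   \eqn{\theta_b = 0.4}, \eqn{\sigma_b = 0.1}).
#' @return \eqn{b_\infty(r)}, zero at `r = 0` and increasing in `r`.
#' @export
b_inf <- function(r, spec = stn_params()$gating$b) {
  gate_inf(spec, r) - gate_inf(spec, 0)
}

#' Construct and validate a cell state
#'
#' @param v membrane potential (mV).
#' @param n,h,r gating variables, clamped to [0, 1].
#' @param Ca intracellular calcium concentration (dimensionless,
#'   non-negative).
#' @return A named numeric vector of class `"cell_state"`.
#' @export
cell_state <- function(v, n, h, r, Ca) {
  stopifnot(is.finite(v), is.finite(n), is.finite(h), is.finite(r), is.finite(Ca))
  structure(c(v = v, n = min(max(n, 0), 1), h = min(max(h, 0), 1),
              r = min(max(r, 0), 1), Ca = max(Ca, 0)),
            class = "cell_state")
}

#' Cell state at the gating steady state for a holding potential
#'
#' All gates are set to their steady-state values at `v`; calcium is set
#' to its quasi-equilibrium \eqn{-(I_{Ca}+I_T)/k_{Ca}} (floored at 0).
#'
#' @param params a `"cell_params"` set.
#' @param v holding potential (mV).
#' @return A `"cell_state"`.
#' @export
steady_cell_state <- function(params, v) {
  g <- params$gating
  st <- cell_state(v = v, n = gate_inf(g$n, v), h = gate_inf(g$h, v),
                   r = gate_inf(g$r, v), Ca = 0)
  cur <- ionic_currents(params, st)
  cell_state(v = v, n = st[["n"]], h = st[["h"]], r = st[["r"]],
             Ca = max(-(cur[["I_Ca"]] + cur[["I_T"]]) / params$k_Ca, 0))
}

#' Ionic membrane currents
#'
#' Evaluates the six intrinsic currents (pA/um^2) of the Terman-Rubin
#' model at a given state:
#' \deqn{I_L = g_L (v-v_L), \quad I_K = g_K n^4 (v-v_K),}
#' \deqn{I_{Na} = g_{Na} m_\infty^3(v)\, h\, (v-v_{Na}),}
#' \deqn{I_T^{STN} = g_T a_\infty^3(v)\, b_\infty^2(r)\, (v-v_{Ca}), \quad
#'       I_T^{GPe} = g_T a_\infty^3(v)\, r\, (v-v_{Ca}),}
#' \deqn{I_{Ca} = g_{Ca} s_\infty^2(v)\, h\, (v-v_{Ca}), \quad
#'       I_{ahp} = g_{ahp} (v-v_K)\, [Ca]/([Ca]+k_1).}
#' The after-hyperpolarization potassium current \eqn{I_{ahp}} grows with
#' intracellular calcium, saturating with half-maximum at \eqn{[Ca]=k_1}.
#'
#' @param params a `"cell_params"` set (STN or GPe).
#' @param state a `"cell_state"` (or named numeric with v, n, h, r, Ca).
#' @param override optional named list of per-neuron heterogenized values
#'   (conductances/reversals) replacing the reference means.
#' @return Named numeric vector `c(I_L, I_K, I_Na, I_T, I_Ca, I_ahp)`.
#' @export
ionic_currents <- function(params, state, override = NULL) {
  p <- params
  if (!is.null(override)) p[names(override)] <- override
  g <- params$gating
  v <- state[["v"]]; n <- state[["n"]]; h <- state[["h"]]
  r <- state[["r"]]; Ca <- state[["Ca"]]
  stopifnot(n >= 0, n <= 1, h >= 0, h <= 1, r >= 0, r <= 1, Ca >= 0)
  I_L <- p$g_L * (v - p$v_L)
  I_K <- p$g_K * n^4 * (v - p$v_K)
  I_Na <- p$g_Na * gate_inf(g$m, v)^3 * h * (v - p$v_Na)
  I_T <- if (identical(p$cell_kind, "STN")) {
    p$g_T * gate_inf(g$a, v)^3 * b_inf(r, g$b)^2 * (v - p$v_Ca)
  } else if (identical(p$cell_kind, "GPe")) {
    p$g_T * gate_inf(g$a, v)^3 * r * (v - p$v_Ca)
  } else {
    stop("unknown cell_kind: ", p$cell_kind)
  }
  I_Ca <- p$g_Ca * gate_inf(g$s, v)^2 * h * (v - p$v_Ca)
  I_ahp <- p$g_ahp * (v - p$v_K) * Ca / (Ca + p$k1)
  c(I_L = I_L, I_K = I_K, I_Na = I_Na, I_T = I_T, I_Ca = I_Ca, I_ahp = I_ahp)
}

#' Time derivative of the full cell state
#'
#' Membrane equation
#' \deqn{c_m \frac{dv}{dt} = -I_L-I_K-I_{Na}-I_T-I_{Ca}-I_{ahp}
#'        - I_{syn} + I_{stim} + I_{noise},}
#' first-order gating kinetics
#' \eqn{dX/dt = \phi_X (X_\infty(v)-X)/\tau_X(v)} for \eqn{X \in \{n,h,r\}},
#' and calcium balance
#' \deqn{\frac{d[Ca]}{dt} = \Gamma\,(-I_{Ca} - I_T - k_{Ca}[Ca])}
#' with \eqn{\Gamma} converted from its per-second statement to the
#' per-millisecond time base.
#'
#' @inheritParams ionic_currents
#' @param I_syn,I_stim,I_noise input currents (pA/um^2); `I_syn` enters
#'   with a negative sign (an excitatory synaptic term, which is negative
#'   below its reversal potential, therefore depolarizes).
#' @return Named numeric vector of derivatives `c(v, n, h, r, Ca)` (per ms).
#' @export
cell_derivative <- function(params, state, I_syn = 0, I_stim = 0, I_noise = 0,
                            override = NULL) {
  stopifnot(is.finite(I_syn), is.finite(I_stim), is.finite(I_noise),
            all(is.finite(unclass(state))))
  p <- params
  if (!is.null(override)) p[names(override)] <- override
  g <- params$gating
  cur <- ionic_currents(params, state, override = override)
  v <- state[["v"]]
  dv <- (-sum(cur) - I_syn + I_stim + I_noise) / p$c_m
  dn <- g$n$phi * (gate_inf(g$n, v) - state[["n"]]) / gate_tau(g$n, v)
  dh <- g$h$phi * (gate_inf(g$h, v) - state[["h"]]) / gate_tau(g$h, v)
  dr <- g$r$phi * (gate_inf(g$r, v) - state[["r"]]) / gate_tau(g$r, v)
  eps <- p$Gamma * 1e-3  # Gamma stated per second; model time is ms
  dCa <- eps * (-cur[["I_Ca"]] - cur[["I_T"]] - p$k_Ca * state[["Ca"]])
  c(v = dv, n = dn, h = dh, r = dr, Ca = dCa)
}
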