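# High-accuracy single-neuron reference integration (deSolve/lsoda).
# Serves as the independent oracle against which the network engine's
# single-neuron trajectories are validated (spike period within 1%).

#' Integrate a single isolated neuron with a stiff adaptive solver
#'
#' Solves the five-dimensional single-cell system with `deSolve::lsoda`
#' at tight tolerances, independently of the network engine. Intended as
#' a reference for convergence and spike-period checks, and for
#' exploring single-cell behaviour (e.g. the tonic firing of an isolated
#' STN cell at mean parameters with zero input).
#'
#' @param params a `"cell_params"` set.
#' @param duration simulated time (ms).
#' @param v0 initial potential (mV); gates start at their steady state
#'   for `v0` via [steady_cell_state()].
#' @param I_const constant injected current (pA/um^2), added as
#'   `I_stim`.
#' @param dt_out output sampling interval (ms).
#' @param rtol,atol solver tolerances.
#' @param override optional heterogenized parameter values.
#' @return A list with `times`, state `trace` (matrix with columns
#'   v, n, h, r, Ca), detected `spikes` (ms) and the mean inter-spike
#'   `period` (ms, `NA` if fewer than two spikes after discarding an
#'   initial 10% transient).
#' @export
single_neuron_reference <- function(params, duration, v0 = -62, I_const = 0,
                                    dt_out = 0.05, rtol = 1e-8, atol = 1e-8,
                                    override = NULL) {
  st <- steady_cell_state(params, v0)
  times <- seq(0, duration, by = dt_out)
  deriv <- function(t, y, parms) {
    list(cell_derivative(params, y, I_stim = I_const, override = override))
  }
  sol <- deSolve::lsoda(y = unclass(st), times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  trace <- sol[, -1, drop = FALSE]
  spikes <- detect_spikes(trace[, "v"], dt = dt_out, threshold = -10)
  keep <- spikes[spikes > duration * 0.1]
  period <- if (length(keep) >= 2) mean(diff(keep)) else NA_real_
  list(times = times, trace = trace, spikes = spikes, period = period)
}
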