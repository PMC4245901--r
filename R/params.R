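#' Gating-variable kinetic specification
#'
#' Bundles the parameters of one Hodgkin-Huxley-type gating variable
#' \eqn{X}: the steady-state sigmoid
#' \deqn{X_\infty(v) = 1/(1 + \exp(-(v - \theta_X)/\sigma_X))}
#' and (for non-instantaneous gates) the voltage-dependent time constant
#' \deqn{\tau_X(v) = \tau^0_X + \tau^1_X/(1 + \exp(-(v - \theta^\tau_X)/\sigma^\tau_X))}
#' together with the dimensionless rate scale \eqn{\phi_X} entering
#' \eqn{dX/dt = \phi_X (X_\infty(v) - X)/\tau_X(v)}.
#'
#' @param theta half-activation voltage (mV).
#' @param sigma activation slope (mV); positive for activation gates,
#'   negative for inactivation gates. Must be non-zero.
#' @param phi dimensionless rate scale (1 for instantaneous gates).
#' @param tau0 baseline time constant (ms), non-negative.
#' @param tau1 amplitude of the voltage-dependent part of the time
#'   constant (ms), non-negative; 0 gives a voltage-independent constant.
#' @param theta_tau half-voltage of the time-constant sigmoid (mV).
#' @param sigma_tau slope of the time-constant sigmoid (mV), non-zero
#'   whenever `tau1 > 0`.
#' @return An object of class `"gating_spec"`.
#' @export
gating_spec <- function(theta, sigma, phi = 1, tau0 = 0, tau1 = 0,
                        theta_tau = 0, sigma_tau = 1) {
  stopifnot(sigma != 0, tau0 >= 0, tau1 >= 0)
  if (tau1 > 0 && sigma_tau == 0) stop("sigma_tau must be non-zero when tau1 > 0")
  structure(list(theta = theta, sigma = sigma, phi = phi, tau0 = tau0,
                 tau1 = tau1, theta_tau = theta_tau, sigma_tau = sigma_tau),
            class = "gating_spec")
}

#' Reference parameter set for STN neurons
#'
#' Single-compartment Terman-Rubin parameters for subthalamic nucleus
#' neurons: maximal conductances (nS/um^2), reversal potentials (mV),
#' calcium-handling constants and the kinetic specification of each
#' gating variable. The `b` gate is a function of the inactivation
#' variable `r` rather than of voltage; its sigmoid carries an offset so
#' that \eqn{b_\infty(0) = 0} (see [b_inf()]).
#'
#' The calcium scale factor `Gamma` is stated per second and converted
#' to the per-millisecond time base of the model internally.
#'
#' @return A list of class `"cell_params"` with `cell_kind = "STN"`.
#' @seealso [gpe_params()], [heterogenize_params()]
#' @export
stn_params <- function() {
  structure(list(
    cell_kind = "STN",
    g_L = 2.25, g_K = 45.0, g_Na = 37.5, g_Ca = 0.5, g_ahp = 9.0, g_T = 0.5,
    v_L = -60.0, v_K = -80.0, v_Na = 55.0, v_Ca = 140.0,
    k1 = 15.0, k_Ca = 22.5, Gamma = 0.0375, c_m = 1.0,
    gating = list(
      m = gating_spec(theta = -30.0, sigma = 15.0),
      h = gating_spec(theta = -39.0, sigma = -3.1, phi = 0.75,
                      tau0 = 1.0, tau1 = 500.0, theta_tau = -57.0, sigma_tau = -3.0),
      n = gating_spec(theta = -32.0, sigma = 8.0, phi = 0.75,
                      tau0 = 1.0, tau1 = 100.0, theta_tau = -80.0, sigma_tau = -26.0),
      r = gating_spec(theta = -67.0, sigma = -2.0, phi = 0.2,
                      tau0 = 40.0, tau1 = 17.5, theta_tau = 68.0, sigma_tau = -2.2),
      a = gating_spec(theta = -63.0, sigma = 7.8),
      b = gating_spec(theta = 0.4, sigma = 0.1),
      s = gating_spec(theta = -39.0, sigma = 8.0)
    )
  ), class = "cell_params")
}

#' Reference parameter set for GPe neurons
#'
#' Terman-Rubin parameters for globus pallidus externus neurons. The GPe
#' low-threshold calcium current uses the inactivation variable `r`
#' directly (no `b` gate), and the `r` time constant is voltage
#' independent (30 ms).
#'
#' @return A list of class `"cell_params"` with `cell_kind = "GPe"`.
#' @export
gpe_params <- function() {
  structure(list(
    cell_kind = "GPe",
    g_L = 0.1, g_K = 30.0, g_Na = 120.0, g_Ca = 0.15, g_ahp = 30.0, g_T = 0.5,
    v_L = -55.0, v_K = -80.0, v_Na = 55.0, v_Ca = 120.0,
    k1 = 30.0, k_Ca = 20.0, Gamma = 0.1, c_m = 1.0,
    gating = list(
      m = gating_spec(theta = -37.0, sigma = 10.0),
      h = gating_spec(theta = -58.0, sigma = -12.0, phi = 0.05,
                      tau0 = 0.05, tau1 = 0.27, theta_tau = -40.0, sigma_tau = -12.0),
      n = gating_spec(theta = -50.0, sigma = 14.0, phi = 0.05,
                      tau0 = 0.05, tau1 = 0.27, theta_tau = -40.0, sigma_tau = -12.0),
      r = gating_spec(theta = -70.0, sigma = -2.0, phi = 1.0,
                      tau0 = 30.0, tau1 = 0.0),
      a = gating_spec(theta = -57.0, sigma = 2.0),
      s = gating_spec(theta = -35.0, sigma = 2.0)
    )
  ), class = "cell_params")
}

#' Draw heterogenized per-neuron biophysical parameters
#'
#' Maximal conductances and reversal potentials are drawn independently
#' per neuron from Gaussians centred on the reference values with a
#' standard deviation equal to a fraction (default 5%) of the mean;
#' conductances are truncated at zero. Gating kinetics and calcium
#' constants are shared by all neurons of a kind.
#'
#' @param params a `"cell_params"` reference set ([stn_params()] or
#'   [gpe_params()]).
#' @param n number of neurons.
#' @param sd_frac standard deviation as a fraction of each mean value.
#' @param seed optional integer seed for reproducible draws.
#' @return A data.frame with `n` rows and one column per heterogenized
#'   parameter (`g_L, g_K, g_Na, g_Ca, g_ahp, g_T, v_L, v_K, v_Na, v_Ca`).
#' @export
heterogenize_params <- function(params, n, sd_frac = 0.05, seed = NULL) {
  stopifnot(inherits(params, "cell_params"), n >= 1, sd_frac >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cond <- c("g_L", "g_K", "g_Na", "g_Ca", "g_ahp", "g_T")
  revp <- c("v_L", "v_K", "v_Na", "v_Ca")
  out <- lapply(c(cond, revp), function(p) {
    x <- stats::rnorm(n, mean = params[[p]], sd = abs(params[[p]]) * sd_frac)
    if (p %in% cond) x <- pmax(x, 0)
    x
  })
  names(out) <- c(cond, revp)
  as.data.frame(out)
}
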