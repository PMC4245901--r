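# R-side interface to the network integration core: configuration,
# system assembly (gating lookup tables, kernel slots, edge CSR inputs,
# noise and stimulation programs) and the run wrappers.

#' Engine configuration
#'
#' @param dt_event event-grid resolution (ms, default 0.1): spike
#'   detection accuracy, delay quantization and noise/stimulation event
#'   timing all live on this grid. Transmission delays must be integer
#'   multiples of it.
#' @param record_dt recording resolution for population traces (ms,
#'   default 1.0); must be a multiple of `dt_event`.
#' @param spike_threshold membrane-potential threshold for the combined
#'   threshold/local-maximum spike detection (mV, default -10: well
#'   above subthreshold oscillations, below spike peaks).
#' @param abs_tol,rel_tol local error tolerances of the adaptive
#'   Runge-Kutta-Fehlberg 4(5) integrator.
#' @param seed master integer seed for all engine randomness (noise
#'   streams, initial conditions).
#' @return A list of class `"engine_config"`.
#' @export
engine_config <- function(dt_event = 0.1, record_dt = 1.0,
                          spike_threshold = -10, abs_tol = 1e-6,
                          rel_tol = 1e-6, seed = 1L) {
  stopifnot(dt_event > 0, record_dt >= dt_event)
  structure(list(dt_event = dt_event, record_dt = record_dt,
                 spike_threshold = spike_threshold, abs_tol = abs_tol,
                 rel_tol = rel_tol, seed = seed),
            class = "engine_config")
}

# gating lookup tables for the C++ core, built from the definitional
# R-level gating functions so parameter overrides flow through
.gating_tables <- function(params, v_range = c(-150, 80), dv = 0.02) {
  g <- params$gating
  v <- seq(v_range[1], v_range[2], by = dv)
  gates <- cbind(
    gate_inf(g$m, v), gate_inf(g$h, v), gate_inf(g$n, v), gate_inf(g$r, v),
    gate_inf(g$a, v), gate_inf(g$s, v),
    gate_tau(g$h, v), gate_tau(g$n, v), gate_tau(g$r, v))
  out <- list(v0 = v_range[1], dv = dv, gates = gates,
              phi_h = g$h$phi, phi_n = g$n$phi, phi_r = g$r$phi,
              k1 = params$k1, k_Ca = params$k_Ca,
              eps = params$Gamma * 1e-3, c_m = params$c_m,
              I_app = 0.0)
  if (!is.null(g$b)) {
    r <- seq(0, 1, length.out = 2049)
    out$b_table <- list(x0 = 0, dx = r[2] - r[1], y = b_inf(r, g$b))
  }
  out
}

# initial state: potentials uniform in v_range, gates at steady state,
# calcium at quasi-equilibrium
.initial_state <- function(params_ref, het, v0) {
  g <- params_ref$gating
  n <- gate_inf(g$n, v0); h <- gate_inf(g$h, v0); r <- gate_inf(g$r, v0)
  bt <- if (identical(params_ref$cell_kind, "STN")) b_inf(r, g$b)^2 else r
  I_T <- het$g_T * gate_inf(g$a, v0)^3 * bt * (v0 - het$v_Ca)
  I_Ca <- het$g_Ca * gate_inf(g$s, v0)^2 * h * (v0 - het$v_Ca)
  Ca <- pmax(-(I_Ca + I_T) / params_ref$k_Ca, 0)
  cbind(v0, n, h, r, Ca)
}

# kernel slot metadata per cell kind; slot 0 = excitatory network input,
# slot 1 = inhibitory network input, slot 2 = noise
.slot_meta <- function() {
  cls <- synapse_classes()
  gv <- function(nm, f) cls[[f]][cls$name == nm]
  list(
    list(tau_idx = c(0, 1, 0),
         v_syn = c(gv("ss", "v_syn"), gv("gs", "v_syn"), gv("noise", "v_syn"))),
    list(tau_idx = c(0, 1, 0),
         v_syn = c(gv("sg", "v_syn"), gv("gg", "v_syn"), gv("noise", "v_syn")))
  )
}

#' Run the coupled STN-GPe network
#'
#' Advances the full network for `duration` ms: adaptive RKF45
#' integration of the membrane/gating/calcium states, exact analytic
#' alpha-kernel dynamics, delayed spike delivery on a 0.1 ms event grid,
#' optional STDP on ss synapses and optional CR stimulation. Results are
#' deterministic under a fixed `config` seed.
#'
#' @param network an [build_network()] object.
#' @param duration biological time to simulate (ms).
#' @param config an [engine_config()].
#' @param stdp `TRUE` (default) to evolve ss weights under the STDP
#'   rule, `FALSE` to freeze all weights; or an [stdp_rule()].
#' @param lam_mult multiplier on the STDP learning rate (compresses the
#'   slow weight dynamics into shorter simulated protocols; recorded in
#'   the run metadata).
#' @param noise `TRUE` for the standard Poisson + applied-current drive
#'   ([noise_spec()]), `FALSE` for none.
#' @param stim `NULL` for no stimulation, or a list with elements
#'   `schedule` ([cr_schedule()]), `pulse` ([pulse_spec()]), `t_on`,
#'   `t_off` (ms) and optional `gain` (default 1); requires the network
#'   to carry an electrode.
#' @param kernel_norm alpha-kernel amplitude convention: `"peak"`
#'   (default) scales every synapse so that a unit weight produces a
#'   unit-amplitude postsynaptic kernel at its maximum (the convention
#'   of common simulation platforms; amplitude factor `e * tau_syn` on
#'   the unit-area kernel), `"area"` uses the unit-area kernel
#'   literally.
#' @param record_ids optional global neuron ids (1..n) whose membrane
#'   potential is recorded at `record_dt`.
#' @param init_state optional n x 5 state matrix to resume from (e.g.
#'   `$state` of a previous run).
#' @param init_w_ss optional vector of ss weights to resume from.
#' @return A list of class `"stngpe_run"`: `raster` (data.frame `id`,
#'   `time`; STN ids are `1..n_stn`), `rec` (data.frame `t`,
#'   `mean_v_stn`, `mean_v_gpe`, `mean_w_ss`), `v_traces`, `state`,
#'   `w_ss`, `meta`.
#' @export
run_network <- function(network, duration, config = engine_config(),
                        stdp = TRUE, lam_mult = 1, noise = TRUE, stim = NULL,
                        kernel_norm = c("peak", "area"),
                        record_ids = NULL, init_state = NULL, init_w_ss = NULL) {
  kernel_norm <- match.arg(kernel_norm)
  stopifnot(inherits(network, "stngpe_network"), duration >= 0)
  cfg <- network$config
  n_stn <- cfg$n_stn; n_gpe <- cfg$n_gpe; n <- n_stn + n_gpe
  cls <- synapse_classes()

  rule <- if (inherits(stdp, "stdp_rule")) stdp else stdp_rule(w_max = cfg$w_max)
  stdp_on <- !identical(stdp, FALSE)

  pr_stn <- network$cell_params$stn_ref
  pr_gpe <- network$cell_params$gpe_ref
  tab_stn <- .gating_tables(pr_stn)
  tab_gpe <- .gating_tables(pr_gpe)
  ns_stn <- noise_spec("STN"); ns_gpe <- noise_spec("GPe")
  # constant applied current is part of the cell environment; disabled
  # only jointly with the Poisson drive
  if (isTRUE(noise) || is.list(noise)) {
    iam <- if (is.list(noise) && !is.null(noise$I_app_mult)) noise$I_app_mult else 1
    tab_gpe$I_app <- ns_gpe$I_app * iam
    tab_stn$I_app <- ns_stn$I_app * iam
  }

  pm <- as.matrix(rbind(network$cell_params$stn, network$cell_params$gpe))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  v0 <- stats::runif(n, -65, -55)
  state0 <- rbind(
    .initial_state(pr_stn, network$cell_params$stn, v0[seq_len(n_stn)]),
    .initial_state(pr_gpe, network$cell_params$gpe, v0[n_stn + seq_len(n_gpe)]))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (!is.null(init_state)) state0 <- unname(as.matrix(init_state))

  gain_ref <- cfg$syn_gain_ref
  knorm <- function(tau) if (kernel_norm == "peak") exp(1) * tau else 1
  gain_for <- function(n_src, tau) {
    (if (is.null(gain_ref)) 1 else gain_ref / n_src) * knorm(tau)
  }
  mk_edge <- function(e, slot, gain, plastic, src_off, dst_off) {
    list(pre = as.integer(e$pre - 1L + src_off),
         post = as.integer(e$post - 1L + dst_off),
         weight = as.numeric(e$weight), slot = as.integer(slot),
         gain = gain, delay = e$delay[1] %||% 4.0, plastic = plastic)
  }
  `%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
  w_ss <- if (!is.null(init_w_ss)) init_w_ss else network$edges$ss$weight
  ess <- network$edges$ss; ess$weight <- w_ss
  edges <- list(
    mk_edge(ess, 0L, gain_for(n_stn, 1.0), TRUE, 0L, 0L),
    mk_edge(network$edges$sg, 0L, gain_for(n_stn, 1.0), FALSE, 0L, n_stn),
    mk_edge(network$edges$gs, 1L, gain_for(n_gpe, 3.3), FALSE, n_stn, 0L),
    mk_edge(network$edges$gg, 1L, gain_for(n_gpe, 3.3), FALSE, n_stn, n_stn))
  edges <- Filter(function(e) length(e$pre) > 0, edges)

  w_mult <- if (is.list(noise)) noise$w_mult %||% 1 else 1
  noise_on <- isTRUE(noise) || is.list(noise)
  noise_rate <- if (noise_on) {
    c(rep(ns_stn$f_p, n_stn), rep(ns_gpe$f_p, n_gpe)) / 1000
  } else rep(0, n)
  noise_w <- w_mult * knorm(ns_stn$tau_noise) *
    c(rep(ns_stn$w_noise, n_stn), rep(ns_gpe$w_noise, n_gpe))

  stim_in <- NULL
  seq_tab <- NULL
  if (!is.null(stim)) {
    if (is.null(network$electrode)) stop("network carries no electrode; rebuild with one")
    el <- network$electrode
    pulse <- stim$pulse %||% pulse_spec()
    t_on <- stim$t_on %||% 0
    t_off <- stim$t_off %||% duration
    seq_tab <- cr_sequence(stim$schedule, horizon = t_off - t_on,
                           pulse = pulse, t_start = t_on)
    gains <- matrix(vapply(seq_len(el$n_contacts), function(j) {
      d <- distance_to_contact(network$positions$stn, el, j)
      field_profile(d, el$contact_length, el$d_min)
    }, numeric(n_stn)), nrow = n_stn)
    # kappa * S(d) is a current density in mA/mm^2; the membrane equation
    # uses pA/um^2 (1 mA/mm^2 = 1000 pA/um^2). `gain` is an additional
    # dimensionless knob on top of the unit conversion.
    stim_in <- list(gains = gains * 1000 * (stim$gain %||% 1.0),
                    onset = seq_tab$onset, contact = as.integer(seq_tab$contact),
                    kappa = pulse$kappa, omega = pulse$omega, p_s = pulse$p_s)
  }

  sys <- list(
    n_stn = as.integer(n_stn), n = as.integer(n),
    tables = list(tab_stn, tab_gpe),
    cell_params = pm, state0 = state0,
    slots = .slot_meta(), kernel_taus = c(1.0, 3.3),
    edges = edges,
    stdp = list(enabled = stdp_on, lam = rule$lam * lam_mult, beta = rule$beta,
                tau_plus = rule$tau_plus, tau_minus = rule$tau_minus,
                w_max = rule$w_max),
    noise = list(rate_per_ms = noise_rate, w_noise = noise_w),
    stim = stim_in)
  ccfg <- list(duration = duration, dt_event = config$dt_event,
               record_dt = config$record_dt,
               spike_threshold = config$spike_threshold,
               abs_tol = config$abs_tol, rel_tol = config$rel_tol,
               seed = as.double(config$seed), record_ids = record_ids)
  out <- .engine_run(sys, ccfg)
  structure(list(
    raster = data.frame(id = out$spike_id, time = out$spike_t),
    rec = data.frame(t = out$rec_t, mean_v_stn = out$mean_v_stn,
                     mean_v_gpe = out$mean_v_gpe, mean_w_ss = out$mean_w_ss),
    v_traces = out$v_traces, state = out$state, w_ss = out$w_ss,
    meta = list(n_stn = n_stn, n_gpe = n_gpe, duration = duration,
                config = config, stdp = stdp_on, lam_mult = lam_mult,
                noise = isTRUE(noise),
                stim = if (is.null(stim)) NULL else
                  list(kappa = (stim$pulse %||% pulse_spec())$kappa,
                       gain = stim$gain %||% 1.0,
                       t_on = stim$t_on %||% 0, t_off = stim$t_off %||% duration,
                       n_pulses = if (is.null(seq_tab)) 0L else nrow(seq_tab)),
                record_ids = record_ids, seed = config$seed)),
    class = "stngpe_run")
}

#' Run one isolated neuron through the network engine
#'
#' Convenience wrapper that builds a one-neuron, edge-free system (no
#' noise by default) and integrates it with the engine, e.g. for
#' comparing the engine's single-neuron trajectory with the independent
#' reference solver ([single_neuron_reference()]).
#'
#' @param kind `"STN"` or `"GPe"`.
#' @param duration simulated time (ms).
#' @param v0 initial potential (mV); gates start at steady state.
#' @param I_const constant injected current (pA/um^2) realized through a
#'   unit stimulation gain.
#' @param config an [engine_config()].
#' @return An `"stngpe_run"` (raster ids are all 1).
#' @export
run_single_neuron <- function(kind = c("STN", "GPe"), duration, v0 = -62,
                              I_const = 0, config = engine_config()) {
  kind <- match.arg(kind)
  ref <- if (kind == "STN") stn_params() else gpe_params()
  het <- as.data.frame(as.list(unlist(
    ref[c("g_L", "g_K", "g_Na", "g_Ca", "g_ahp", "g_T",
          "v_L", "v_K", "v_Na", "v_Ca")])))
  tab <- .gating_tables(ref)
  state0 <- .initial_state(ref, het, v0)
  sys <- list(
    n_stn = if (kind == "STN") 1L else 0L, n = 1L,
    tables = if (kind == "STN") list(tab, .gating_tables(gpe_params()))
             else list(.gating_tables(stn_params()), tab),
    cell_params = as.matrix(het), state0 = state0,
    slots = .slot_meta(), kernel_taus = c(1.0, 3.3),
    edges = list(),
    stdp = list(enabled = FALSE, lam = 0, beta = 1, tau_plus = 1,
                tau_minus = 1, w_max = 1),
    noise = list(rate_per_ms = 0.0, w_noise = 0.0),
    stim = if (I_const != 0) list(
      gains = matrix(1.0, 1, 1),
      onset = 0.0, contact = 1L, kappa = I_const,
      omega = duration + 1, p_s = 1) else NULL)
  # a constant current is encoded as a single never-ending cathodal phase
  if (!is.null(sys$stim) && kind == "GPe")
    stop("constant-current single-neuron runs are supported for STN only")
  ccfg <- list(duration = duration, dt_event = config$dt_event,
               record_dt = config$record_dt,
               spike_threshold = config$spike_threshold,
               abs_tol = config$abs_tol, rel_tol = config$rel_tol,
               seed = as.double(config$seed), record_ids = 1L)
  out <- .engine_run(sys, ccfg)
  structure(list(
    raster = data.frame(id = out$spike_id, time = out$spike_t),
    rec = data.frame(t = out$rec_t, mean_v_stn = out$mean_v_stn,
                     mean_v_gpe = out$mean_v_gpe, mean_w_ss = out$mean_w_ss),
    v_traces = out$v_traces, state = out$state, w_ss = out$w_ss,
    meta = list(n_stn = if (kind == "STN") 1L else 0L,
                n_gpe = if (kind == "GPe") 1L else 0L,
                duration = duration, config = config)),
    class = "stngpe_run")
}

#' Mean inter-spike period of a run's raster
#'
#' @param run an `"stngpe_run"`.
#' @param transient initial time to discard (ms).
#' @param id neuron id (default 1).
#' @return Mean inter-spike interval (ms), `NA` with fewer than 2 spikes.
#' @export
spike_period <- function(run, transient = 0, id = 1L) {
  st <- run$raster$time[run$raster$id == id & run$raster$time > transient]
  if (length(st) < 2) return(NA_real_)
  mean(diff(sort(st)))
}
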