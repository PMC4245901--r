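# Scenario runners: spontaneous-state characterization, weight
# bistability, CR amplitude scans and electrode-displacement scans at
# configurable (reduced) scale. Each runner returns the observables of
# the corresponding full-scale experiment plus a manifest sufficient to
# re-run it bit-identically.

#' Classify the attractor reached by a run
#'
#' Thresholds on the mean ss weight and the time-averaged STN order
#' parameter: `mean_w < 0.25 w_max` and `R < 0.2` is the desynchronized
#' attractor, `mean_w > 0.75 w_max` and `R > 0.6` the synchronized one;
#' anything else is reported unclassified (non-converged).
#'
#' @param mean_w mean ss weight at the end of the run.
#' @param R time-averaged STN order parameter.
#' @param w_max hard upper weight bound.
#' @return `"synchronized"`, `"desynchronized"` or `"unclassified"`.
#' @export
classify_attractor <- function(mean_w, R, w_max = 20e-3) {
  if (mean_w < 0.25 * w_max && R < 0.2) "desynchronized"
  else if (mean_w > 0.75 * w_max && R > 0.6) "synchronized"
  else "unclassified"
}

# shared summary of a finished run over an analysis window
.summarize_run <- function(run, net, t_range, dt_phase = 1.0) {
  n_stn <- run$meta$n_stn; n_gpe <- run$meta$n_gpe
  r <- run$raster
  stn <- r[r$id <= n_stn & r$time >= t_range[1] & r$time <= t_range[2], ]
  gpe <- r[r$id > n_stn & r$time >= t_range[1] & r$time <= t_range[2], ]
  times <- seq(t_range[1], t_range[2], by = dt_phase)
  R_stn <- order_parameter_trace(stn, times, seq_len(n_stn))
  R_gpe <- order_parameter_trace(gpe, times, n_stn + seq_len(n_gpe))
  keep <- run$rec$t >= t_range[1] & run$rec$t <= t_range[2]
  list(
    R_stn = mean(R_stn, na.rm = TRUE), R_gpe = mean(R_gpe, na.rm = TRUE),
    R_stn_trace = R_stn, times = times,
    isi_stn = if (nrow(stn) > n_stn) isi_stats(stn) else NULL,
    isi_gpe = if (nrow(gpe) > n_gpe) isi_stats(gpe) else NULL,
    mean_v_stn = mean(run$rec$mean_v_stn[keep]),
    mean_v_gpe = mean(run$rec$mean_v_gpe[keep]),
    mean_w = tail(run$rec$mean_w_ss, 1),
    local = tryCatch(local_order(net$positions$stn, stn, t_range = t_range),
                     error = function(e) NULL))
}

#' Spontaneous activity of the network in one of its two regimes
#'
#' Simulates the unstimulated network in the weak-coupling
#' (desynchronized, "healthy") or strong-coupling (synchronized,
#' "parkinsonian") regime and reports the standard observable set:
#' population order parameters, ISI statistics (median, MD, median
#' rate), mean membrane potentials and the voxel-local order parameter.
#'
#' @param state `"desynchronized"` (initial mean ss weight 2e-3) or
#'   `"synchronized"` (18e-3).
#' @param n neurons per nucleus (default 500, the package's reduced
#'   reference scale).
#' @param duration total simulated time (ms).
#' @param transient initial time excluded from all averages (ms).
#' @param seed master seed (network and engine seeds derive from it).
#' @param stdp evolve ss weights under STDP (default TRUE).
#' @param config optional [engine_config()] (seed field is overridden).
#' @return A list with the summary fields of the regime (see above),
#'   the full `run`, the `net`, and a `manifest`.
#' @export
run_spontaneous <- function(state = c("desynchronized", "synchronized"),
                            n = 500, duration = 35000, transient = 5000,
                            seed = 1, stdp = TRUE, config = NULL) {
  state <- match.arg(state)
  w0 <- if (state == "synchronized") 18e-3 else 2e-3
  net <- build_network(network_config(n_stn = n, n_gpe = n, w_ss0 = w0),
                       seed = seed)
  cfg <- config %||% engine_config()
  cfg$seed <- seed + 1000L
  run <- run_network(net, duration, cfg, stdp = stdp)
  out <- .summarize_run(run, net, c(transient, duration))
  out$state <- state
  out$run <- run
  out$net <- net
  out$manifest <- list(state = state, n = n, duration = duration,
                       transient = transient, seed = seed, stdp = stdp,
                       w_ss0 = w0)
  out
}

#' Bistability of the mean synaptic weight under STDP
#'
#' Runs the plastic network from a grid of initial mean ss weights and
#' classifies the attractor each trajectory approaches: initial weights
#' below the separatrix decay monotonically toward the weak-coupling
#' desynchronized state, initial weights above it grow toward the
#' strongly coupled synchronized state.
#'
#' @param w0_grid initial mean ss weights.
#' @param n neurons per nucleus.
#' @param duration simulated time per trajectory (ms).
#' @param lam_mult learning-rate multiplier (reported in the manifest).
#'   The default 1 is deliberate: multipliers above ~2 let single spike
#'   pairs move a weight across a large part of its range, which
#'   destroys the coexistence of the two attractors — protocols are
#'   compressed by shortening epochs, not by accelerating the rule.
#' @param seed master seed.
#' @param window final fraction of the run used for classification.
#' @return A list with `summary` (data.frame: `w0`, `w_final`, `R_stn`,
#'   `attractor`, `monotone_fraction`), `trajectories` (mean-weight time
#'   series per w0) and a `manifest`.
#' @export
run_bistability <- function(w0_grid = c(2e-3, 18e-3), n = 400,
                            duration = 15000, lam_mult = 1, seed = 1,
                            window = 0.25) {
  rows <- list(); traj <- list()
  for (k in seq_along(w0_grid)) {
    w0 <- w0_grid[k]
    net <- build_network(network_config(n_stn = n, n_gpe = n, w_ss0 = w0),
                         seed = seed)
    cfg <- engine_config(seed = seed + 7L)
    run <- run_network(net, duration, cfg, stdp = TRUE, lam_mult = lam_mult)
    t0 <- duration * (1 - window)
    s <- .summarize_run(run, net, c(t0, duration))
    w_t <- run$rec$mean_w_ss
    # smoothed drift direction: fraction of 1-s steps moving toward the
    # endpoint (monotone approach of the attractor)
    sm <- moving_average(w_t, window = 1000, dt = run$meta$config$record_dt)
    d <- diff(sm[seq(1, length(sm), by = 1000)])
    mono <- if (length(d) == 0) 1 else mean(sign(d) == sign(tail(sm, 1) - sm[1]) | d == 0)
    rows[[k]] <- data.frame(w0 = w0, w_final = s$mean_w, R_stn = s$R_stn,
                            attractor = classify_attractor(s$mean_w, s$R_stn,
                                                           net$config$w_max),
                            monotone_fraction = mono)
    traj[[k]] <- data.frame(t = run$rec$t, mean_w = w_t)
  }
  list(summary = do.call(rbind, rows), trajectories = traj,
       manifest = list(w0_grid = w0_grid, n = n, duration = duration,
                       lam_mult = lam_mult, seed = seed))
}

#' One coordinated-reset stimulation protocol
#'
#' Pre-stimulation epoch, CR stimulation epoch, post-stimulation washout
#' in a single continuous plastic simulation; the outcome measure is the
#' voxel-local order parameter averaged over the final window, after the
#' system has settled into an attractor.
#'
#' @param net an electrode-equipped network ([build_network()]).
#' @param kappa cathodal pulse amplitude (model mA; negative).
#' @param t_pre,t_stim,t_post epoch durations (ms).
#' @param avg_window duration of the final averaging window (ms).
#' @param lam_mult STDP learning-rate multiplier.
#' @param gain stimulation conversion gain.
#' @param seed engine/schedule seed.
#' @param config optional [engine_config()].
#' @return A list: `r1_bar`, `sigma_r1`, `mean_w`, `R_stn`, `summary`
#'   fields, and the `run`.
#' @export
cr_experiment <- function(net, kappa, t_pre = 5000, t_stim = 25000,
                          t_post = 10000, avg_window = 5000, lam_mult = 1,
                          gain = 1, seed = 1, config = NULL) {
  stopifnot(!is.null(net$electrode))
  duration <- t_pre + t_stim + t_post
  cfg <- config %||% engine_config()
  cfg$seed <- seed + 31L
  stim <- if (kappa != 0) list(schedule = cr_schedule(seed = seed + 77L),
                               pulse = pulse_spec(kappa = kappa),
                               t_on = t_pre, t_off = t_pre + t_stim,
                               gain = gain) else NULL
  run <- run_network(net, duration, cfg, stdp = TRUE, lam_mult = lam_mult,
                     stim = stim)
  s <- .summarize_run(run, net, c(duration - avg_window, duration))
  list(kappa = kappa,
       r1_bar = if (is.null(s$local)) NA_real_ else s$local$r1_bar,
       sigma_r1 = if (is.null(s$local)) NA_real_ else s$local$sigma_r1,
       mean_w = s$mean_w, R_stn = s$R_stn, summary = s, run = run)
}

#' CR amplitude scan
#'
#' Sweeps the cathodal amplitude over a grid (one network realization
#' reused across the grid, a paired comparison) and reports the
#' post-stimulation local order parameter and mean weight per amplitude.
#' The expected shape: ineffective at low amplitude (the system stays
#' synchronized), an effective desynchronizing window, and a breakdown
#' at very large amplitudes where the contacts lose spatial specificity
#' and the whole nucleus is driven in phase.
#'
#' @param kappas amplitude grid (model mA; 0 means no stimulation).
#' @param n neurons per nucleus.
#' @param seed master seed (network realization and engine seeds).
#' @param electrode electrode specification (default centred, 4
#'   contacts along y).
#' @inheritParams cr_experiment
#' @return A list with `summary` (data.frame: `kappa`, `r1_bar`,
#'   `sigma_r1`, `mean_w`, `R_stn`, `attractor`) and a `manifest`.
#' @export
run_amplitude_scan <- function(kappas, n = 200, t_pre = 5000, t_stim = 25000,
                               t_post = 10000, avg_window = 5000,
                               lam_mult = 1, gain = 1, seed = 1,
                               electrode = electrode_spec(), config = NULL) {
  net <- build_network(network_config(n_stn = n, n_gpe = n, w_ss0 = 18e-3),
                       electrode = electrode, seed = seed)
  rows <- lapply(kappas, function(k) {
    ex <- cr_experiment(net, k, t_pre, t_stim, t_post, avg_window,
                        lam_mult, gain, seed = seed, config = config)
    data.frame(kappa = k, r1_bar = ex$r1_bar, sigma_r1 = ex$sigma_r1,
               mean_w = ex$mean_w, R_stn = ex$R_stn,
               attractor = classify_attractor(ex$mean_w, ex$R_stn,
                                              net$config$w_max))
  })
  list(summary = do.call(rbind, rows),
       manifest = list(kappas = kappas, n = n, t_pre = t_pre,
                       t_stim = t_stim, t_post = t_post,
                       lam_mult = lam_mult, gain = gain, seed = seed))
}

#' Electrode displacement scan
#'
#' Moves the electrode (and its canal: neuron placement is regenerated
#' per position) out of the STN centre along a coordinate axis and
#' reports the post-stimulation local order parameter per displacement.
#' Desynchronization degrades monotonically with displacement, with a
#' weaker slope along the electrode axis (y) than across it.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param displacements displacement magnitudes from the centre (mm).
#' @param kappa fixed stimulation amplitude (model mA).
#' @inheritParams run_amplitude_scan
#' @return A list with `summary` (data.frame: `axis`, `D`, `r1_bar`,
#'   `sigma_r1`, `mean_w`) and a `manifest`.
#' @export
run_displacement_scan <- function(axis = c("x", "y", "z"),
                                  displacements = c(0, 1, 2), kappa,
                                  n = 200, t_pre = 5000, t_stim = 25000,
                                  t_post = 10000, avg_window = 5000,
                                  lam_mult = 1, gain = 1, seed = 1,
                                  config = NULL) {
  axis <- match.arg(axis)
  u <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  rows <- lapply(displacements, function(D) {
    el <- electrode_spec(axis_origin = D * u)
    net <- build_network(network_config(n_stn = n, n_gpe = n, w_ss0 = 18e-3),
                         electrode = el, seed = seed)
    ex <- cr_experiment(net, kappa, t_pre, t_stim, t_post, avg_window,
                        lam_mult, gain, seed = seed, config = config)
    data.frame(axis = axis, D = D, r1_bar = ex$r1_bar,
               sigma_r1 = ex$sigma_r1, mean_w = ex$mean_w)
  })
  list(summary = do.call(rbind, rows),
       manifest = list(axis = axis, displacements = displacements,
                       kappa = kappa, n = n, lam_mult = lam_mult,
                       gain = gain, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
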