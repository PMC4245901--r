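# Independent oracles used across the suite. These deliberately avoid
# the package's optimized code paths: brute-force pair summation for
# STDP, direct kernel convolution for alpha synapses, and closed-form
# constructions for synchrony measures.

# Brute-force additive STDP: apply the pair rule event-by-event over
# sorted pre-delivery and post-spike times (all-to-all pairing with all
# PAST opposite events at each event; exact coincidences depress once,
# on the pre-arrival event), clipping after every event.
stdp_brute_force <- function(pre_t, post_t, w0, rule = stdp_rule()) {
  ev <- rbind(data.frame(t = pre_t, kind = "pre"),
              data.frame(t = post_t, kind = "post"))
  ev <- ev[order(ev$t, ev$kind != "post"), ]  # post first at equal times
  w <- w0
  for (k in seq_len(nrow(ev))) {
    if (ev$kind[k] == "pre") {
      past_post <- post_t[post_t <= ev$t[k]]
      dw <- sum(-rule$lam * rule$beta *
                  exp(-(ev$t[k] - past_post) / rule$tau_minus))
    } else {
      past_pre <- pre_t[pre_t < ev$t[k]]
      dw <- sum(rule$lam * exp(-(ev$t[k] - past_pre) / rule$tau_plus))
    }
    if (length(dw) && dw != 0) w <- min(max(w + dw, 0), rule$w_max)
  }
  w
}

# Trace-based additive STDP (the formulation the engine uses): two
# exponential traces, decayed between events, bumped at events.
stdp_trace_run <- function(pre_t, post_t, w0, rule = stdp_rule()) {
  ev <- rbind(data.frame(t = pre_t, kind = "pre"),
              data.frame(t = post_t, kind = "post"))
  ev <- ev[order(ev$t, ev$kind != "post"), ]
  w <- w0
  x_pre <- 0; x_post <- 0; t_last <- 0
  for (k in seq_len(nrow(ev))) {
    t <- ev$t[k]
    x_pre <- x_pre * exp(-(t - t_last) / rule$tau_plus)
    x_post <- x_post * exp(-(t - t_last) / rule$tau_minus)
    t_last <- t
    if (ev$kind[k] == "post") {
      x_post <- x_post + 1
      w <- min(max(w + rule$lam * x_pre, 0), rule$w_max)
    } else {
      w <- min(max(w - rule$lam * rule$beta * x_post, 0), rule$w_max)
      x_pre <- x_pre + 1
    }
  }
  w
}

# Direct convolution of a spike train with the unit-area alpha kernel
# (oracle for the engine's auxiliary-ODE kernel formulation)
alpha_convolution <- function(t, spike_times, weights, tau) {
  vapply(t, function(tt) {
    s <- tt - spike_times
    keep <- s >= 0
    sum(weights[keep] * s[keep] / tau^2 * exp(-s[keep] / tau))
  }, numeric(1))
}

# Auxiliary-ODE kernel formulation evaluated by exact per-event
# propagation (the engine's scheme, reimplemented independently of C++)
alpha_kernel_ode <- function(t, spike_times, weights, tau) {
  ord <- order(spike_times)
  spike_times <- spike_times[ord]; weights <- weights[ord]
  vapply(t, function(tt) {
    z <- 0; a <- 0; tl <- 0
    for (k in seq_along(spike_times)) {
      if (spike_times[k] > tt) break
      dt <- spike_times[k] - tl
      E <- exp(-dt / tau)
      a <- E * (a + z * dt / tau)
      z <- z * E + weights[k]
      tl <- spike_times[k]
    }
    dt <- tt - tl
    E <- exp(-dt / tau)
    (E * (a + z * dt / tau)) / tau
  }, numeric(1))
}

# two-neuron ss-only network scaffold for causality/delivery tests
tiny_two_neuron_net <- function(w, seed = 1) {
  cfg <- network_config(n_stn = 2, n_gpe = 2, w_ss0 = 0, sigma_ss = 0,
                        w_gg = 0, sigma_gg = 0, w_sg = 0, sigma_sg = 0,
                        w_gs = 0, sigma_gs = 0, het_sd = 0,
                        syn_gain_ref = NULL)
  net <- build_network(cfg, seed = seed)
  net$edges$ss <- data.frame(pre = 1L, post = 2L, weight = w, delay = 4.0)
  net
}
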