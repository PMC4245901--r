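# stngpe

A scale-configurable simulator of the subthalamic nucleus (STN) – globus
pallidus externus (GPe) loop for studying how coordinated-reset (CR) deep
brain stimulation unlearns pathological synchrony.

Parkinsonian motor symptoms are associated with abnormally synchronized
firing in the STN–GPe circuit. CR stimulation delivers brief pulse bursts
through the contacts of a depth electrode in a shuffled sequence, aiming to
decorrelate sub-populations so that spike-timing-dependent plasticity
(STDP) unlearns the strong recurrent coupling that sustains the synchrony —
a therapy that *reshapes connectivity* rather than suppressing activity.
`stngpe` implements the full model chain needed to study this in silico:

* **Neurons** — single-compartment conductance-based (Terman–Rubin) STN and
  GPe cells: `c_m dv/dt = −I_L − I_K − I_Na − I_T − I_Ca − I_ahp − I_syn +
  I_stim + I_noise`, with first-order gating kinetics and calcium-gated
  after-hyperpolarization; parameters heterogenized at 5% SD.
* **Space** — ellipsoidal nuclei (STN 2.5 × 6 × 3 mm, 188.5 mm³) filled
  with uniformly placed point neurons; a 4-contact electrode along the
  y-axis whose implantation canal excludes neuron positions.
* **Network** — four synapse classes (`ss`, `sg`, `gs`, `gg`) with
  exponentially distance-dependent intra-nucleus wiring
  (`p(x) = exp(−x/c_d)`), uniform inter-nucleus wiring, alpha-function
  postsynaptic currents, 4 ms delays, per-neuron Poisson noise drive.
* **Plasticity** — additive asymmetric STDP on STN→STN synapses
  (`Δw = λ e^{−|Δt|/τ₊}` for causal pairs, `−λβ e^{−|Δt|/τ₋}` otherwise)
  with hard bounds `[0, 20·10⁻³]`, which makes the network bistable between
  a synchronized ("parkinsonian") and a desynchronized ("healthy")
  attractor.
* **Stimulation** — charge-balanced biphasic pulses, a line-charge electrode
  field `S(d) = 1/(d·l_c·sqrt(1+4(d/l_c)²))`, and the randomized 3-ON/2-OFF
  CR schedule.
* **Analysis** — Kuramoto order parameter `R(t)` on linearly interpolated
  spike phases, a voxelized local order parameter `r̄₁ ± σ_r₁`, and pooled
  interspike-interval statistics.
* **Engine** — an adaptive Runge–Kutta–Fehlberg 4(5) core (Rcpp) with exact
  analytic kernel dynamics and a 0.1 ms event grid; deterministic under a
  seed.

## Worked example

A reduced network (400 neurons per nucleus, full-scale wiring fractions and
a synaptic-input-preserving down-scaling gain) started in the two coupling
regimes:

```r
library(stngpe)

net <- build_network(network_config(n_stn = 400, n_gpe = 400, w_ss0 = 18e-3),
                     seed = 1)
run <- run_network(net, duration = 15000, engine_config(seed = 2), stdp = TRUE)

r <- run$raster                                   # (id, time) spike events
stn <- r[r$id <= 400 & r$time > 5000, ]
isi_stats(stn)$median                             # pooled STN median ISI (ms)
#> [1] 46.1
mean(order_parameter_trace(stn, seq(5000, 15000, 1), 1:400), na.rm = TRUE)
#> [1] 0.789
tail(run$rec$mean_w_ss, 1)                        # mean plastic weight
#> [1] 0.00828
```

Started at strong coupling (`w_ss0 = 18e-3`) the run settles into a
synchronized state: STN phase coherence near 0.8 with a fast collective
rhythm (pooled median interspike interval 46 ms), and the mean plastic
weight holds at 8.3e-3 — far above the weak-coupling attractor. The same
network started at `w_ss0 = 2e-3` relaxes to uncorrelated firing (the same
calls print R = 0.070 and a mean weight decaying through 1.5e-3 toward
zero). Run `run_bistability(c(2e-3, 18e-3))` to see both mean-weight
trajectories side by side. `run_spontaneous()`,
`run_amplitude_scan()` and `run_displacement_scan()` wrap the full
experiment protocols, including CR stimulation with post-stimulation
washout; `inst/cli/stngpe.R` exposes them as shell subcommands.

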