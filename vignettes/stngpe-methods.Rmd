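---
title: "Model and methods: a spatially embedded STN-GPe network with STDP and coordinated-reset stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stngpe` simulates the reciprocally coupled subthalamic nucleus (STN) and
globus pallidus externus (GPe) as a spatial network of single-compartment
conductance-based neurons, with spike-timing-dependent plasticity (STDP) on
the recurrent STN connections and electrical coordinated-reset (CR)
stimulation delivered through a multi-contact depth electrode. This vignette
is the package's own account of the model, its numerical treatment, and the
design decisions behind both.

## Single-cell model

Both cell types follow the Terman-Rubin single-compartment formulation. The
membrane potential obeys

$$c_m \frac{dv}{dt} = -I_L - I_K - I_{Na} - I_T - I_{Ca} - I_{ahp}
  - I_{syn} + I_{stim} + I_{noise},$$

with a leak current, spike-generating potassium and sodium currents
($I_K = g_K n^4 (v - v_K)$, $I_{Na} = g_{Na} m_\infty^3(v)\,h\,(v - v_{Na})$),
a low-threshold T-type calcium current ($I_T$), a high-threshold calcium
current ($I_{Ca}$), and a calcium-gated after-hyperpolarization potassium
current $I_{ahp} = g_{ahp}(v - v_K)\,[Ca]/([Ca] + k_1)$. Intracellular
calcium integrates the calcium influx,
$d[Ca]/dt = \Gamma(-I_{Ca} - I_T - k_{Ca}[Ca])$. The two cell kinds differ in
parameter values and in the form of $I_T$: the STN current inactivates
through $b_\infty^2(r)$ while the GPe current uses the slow variable $r$
directly. The STN cell is a slow tonic pacemaker with strong rebound
excitability (post-inhibitory bursts through $I_T$); the GPe cell fires
tonically near 30 Hz in isolation and bursts when driven.

Three choices deserve comment.

* **Gating kinetics.** The kinetic tables list, per gate, a half-activation
  voltage and slope for $X_\infty(v) = 1/(1 + e^{-(v-\theta_X)/\sigma_X})$,
  and a baseline/amplitude/half-voltage/slope quadruple for
  $\tau_X(v) = \tau^0_X + \tau^1_X/(1 + e^{-(v-\theta^\tau_X)/\sigma^\tau_X})$,
  with rate scale $\phi_X$ in
  $dX/dt = \phi_X\,(X_\infty(v) - X)/\tau_X(v)$. Slopes for the STN
  activation gates use the canonical Terman-Rubin values
  ($\sigma_m = 15$, $\sigma_h = -3.1$, $\sigma_n = 8$, $\sigma_r = -2$,
  $\sigma_a = 7.8$, $\sigma_b = 0.1$ in the package's sigmoid convention);
  see `stn_params()`/`gpe_params()` for the full tables, every entry of
  which can be overridden.
* **The calcium rate constant** $\Gamma$ is stated per second and converted
  to the millisecond time base of the integrator ($\times 10^{-3}$), which
  recovers the canonical Terman-Rubin calcium kinetics; $[Ca]$ is treated as
  a dimensionless concentration-like variable.
* **Heterogeneity.** Maximal conductances and reversal potentials are drawn
  per neuron from Gaussians with SD equal to 5% of the mean (conductances
  truncated at zero); kinetic constants are shared. This makes the
  population non-identical without changing its mean behaviour.

## Geometry and connectivity

Each nucleus is an ellipsoid filled with uniformly distributed point
neurons: STN semi-axes $(2.5, 6.0, 3.0)$ mm (volume $188.5$ mm$^3$), GPe
$(4.6, 12.3, 3.2)$ mm. Only the STN geometry matters for stimulation; both
ellipsoids share a frame centred on the STN, with a configurable offset. The
electrode axis is the $y$-axis, four point contacts 2 mm apart centred in
the volume; neuron placement excludes the 0.7 mm-radius electrode canal,
which also enforces the minimal neuron-contact distance $d_{min} = 0.7$ mm.
When the electrode is displaced, the canal (and hence the placement) moves
with it.

Connectivity is built per class:

* **ss** (STN to STN, excitatory, plastic): each neuron contacts 7% of its
  population, targets drawn without replacement with probability
  $\propto e^{-d/c_d}$, $c_d = 0.5$ mm (connection probability 33% at the
  mean dendritic range 0.543 mm). Reading "7% of the population" as a fixed
  out-degree with distance-biased sampling reconciles the stated per-neuron
  synapse count with the stated probability profile.
* **gg** (GPe to GPe, inhibitory): 1% out-degree, $c_d = 0.63$ mm.
* **sg / gs** (between nuclei): fixed 2% out-degree, uniform targets, no
  distance dependence (long axonal projections).

All four classes share a 4.0 ms transmission delay. Initial weights are
Gaussian per class (ss: mean $w_{ss}(0)$, SD $0.1\times10^{-3}$; gg:
$0.25\times10^{-3}$; sg: $6\times10^{-3}$; gs: $3\times10^{-3}$), clipped to
their admissible ranges.

## Synapses, noise, and the kernel amplitude convention

Every delivered spike triggers an alpha-function postsynaptic kernel
$\alpha(t) = (t/\tau_{syn}^2)e^{-t/\tau_{syn}}$ (unit area, peak at
$t = \tau_{syn}$), and the total synaptic current is
$I_{syn} = \sum_j W_{ij}(v_i - v_{syn})\alpha_j$ with class reversal
potentials $v_{ss} = v_{sg} = 0$, $v_{gg} = -80$, $v_{gs} = -100$ mV and
time constants $\tau_{ss} = \tau_{sg} = 1.0$, $\tau_{gs} = \tau_{gg} = 3.3$
ms. External drive is a unique 20 Hz (STN) / 40 Hz (GPe) Poisson train per
neuron on an excitatory $\tau = 1$ ms kernel with weight 0.2, plus a
constant $-7$ pA applied current to every GPe cell (striatal inhibition).

The engine's default kernel amplitude convention is **peak-normalized**
(`kernel_norm = "peak"`): a unit weight produces a unit-amplitude kernel at
its peak, i.e. the unit-area kernel scaled by $e\,\tau_{syn}$. This is the
convention of the major spiking-network simulation platforms, and it is the
only reading of the drive parameters under which the GPe population is
viable: with literal unit-area kernels, the Poisson drive is too weak to
balance the constant $-7$ pA applied current against the small GPe leak
conductance, and the population sits tens of millivolts below its working
range, nearly silent, instead of in the reported desynchronized state.
The unit-area convention remains available (`kernel_norm = "area"`), and
all closed-form kernel functions (`alpha_psc()`) are stated in unit-area
form.

## Plasticity

Only ss synapses are plastic, under the additive asymmetric pair rule

$$\Delta w(\Delta t) = \begin{cases}
 \lambda e^{-|\Delta t|/\tau_+} & \Delta t > 0\\
 -\lambda\beta e^{-|\Delta t|/\tau_-} & \Delta t \le 0
\end{cases}$$

with $\tau_+ = 12$ ms, $\tau_- = 27.5$ ms, $\lambda = 2\times10^{-3}$,
$\beta = 1.1$, and hard bounds $w \in [0, 20\times10^{-3}]$. The
depression/potentiation area ratio $\beta\tau_-/\tau_+ \approx 2.52$ makes
the rule net-depressing for uncorrelated spiking; causally ordered
(pre-then-post) firing potentiates. The implementation is the standard
all-to-all trace formulation (two exponential traces per neuron, updated at
events), with exact coincidences assigned to the depression branch and
never double-counted.

The pairing times use the **dendritic-delay convention** of the major
simulation platforms: the transmission delay is attributed to the dendrite,
so the pre spike acts at the synapse at its emission time while the somatic
post spike back-propagates and reaches the synapse one full delay later —
$\Delta t = (t_{post} + d) - t_{pre}$. This choice is load-bearing for the
network's bistability: synchronous volleys then pair at $+4$ ms, inside the
potentiation window, so tight synchrony reinforces the strong coupling that
sustains it, while uncorrelated firing still nets depression. Under the
alternative axonal reading ($\Delta t = t_{post} - t_{pre} - d$) synchronous
volleys pair at $-4$ ms and the synchronized attractor cannot exist at any
scale — the rule would erode exactly the correlations that define the
state. A nearest-neighbour pairing variant was considered and not
implemented: the additive all-to-all rule with hard bounds is the object of
study, and the trace form is exactly its sum.

## Stimulation

Stimulation pulses are charge-balanced biphasic rectangles: cathodal
amplitude $\kappa$ for $\omega = 200\ \mu$s, then $-\kappa/8$ for
$8\omega$ (zero net charge per pulse). The spatial attenuation follows the
radial field of a finite line charge of contact length $l_c = 1.5$ mm,
$S(d) = 1/(d\,l_c\sqrt{1 + 4(d/l_c)^2})$, evaluated at the (floored)
neuron-contact distance; $\kappa S(d)$ enters the membrane equation through
a configurable conversion gain (default 1 in model units — absolute
amplitude values are meaningful only relative to this field model).

The CR schedule divides each 125 ms cycle into $M = 4$ slots; in an ON
cycle each contact bursts in exactly one slot (as many complete pulses at
$T_p = 7.69$ ms as fit: four), the slot order re-randomized each cycle under
the constraint that the closing contact of one cycle never opens the next.
Three ON cycles alternate with two silent OFF cycles. Pulse onsets are
snapped to the 0.1 ms event grid (a shift of at most 0.05 ms that preserves
exact charge balance). Only STN neurons receive stimulation, each from all
four contacts.

## Numerical integration

The engine uses a hybrid scheme:

* The five continuous states per neuron are advanced with an embedded
  Runge-Kutta-Fehlberg 4(5) method with per-neuron adaptive step size
  (tolerances $10^{-6}$ absolute and relative by default), inside a fixed
  0.1 ms event grid.
* Alpha-kernels are class-aggregated per neuron as two auxiliary linear
  states and advanced *analytically*, so kernel dynamics are exact and the
  per-neuron state stays small; within one grid interval neurons are
  mutually decoupled and integrate independently.
* All discrete events — spike detection, delayed delivery, STDP updates,
  Poisson noise arrivals, stimulation phase changes — live on the grid,
  making delays and plasticity timing exact to 0.1 ms.
* Spikes are detected as local maxima of the 0.1 ms-sampled potential above
  a threshold (default $-10$ mV: above subthreshold oscillations, below
  spike peaks; the exact value is uncritical and configurable), without
  distinguishing single spikes from intra-burst spikes.
* Gating variables are projected onto $[0,1]$ after each accepted step
  (cheap, and preserves the invariant under adaptive stepping).
* Gating sigmoids are evaluated through 0.02 mV-resolution lookup tables
  built from the definitional R functions (interpolation error
  $\sim 10^{-6}$); the single-neuron engine trajectory is validated against
  an independent `deSolve::lsoda` reference integration to within 1% in
  spike period (measured agreement is at the $10^{-5}$ level).
* Noise streams are per-neuron counter-seeded RNGs, so results are
  reproducible and independent of any execution layout.

## Analysis

Phases are assigned by linear interpolation between consecutive spikes
($\phi = 0$ at each spike, undefined outside the spike-bracketed support),
and synchrony is the Kuramoto order parameter
$R(t) = |n^{-1}\sum_j e^{i\phi_j(t)}|$ evaluated on a 1 ms grid; an
incoherent population of $n$ neurons has an $R$ baseline of $1/\sqrt{n}$.
The spatial structure of synchrony is summarized by tiling the STN volume
into cubic voxels (edge chosen so the mean occupancy is ~42 neurons at the
configured population, voxels with fewer than 10 neurons discarded),
time-averaging $R_k$ per voxel, and reporting
$\bar r_1 = N_V^{-1}\sum_k \langle R_k\rangle$ with its across-voxel SD
$\sigma_{r_1}$: $\bar r_1$ is high whenever the volume is synchronized
voxel-wise — even with phase shifts between voxels — and $\sigma_{r_1}$
flags spatially inhomogeneous (core/shell) outcomes. Firing statistics are
pooled interspike-interval histograms (5 ms bins) with median, mean
absolute deviation from the median (MD), and median rate — medians because
the distributions are asymmetric (GPe cells burst). Recorded traces are
smoothed with a centred 1000 ms moving average where long-term trends are
of interest.

## Scale reduction

The full-scale system ($10^4$ neurons per nucleus, $1.2\times10^7$
synapses, minutes of biological time) is a configuration choice, not a
default. The package's reduced-scale contract is:

* **Connectivity fractions** (7% / 1% / 2%) are preserved, so out-degrees
  shrink with the population.
* **Per-neuron mean synaptic input is preserved** by a per-class current
  gain $N_{ref}/N_{source}$ ($N_{ref} = 10^4$) applied at injection time.
  Weights, STDP bounds, and reported mean weights therefore keep their
  full-scale meaning at any scale. What this gain cannot preserve is the
  *variance* of the input: with 20-fold fewer, 20-fold stronger synapses,
  synaptic fluctuations are amplified, which biases reduced-scale firing
  rates upward and loosens spike-time alignment relative to full scale.
  Reduced-scale runs reproduce regime structure and qualitative transitions;
  absolute rates, order-parameter plateaus and stimulation amplitude values
  carry finite-size biases that shrink as $N$ grows.
* **Protocol compression.** The plain STDP learning rate makes attractor
  transitions take hundreds of seconds. The scenario runners accept a
  learning-rate multiplier `lam_mult` (recorded in every manifest), but its
  default is 1 and multipliers above ~2 are not usable for attractor
  studies: a single spike pair then moves a weight across a large fraction
  of its admissible range, the weight dynamics become a coarse bounded
  random walk, and the coexistence of the two attractors is destroyed (the
  weak-coupling state drifts up to an intermediate synchronized state at
  any population size we examined). Protocols are therefore compressed by
  shortening epochs at the plain learning rate, accepting that slow
  transitions are then only partially traversed.

Problem sizes used by the package's own test suite and acceptance script
(chosen as sizes a laptop handles in minutes): spontaneous-state runs use
500 neurons per nucleus and 30-35 s of biological time; bistability uses
400 per nucleus, and CR protocol runs 350-500 per nucleus with stimulation
epochs of 8-15 s — the smallest sizes at which the weak-coupling attractor
is stable. The synthetic networks emulate the spatial geometry,
wiring statistics, heterogeneity and drive of the full-scale system; they
do not emulate its input variance (see above) or any feature absent from
the model itself (axonal stimulation effects, multi-compartment morphology,
inhomogeneous tissue conductivity), so passing tests certify the
implementation and its scaling contract, not clinical parameter values.

## Known limitations

* Absolute firing rates and the collective oscillation period are sensitive
  to drive conventions (kernel amplitude normalization, noise-generator
  semantics, current units) that published parameter tables underdetermine;
  the package fixes one coherent set of conventions (documented above) and
  treats regime structure, attractors and transitions as the primary
  reproducibles.
* Stimulation amplitudes are in model units; mapping to milliamperes is
  meaningful only relative to the line-charge field approximation and the
  unit conversion gain.
* The soma-only injection omits axonal and antidromic activation.
* Hard STDP bounds only; soft-bound variants change the attractor
  structure and are out of scope.
* The GPe ellipsoid position relative to the STN is configurable but
  defaults to a shared centre; only STN geometry affects stimulation.
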