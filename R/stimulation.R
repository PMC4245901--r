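# Charge-balanced biphasic pulses, the line-charge electrode field
# profile, and the randomized coordinated-reset (CR) schedule with
# ON/OFF cycling, combined into per-neuron stimulation currents.

#' Charge-balanced biphasic pulse specification
#'
#' A stimulation pulse has a cathodal phase of amplitude `kappa` and
#' width `omega`, immediately followed by a charge-balancing anodal
#' phase of amplitude `-kappa/p_s` and width `p_s * omega`, so the net
#' charge of every pulse is exactly zero. `T_p` is the pulse period
#' within a burst.
#'
#' @param kappa cathodal amplitude (mA; negative by convention).
#' @param omega cathodal width (ms, default 0.2 = 200 us).
#' @param p_s balance ratio (default 8): anodal phase is `p_s` times
#'   longer and `p_s` times weaker than the cathodal phase.
#' @param T_p intra-burst pulse period (ms, default 7.69). Must exceed
#'   the total pulse duration `omega * (1 + p_s)`.
#' @return A list of class `"pulse_spec"`.
#' @export
pulse_spec <- function(kappa = -3.3, omega = 0.2, p_s = 8, T_p = 7.69) {
  stopifnot(omega > 0, p_s > 0)
  if (omega * (1 + p_s) >= T_p) stop("total pulse duration must be shorter than T_p")
  structure(list(kappa = kappa, omega = omega, p_s = p_s, T_p = T_p),
            class = "pulse_spec")
}

#' Biphasic pulse train waveform
#'
#' Piecewise-constant current: `kappa` on `[t_k, t_k + omega)`,
#' `-kappa/p_s` on `[t_k + omega, t_k + omega(1+p_s))`, zero elsewhere.
#' The time integral over any whole pulse vanishes (charge balance).
#'
#' @param t evaluation time(s) (ms); vectorized.
#' @param spec a [pulse_spec()].
#' @param onsets sorted pulse onset times (ms), spaced at least one full
#'   pulse duration apart (overlap is an error).
#' @return Current amplitude(s) at `t`.
#' @export
pulse_waveform <- function(t, spec, onsets) {
  dur <- spec$omega * (1 + spec$p_s)
  if (length(onsets) > 1) {
    if (is.unsorted(onsets)) stop("pulse onsets must be sorted")
    if (any(diff(onsets) < dur)) stop("overlapping pulses")
  }
  out <- numeric(length(t))
  if (length(onsets) == 0) return(out)
  k <- findInterval(t, onsets)
  hit <- k >= 1
  s <- t[hit] - onsets[k[hit]]
  amp <- numeric(sum(hit))
  amp[s >= 0 & s < spec$omega] <- spec$kappa
  amp[s >= spec$omega & s < dur] <- -spec$kappa / spec$p_s
  out[hit] <- amp
  out
}

#' Line-charge electrode field profile
#'
#' Spatial attenuation of the stimulation strength with distance from a
#' cylindrical contact, approximated by the radial field of a finite
#' line charge of length `l_c`:
#' \deqn{S(d) = \frac{1}{d\, l_c \sqrt{1 + 4 (d/l_c)^2}}}
#' Strictly decreasing in `d`; behaves as \eqn{1/(2 d^2)} far from the
#' contact. The singularity at `d = 0` is excluded by the minimal
#' neuron-electrode distance, which must be floored upstream (see
#' [distance_to_contact()]).
#'
#' @param d distance(s) to the contact (mm), `>= d_min`.
#' @param l_c contact length (mm, default 1.5).
#' @param d_min minimal admissible distance (mm, default 0.7); smaller
#'   distances signal a missing upstream floor.
#' @return Attenuation value(s) (1/mm^2).
#' @export
field_profile <- function(d, l_c = 1.5, d_min = 0.7) {
  if (any(d < d_min)) stop("distance below d_min; apply the floor upstream")
  1 / (d * l_c * sqrt(1 + 4 * (d / l_c)^2))
}

#' Coordinated-reset stimulation schedule
#'
#' One CR cycle of period `T` splits into `M` equal slots; in an ON
#' cycle every contact bursts in exactly one slot, in an order
#' re-randomized every cycle under the constraint that the contact
#' closing one cycle never opens the next. `on_cycles` ON cycles
#' alternate with `off_cycles` silent OFF cycles (the 3 ON / 2 OFF
#' pattern maximizes the desynchronization attained during the pauses).
#'
#' @param T_cycle CR cycle period (ms, default 125), roughly matching
#'   the period of the targeted pathological rhythm.
#' @param M number of contacts/sub-populations (default 4).
#' @param on_cycles,off_cycles counts of stimulation and silent cycles
#'   per pattern (defaults 3 and 2).
#' @param seed integer seed for the per-cycle permutations.
#' @return A list of class `"cr_schedule"`.
#' @export
cr_schedule <- function(T_cycle = 125.0, M = 4, on_cycles = 3, off_cycles = 2,
                        seed = 1L) {
  stopifnot(T_cycle > 0, M >= 1, on_cycles >= 1, off_cycles >= 0)
  structure(list(T_cycle = T_cycle, M = M, on_cycles = on_cycles,
                 off_cycles = off_cycles, seed = seed),
            class = "cr_schedule")
}

#' Generate the CR pulse-onset sequence
#'
#' Expands a schedule into per-contact pulse onset times over a horizon.
#' Within an ON cycle starting at `t_c`, the contact assigned to slot
#' `m` (0-based) delivers a burst of pulses starting at
#' `t_c + m T / M`, with intra-burst period `T_p`; as many complete
#' pulses are placed as fit in the slot (4 under default parameters).
#' OFF cycles contribute nothing. Deterministic under the schedule seed.
#'
#' @param schedule a [cr_schedule()].
#' @param horizon duration to cover (ms), positive.
#' @param pulse a [pulse_spec()] (supplies `T_p` and the pulse width).
#' @param t_start time of the first cycle (ms, default 0).
#' @return A data.frame with columns `onset` (ms, sorted), `contact`
#'   (1..M), `cycle` (1-based index of the ON cycle).
#' @export
cr_sequence <- function(schedule, horizon, pulse = pulse_spec(), t_start = 0) {
  stopifnot(horizon > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(schedule$seed)
  M <- schedule$M
  slot_len <- schedule$T_cycle / M
  dur <- pulse$omega * (1 + pulse$p_s)
  n_pulse <- max(floor((slot_len - dur) / pulse$T_p) + 1, 0)
  pattern_len <- schedule$on_cycles + schedule$off_cycles
  n_cycles <- ceiling((horizon - t_start) / schedule$T_cycle)
  prev_last <- 0L
  rows <- vector("list", n_cycles)
  cyc_id <- 0L
  for (c in seq_len(n_cycles) - 1L) {
    if (c %% pattern_len >= schedule$on_cycles) next  # OFF cycle
    perm <- sample.int(M)
    while (M > 1 && perm[1] == prev_last) perm <- sample.int(M)
    prev_last <- perm[M]
    cyc_id <- cyc_id + 1L
    t_c <- t_start + c * schedule$T_cycle
    onsets <- rep(t_c + (seq_len(M) - 1) * slot_len, each = n_pulse) +
      rep((seq_len(n_pulse) - 1) * pulse$T_p, times = M)
    rows[[c + 1L]] <- data.frame(onset = onsets,
                                 contact = rep(perm, each = n_pulse),
                                 cycle = cyc_id)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(onset = numeric(0), contact = integer(0),
                                      cycle = integer(0)))
  out <- out[out$onset < t_start + horizon, , drop = FALSE]
  out[order(out$onset), , drop = FALSE]
}

#' Per-neuron stimulation current at a time point
#'
#' Reference composition of pulse train, indicator and field profile:
#' \deqn{I_{stim,i}(t) = \sum_{j=1}^{M} S(d_{ij})\,\rho_j(t)\,P(t)}
#' where \eqn{\rho_j} selects the pulses delivered through contact `j`.
#' Every STN neuron receives input from all `M` contacts, attenuated by
#' its distance to each. (GPe neurons are never stimulated.)
#'
#' @param xyz n x 3 matrix of STN neuron positions (mm).
#' @param t evaluation time (ms), scalar.
#' @param sequence a [cr_sequence()] onset table.
#' @param pulse a [pulse_spec()].
#' @param electrode an [electrode_spec()].
#' @param gain unit-bridging conversion gain from `kappa * S(d)`
#'   (mA/mm^2) to the membrane equation's current density (default 1 in
#'   model units).
#' @return Numeric vector of per-neuron stimulation currents at `t`.
#' @export
stim_current <- function(xyz, t, sequence, pulse, electrode, gain = 1.0) {
  xyz <- matrix(xyz, ncol = 3)
  out <- numeric(nrow(xyz))
  for (j in seq_len(electrode$n_contacts)) {
    ons <- sequence$onset[sequence$contact == j]
    if (length(ons) == 0) next
    p <- pulse_waveform(t, pulse, ons)
    if (p != 0) {
      d <- distance_to_contact(xyz, electrode, j)
      out <- out + field_profile(d, electrode$contact_length, electrode$d_min) * p
    }
  }
  gain * out
}
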