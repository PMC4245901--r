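# Synchrony and firing observables: spike detection on sampled traces,
# linearly interpolated spike phases, global and voxelized Kuramoto
# order parameters, moving averages, and interspike-interval statistics.

#' Detect spikes on a sampled membrane-potential trace
#'
#' Combined threshold and local-maximum search: every local maximum of
#' the sampled trace above the threshold counts as one spike (single
#' spikes and intra-burst spikes are not distinguished). Maxima closer
#' together than `min_gap` are merged into the larger one, which floors
#' the per-neuron inter-event gap at the detection resolution.
#'
#' @param v sampled membrane potential (mV).
#' @param dt sampling interval (ms).
#' @param threshold detection threshold (mV, default -10).
#' @param min_gap minimal separation between detected spikes (ms,
#'   default 0.1).
#' @param t0 time of the first sample (ms).
#' @return Sorted spike times (ms).
#' @export
detect_spikes <- function(v, dt, threshold = -10, min_gap = 0.1, t0 = 0) {
  n <- length(v)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  is_max <- v[i] > threshold & v[i] >= v[i - 1] & v[i] > v[i + 1]
  idx <- i[is_max]
  if (length(idx) == 0) return(numeric(0))
  times <- t0 + (idx - 1) * dt
  keep <- logical(length(idx))
  last_t <- -Inf; last_k <- 0L
  for (k in seq_along(idx)) {
    if (times[k] - last_t >= min_gap) {
      keep[k] <- TRUE; last_t <- times[k]; last_k <- k
    } else if (v[idx[k]] > v[idx[last_k]]) {
      keep[last_k] <- FALSE; keep[k] <- TRUE; last_t <- times[k]; last_k <- k
    }
  }
  times[keep]
}

#' Kuramoto order parameter of a phase set
#'
#' \eqn{R = |n^{-1} \sum_j e^{i\phi_j}|}, the coherence of the phases:
#' 1 for full in-phase synchrony, of order \eqn{1/\sqrt{n}} for an
#' incoherent population (finite-size baseline, e.g. 0.01 for n = 1e4).
#'
#' @param phases numeric vector of phases (radians); `NA` entries
#'   (undefined phases) are dropped.
#' @return R in [0, 1], or `NA` if no phase is defined.
#' @export
order_parameter <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (length(phases) == 0) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Linearly interpolated spike phase of one neuron
#'
#' Between consecutive spikes at \eqn{t_k \le t < t_{k+1}} the phase
#' grows linearly from 0 to \eqn{2\pi}:
#' \eqn{\phi(t) = 2\pi (t - t_k)/(t_{k+1} - t_k)}. The phase is
#' undefined (NA) before the first and after the last spike.
#'
#' @param spike_times sorted spike times of the neuron (ms).
#' @param t evaluation time(s) (ms); vectorized.
#' @return Phase(s) in [0, 2*pi), `NA` outside the spike-bracketed
#'   support.
#' @export
spike_phase <- function(spike_times, t) {
  if (length(spike_times) < 2) return(rep(NA_real_, length(t)))
  k <- findInterval(t, spike_times)
  ok <- k >= 1 & k < length(spike_times) & t >= spike_times[1]
  phi <- rep(NA_real_, length(t))
  kk <- k[ok]
  phi[ok] <- 2 * pi * (t[ok] - spike_times[kk]) /
    (spike_times[kk + 1] - spike_times[kk])
  phi
}

#' Phase matrix of a population from a spike raster
#'
#' @param raster data.frame with columns `id`, `time` (ms).
#' @param times evaluation grid (ms).
#' @param ids neuron ids forming the population (rows of the result).
#' @return A `length(ids)` x `length(times)` matrix of phases (NA where
#'   undefined).
#' @export
phase_traces <- function(raster, times, ids) {
  spl <- split(raster$time, factor(raster$id, levels = ids))
  t(vapply(spl, function(st) spike_phase(sort(st), times), numeric(length(times))))
}

#' Order-parameter time course of a population
#'
#' Computes \eqn{R(t)} on an evaluation grid from a spike raster;
#' neurons with undefined phase at an instant are excluded from that
#' instant's average (the population count adjusts accordingly).
#'
#' @inheritParams phase_traces
#' @return Numeric vector `R(t)` over `times`.
#' @export
order_parameter_trace <- function(raster, times, ids) {
  ph <- phase_traces(raster, times, ids)
  z <- exp(1i * ph)
  z[is.na(ph)] <- NA
  R <- Mod(colMeans(z, na.rm = TRUE))
  R[colSums(!is.na(ph)) == 0] <- NA_real_
  R
}

#' Centered moving average
#'
#' Sliding mean over a window of fixed duration (default 1000 ms), used
#' to smooth short-term fluctuations of recorded observables. Edges use
#' the partial window; a constant input is returned unchanged.
#'
#' @param x sampled trace.
#' @param window window duration (ms, default 1000).
#' @param dt sampling interval of `x` (ms).
#' @return Smoothed trace, same length as `x`.
#' @export
moving_average <- function(x, window = 1000, dt = 1) {
  w <- max(1L, round(window / dt))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Voxelized local order parameter
#'
#' Subdivides the nucleus volume into equally sized cubic voxels and
#' time-averages the per-voxel order parameter \eqn{R_k(t)} over the
#' neurons contained in each voxel; only voxels holding at least
#' `min_neurons` neurons are considered (finite-size fluctuations make
#' smaller voxels uninformative). Summaries are
#' \eqn{\bar r_1 = N_V^{-1} \sum_k \langle R_k\rangle} and its standard
#' deviation \eqn{\sigma_{r_1}} across voxels: \eqn{\bar r_1} is high
#' when the volume is synchronized voxel-wise even if phase shifts exist
#' between voxels, and \eqn{\sigma_{r_1}} flags spatially inhomogeneous
#' (core/shell) outcomes.
#'
#' @param positions n x 3 matrix of neuron positions (mm).
#' @param raster spike raster (`id`, `time`) of the same population.
#' @param t_range time window `c(from, to)` (ms) over which to average.
#' @param voxel_edge cubic voxel edge length (mm). Default `NULL`
#'   targets a mean occupancy of ~42 neurons per voxel inside the
#'   nucleus volume, mirroring the full-scale configuration.
#' @param dt_phase phase evaluation grid step (ms, default 1).
#' @param min_neurons minimal voxel occupancy (default 10).
#' @param volume nucleus volume (mm^3) used for the default voxel edge
#'   (default: the STN ellipsoid volume).
#' @return A list with `voxels` (data.frame: voxel center coordinates,
#'   `n` neurons, `R_mean`), `r1_bar`, `sigma_r1`, `n_voxels`,
#'   `voxel_edge`.
#' @export
local_order <- function(positions, raster, t_range, voxel_edge = NULL,
                        dt_phase = 1.0, min_neurons = 10,
                        volume = ellipsoid_volume(stn_ellipsoid())) {
  stopifnot(length(t_range) == 2, t_range[2] > t_range[1])
  n <- nrow(positions)
  if (is.null(voxel_edge)) voxel_edge <- (volume * 42 / n)^(1 / 3)
  anchor <- apply(positions, 2, min)
  key <- floor(sweep(positions, 2, anchor) / voxel_edge)
  kid <- paste(key[, 1], key[, 2], key[, 3], sep = ":")
  times <- seq(t_range[1], t_range[2], by = dt_phase)
  ids <- seq_len(n)
  ph <- phase_traces(raster, times, ids)
  groups <- split(ids, kid)
  groups <- groups[vapply(groups, length, 1L) >= min_neurons]
  if (length(groups) == 0) stop("no voxel holds at least ", min_neurons, " neurons")
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    Rk <- apply(ph[idx, , drop = FALSE], 2, order_parameter)
    ctr <- anchor + (as.numeric(strsplit(g, ":")[[1]]) + 0.5) * voxel_edge
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3], n = length(idx),
               R_mean = mean(Rk, na.rm = TRUE))
  })
  vox <- do.call(rbind, rows)
  list(voxels = vox, r1_bar = mean(vox$R_mean), sigma_r1 = stats::sd(vox$R_mean),
       n_voxels = nrow(vox), voxel_edge = voxel_edge)
}

#' Pooled interspike-interval statistics
#'
#' Interspike intervals are computed per neuron and pooled over the
#' population; reported are the 5-ms-binned histogram, the median
#' interval \eqn{\tilde T}, the mean absolute deviation from the median
#' (MD), and the median firing rate \eqn{1000/\tilde T} Hz. Median and
#' MD are preferred over mean/SD because the distributions are
#' asymmetric (GPe cells burst).
#'
#' @param raster spike raster (`id`, `time` in ms).
#' @param bin histogram bin width (ms, default 5).
#' @return A list with `isi` (pooled intervals), `median`, `md`,
#'   `rate_hz`, `hist` (data.frame `mid`, `count`).
#' @export
isi_stats <- function(raster, bin = 5.0) {
  isi <- unlist(lapply(split(raster$time, raster$id), function(st) {
    if (length(st) >= 2) diff(sort(st)) else numeric(0)
  }), use.names = FALSE)
  if (length(isi) == 0) stop("no interspike interval available")
  med <- stats::median(isi)
  breaks <- seq(0, max(isi) + bin, by = bin)
  h <- graphics::hist(isi, breaks = breaks, plot = FALSE)
  list(isi = isi, median = med, md = mean(abs(isi - med)),
       rate_hz = 1000 / med,
       hist = data.frame(mid = h$mids, count = h$counts))
}
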