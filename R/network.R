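# Directed weighted connectivity of the two-nucleus network: the four
# synapse classes (ss, sg, gs, gg), distance-dependent intra-nucleus
# wiring with fixed out-degree, uniform inter-nucleus wiring, Gaussian
# initial weights, and homogeneous 4 ms transmission delays.

#' Synapse class table
#'
#' Reversal potentials, alpha-function time constants, transmission
#' delays and plasticity flags for the four network synapse classes and
#' the external noise synapse. Only STN-to-STN (`ss`) synapses are
#' plastic.
#'
#' @return A data.frame with columns `name`, `v_syn` (mV), `tau_syn`
#'   (ms), `delay` (ms), `sign`, `plastic`.
#' @export
synapse_classes <- function() {
  data.frame(
    name = c("ss", "sg", "gs", "gg", "noise"),
    v_syn = c(0, 0, -100, -80, 0),
    tau_syn = c(1.0, 1.0, 3.3, 3.3, 1.0),
    delay = c(4.0, 4.0, 4.0, 4.0, 0.0),
    sign = c("excitatory", "excitatory", "inhibitory", "inhibitory", "excitatory"),
    plastic = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Distance-dependent connection probability
#'
#' \eqn{p(x) = e^{-x/c_d}}, the exponential decline of intra-nucleus
#' connection probability with somatic distance, motivated by the
#' falling density of dendritic branches away from the soma. The decay
#' constants are calibrated so that \eqn{p(r_d) = 0.33} at the mean
#' dendritic range (STN: \eqn{r_d = 0.543} mm, \eqn{c_d = 0.5};
#' GPe: \eqn{r_d = 0.7} mm, \eqn{c_d = 0.63}).
#'
#' @param x distance (mm), non-negative; vectorized.
#' @param c_d decay constant (mm), positive.
#' @return Probability in (0, 1].
#' @export
distance_probability <- function(x, c_d) {
  stopifnot(all(x >= 0), c_d > 0)
  exp(-x / c_d)
}

# Weighted sampling of k distinct indices with probability proportional
# to w, via exponential keys (Efraimidis-Spirakis); O(n) per call.
.sample_weighted <- function(w, k) {
  keys <- stats::rexp(length(w)) / w
  kth <- sort.int(keys, partial = k)[k]
  idx <- which(keys <= kth)
  if (length(idx) > k) idx <- idx[order(keys[idx])][seq_len(k)]
  idx
}

#' Distance-biased intra-nucleus wiring
#'
#' Every source neuron extends exactly `out_degree` synapses to distinct
#' targets within its own nucleus (no self-connections), sampled without
#' replacement with probability proportional to
#' \eqn{e^{-d/c_d}} of the pairwise distance. The fixed out-degree
#' realizes the stated per-neuron synapse count while the sampling bias
#' realizes the stated distance profile.
#'
#' @param positions n x 3 matrix of neuron positions (mm).
#' @param out_degree synapses per source neuron; must be < n - 1.
#' @param c_d decay constant of [distance_probability()] (mm).
#' @param seed optional integer seed.
#' @return A two-column integer matrix `(pre, post)` with
#'   `n * out_degree` rows.
#' @export
connect_intranucleus <- function(positions, out_degree, c_d, seed = NULL) {
  n <- nrow(positions)
  if (out_degree >= n - 1) stop("out_degree must be smaller than the population size minus 1")
  if (out_degree == 0) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("pre", "post"))))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  post <- matrix(0L, nrow = out_degree, ncol = n)
  for (i in seq_len(n)) {
    d2 <- (positions[, 1] - positions[i, 1])^2 +
          (positions[, 2] - positions[i, 2])^2 +
          (positions[, 3] - positions[i, 3])^2
    w <- exp(-sqrt(d2) / c_d)
    w[i] <- 0  # no self-connections
    post[, i] <- .sample_weighted(w, out_degree)
  }
  cbind(pre = rep(seq_len(n), each = out_degree), post = as.integer(post))
}

#' Uniform inter-nucleus wiring
#'
#' Long-range axonal projections between the nuclei carry no distance
#' dependence: each source neuron contacts exactly `out_degree`
#' uniform-randomly chosen distinct targets in the other nucleus.
#'
#' @param n_src,n_dst source and destination population sizes.
#' @param out_degree synapses per source neuron; must be < `n_dst`.
#' @param seed optional integer seed.
#' @return A two-column integer matrix `(pre, post)`.
#' @export
connect_internucleus <- function(n_src, n_dst, out_degree, seed = NULL) {
  if (out_degree >= n_dst) stop("out_degree must be smaller than the destination size")
  if (out_degree == 0) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("pre", "post"))))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  post <- vapply(seq_len(n_src), function(i) sample.int(n_dst, out_degree),
                 integer(out_degree))
  cbind(pre = rep(seq_len(n_src), each = out_degree), post = as.integer(post))
}

#' Gaussian initial synaptic weights
#'
#' Weights are drawn i.i.d. Gaussian around the class mean and clipped
#' to the admissible range: `[0, w_max]` for plastic ss synapses (hard
#' STDP bounds), `[0, Inf)` otherwise.
#'
#' @param n number of weights.
#' @param mean,sd Gaussian parameters (`sd >= 0`).
#' @param w_max upper clip (default `Inf`).
#' @param seed optional integer seed.
#' @return Numeric vector of non-negative weights.
#' @export
draw_weights <- function(n, mean, sd, w_max = Inf, seed = NULL) {
  stopifnot(sd >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pmin(pmax(stats::rnorm(n, mean, sd), 0), w_max)
}

#' Network construction configuration
#'
#' Collects population sizes, connectivity fractions, distance-decay
#' constants and initial-weight statistics. Connectivity is specified as
#' FRACTIONS of the population so that reduced-scale networks keep the
#' full-scale wiring statistics; out-degrees are `round(fraction * N)`.
#'
#' The synaptic current of every network class is scaled by
#' `n_ref / N` of the receiving projection's source population
#' (`syn_gain_ref`), which preserves the summed synaptic input per
#' neuron under down-scaling while weights, STDP bounds and reported
#' mean weights keep their full-scale meaning.
#'
#' @param n_stn,n_gpe population sizes (full scale: 1e4 each).
#' @param p_ss,p_gg,p_inter connectivity fractions (0.07, 0.01, 0.02).
#' @param c_d_stn,c_d_gpe distance-decay constants (mm).
#' @param w_ss0 initial mean ss weight (weak <= 2e-3 desynchronized
#'   regime; 18e-3 strongly synchronized regime).
#' @param sigma_ss ss weight SD (0.1e-3).
#' @param w_gg,sigma_gg,w_sg,sigma_sg,w_gs,sigma_gs static class weight
#'   statistics.
#' @param w_max hard upper STDP bound for ss weights.
#' @param syn_gain_ref reference population size for the down-scaling
#'   current gain (1e4; gains are `syn_gain_ref / N_source`, 1 at full
#'   scale). Set `NULL` to disable compensation.
#' @param het_sd heterogeneity SD as fraction of parameter means.
#' @return A list of class `"network_config"`.
#' @export
network_config <- function(n_stn = 500, n_gpe = 500,
                           p_ss = 0.07, p_gg = 0.01, p_inter = 0.02,
                           c_d_stn = 0.5, c_d_gpe = 0.63,
                           w_ss0 = 18e-3, sigma_ss = 0.1e-3,
                           w_gg = 0.25e-3, sigma_gg = 0.125e-3,
                           w_sg = 6e-3, sigma_sg = 0.3e-3,
                           w_gs = 3e-3, sigma_gs = 0.15e-3,
                           w_max = 20e-3, syn_gain_ref = 1e4,
                           het_sd = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "network_config"
  cfg
}

#' Build the full spatial STN-GPe network
#'
#' Places neurons in the two ellipsoids (STN positions avoid the
#' electrode canal when an electrode is supplied), wires the four
#' synapse classes, draws initial weights and heterogenized cell
#' parameters. Everything is derived deterministically from the master
#' seed.
#'
#' @param config a [network_config()].
#' @param electrode optional [electrode_spec()]; its canal excludes STN
#'   positions and it is stored for stimulation experiments.
#' @param stn_shape,gpe_shape nucleus ellipsoids.
#' @param seed master integer seed.
#' @return A list of class `"stngpe_network"` with elements `positions`
#'   (list `stn`, `gpe` of n x 3 matrices), `edges` (list per class of
#'   data.frames `pre`, `post`, `weight`, `delay`), `cell_params`
#'   (heterogenized per-neuron tables plus the reference sets),
#'   `electrode`, `config`, `seed`.
#' @export
build_network <- function(config = network_config(), electrode = NULL,
                          stn_shape = stn_ellipsoid(), gpe_shape = gpe_ellipsoid(),
                          seed = 1L) {
  cfg <- config
  cls <- synapse_classes()
  sub <- function(k) (seed * 11L + k) %% 2147483647L
  pos_stn <- place_neurons(stn_shape, cfg$n_stn, exclusion = electrode, seed = sub(1L))
  pos_gpe <- place_neurons(gpe_shape, cfg$n_gpe, seed = sub(2L))

  k_ss <- round(cfg$p_ss * cfg$n_stn)
  k_gg <- round(cfg$p_gg * cfg$n_gpe)
  k_sg <- round(cfg$p_inter * cfg$n_gpe)
  k_gs <- round(cfg$p_inter * cfg$n_stn)

  e_ss <- connect_intranucleus(pos_stn, k_ss, cfg$c_d_stn, seed = sub(3L))
  e_gg <- connect_intranucleus(pos_gpe, k_gg, cfg$c_d_gpe, seed = sub(4L))
  e_sg <- connect_internucleus(cfg$n_stn, cfg$n_gpe, k_sg, seed = sub(5L))
  e_gs <- connect_internucleus(cfg$n_gpe, cfg$n_stn, k_gs, seed = sub(6L))

  mk <- function(e, name, mean, sd, w_max = Inf, sd_seed) {
    data.frame(pre = e[, "pre"], post = e[, "post"],
               weight = draw_weights(nrow(e), mean, sd, w_max, seed = sd_seed),
               delay = rep(cls$delay[cls$name == name], nrow(e)))
  }
  edges <- list(
    ss = mk(e_ss, "ss", cfg$w_ss0, cfg$sigma_ss, cfg$w_max, sub(7L)),
    sg = mk(e_sg, "sg", cfg$w_sg, cfg$sigma_sg, sd_seed = sub(8L)),
    gs = mk(e_gs, "gs", cfg$w_gs, cfg$sigma_gs, sd_seed = sub(9L)),
    gg = mk(e_gg, "gg", cfg$w_gg, cfg$sigma_gg, sd_seed = sub(10L))
  )
  cell_params <- list(
    stn_ref = stn_params(), gpe_ref = gpe_params(),
    stn = heterogenize_params(stn_params(), cfg$n_stn, cfg$het_sd, seed = sub(11L)),
    gpe = heterogenize_params(gpe_params(), cfg$n_gpe, cfg$het_sd, seed = sub(12L))
  )
  structure(list(positions = list(stn = pos_stn, gpe = pos_gpe),
                 edges = edges, cell_params = cell_params,
                 electrode = electrode, config = cfg, seed = seed,
                 shapes = list(stn = stn_shape, gpe = gpe_shape)),
            class = "stngpe_network")
}

#' Export the network edge list as a single table
#'
#' @param network an `"stngpe_network"`.
#' @return A data.frame with columns `class`, `pre`, `post`, `weight`,
#'   `delay` (neuron ids are 1-based within each nucleus).
#' @export
edge_table <- function(network) {
  do.call(rbind, lapply(names(network$edges), function(nm) {
    e <- network$edges[[nm]]
    cbind(data.frame(class = nm, stringsAsFactors = FALSE), e)
  }))
}
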