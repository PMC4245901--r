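# Network engine contracts: determinism, causality of delayed delivery,
# kernel superposition, weight conservation and bounds, degenerate runs.

test_that("identical seeds give bit-identical runs", {
  net <- build_network(network_config(n_stn = 60, n_gpe = 60, w_ss0 = 5e-3), seed = 3)
  a <- run_network(net, 1500, engine_config(seed = 9), stdp = TRUE)
  b <- run_network(net, 1500, engine_config(seed = 9), stdp = TRUE)
  expect_identical(a$raster, b$raster)
  expect_identical(a$w_ss, b$w_ss)
  expect_identical(a$rec, b$rec)
  # a different noise seed produces a different raster
  c <- run_network(net, 1500, engine_config(seed = 10), stdp = TRUE)
  expect_false(identical(a$raster, c$raster))
})

test_that("zero-duration run yields empty outputs", {
  net <- build_network(network_config(n_stn = 10, n_gpe = 10), seed = 1)
  r <- run_network(net, 0, engine_config(seed = 1))
  expect_equal(nrow(r$raster), 0)
  expect_equal(nrow(r$rec), 0)
})

test_that("postsynaptic effect begins exactly one delay after the presynaptic spike", {
  netA <- tiny_two_neuron_net(w = 0.05)
  netB <- tiny_two_neuron_net(w = 0)
  cfg <- engine_config(seed = 4, record_dt = 0.1)
  a <- run_network(netA, 800, cfg, stdp = FALSE, noise = FALSE,
                   record_ids = c(1L, 2L))
  b <- run_network(netB, 800, cfg, stdp = FALSE, noise = FALSE,
                   record_ids = c(1L, 2L))
  t1 <- a$raster$time[a$raster$id == 1][1]
  expect_false(is.na(t1))
  v2a <- a$v_traces[, 2]; v2b <- b$v_traces[, 2]
  tt <- a$rec$t
  before <- tt <= t1 + 4.0
  after <- tt > t1 + 4.0 & tt < t1 + 12
  expect_equal(v2a[before], v2b[before], tolerance = 1e-10)
  expect_gt(max(abs(v2a[after] - v2b[after])), 1e-4)
})

test_that("alpha-kernel auxiliary-ODE propagation equals direct convolution", {
  set.seed(31)
  for (tau in c(1.0, 3.3)) {
    st <- sort(runif(40, 0, 60))
    st <- c(st, st[5])  # duplicated event: kernels superpose additively
    w <- runif(41, 0, 2e-3)
    tt <- seq(0, 80, by = 0.37)
    expect_lt(max(abs(alpha_kernel_ode(tt, st, w, tau) -
                      alpha_convolution(tt, st, w, tau))), 1e-8)
  }
})

test_that("weights are conserved without plasticity and bounded with it", {
  net <- build_network(network_config(n_stn = 80, n_gpe = 80, w_ss0 = 10e-3), seed = 6)
  frozen <- run_network(net, 2000, engine_config(seed = 2), stdp = FALSE)
  expect_identical(frozen$w_ss, net$edges$ss$weight)
  plastic <- run_network(net, 2000, engine_config(seed = 2), stdp = TRUE, lam_mult = 5)
  expect_true(all(plastic$w_ss >= 0 & plastic$w_ss <= net$config$w_max))
  expect_false(identical(plastic$w_ss, net$edges$ss$weight))
  expect_true(all(plastic$rec$mean_w_ss >= 0 &
                  plastic$rec$mean_w_ss <= net$config$w_max))
})

test_that("uncoupled identical neurons stay identical; zero-conductance cells hold their potential", {
  cfg0 <- network_config(n_stn = 5, n_gpe = 5, w_ss0 = 0, sigma_ss = 0,
                         w_gg = 0, sigma_gg = 0, w_sg = 0, sigma_sg = 0,
                         w_gs = 0, sigma_gs = 0, het_sd = 0)
  net <- build_network(cfg0, seed = 2)
  st <- steady_cell_state(stn_params(), -59)
  stg <- steady_cell_state(gpe_params(), -59)
  init <- rbind(matrix(rep(unclass(st), each = 5), nrow = 5),
                matrix(rep(unclass(stg), each = 5), nrow = 5))
  r <- run_network(net, 600, engine_config(seed = 1, record_dt = 1),
                   stdp = FALSE, noise = FALSE, record_ids = 1:10,
                   init_state = init)
  for (i in 2:5) expect_equal(r$v_traces[, i], r$v_traces[, 1], tolerance = 1e-12)
  for (i in 7:10) expect_equal(r$v_traces[, i], r$v_traces[, 6], tolerance = 1e-12)
  # all conductances zero and no input: membrane potential is frozen
  net0 <- net
  for (p in c("g_L", "g_K", "g_Na", "g_Ca", "g_ahp", "g_T")) {
    net0$cell_params$stn[[p]] <- rep(0, 5)
    net0$cell_params$gpe[[p]] <- rep(0, 5)
  }
  r0 <- run_network(net0, 300, engine_config(seed = 1), stdp = FALSE,
                    noise = FALSE, record_ids = c(1L, 6L), init_state = init)
  expect_equal(r0$v_traces[, 1], rep(-59, nrow(r0$rec)), tolerance = 1e-9)
  expect_equal(r0$v_traces[, 2], rep(-59, nrow(r0$rec)), tolerance = 1e-9)
})

test_that("per-neuron spike trains respect the detection resolution", {
  net <- build_network(network_config(n_stn = 50, n_gpe = 50, w_ss0 = 10e-3), seed = 8)
  r <- run_network(net, 3000, engine_config(seed = 5), stdp = FALSE)
  gaps <- unlist(lapply(split(r$raster$time, r$raster$id), function(x) diff(sort(x))))
  if (length(gaps)) expect_gte(min(gaps), 0.1)
  expect_true(all(r$raster$time >= 0 & r$raster$time <= 3000))
})
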