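# Single-cell membrane model: gating kinetics, ionic currents, state
# derivative, and agreement between the engine and the independent
# reference integration.

test_that("gating steady state is a correctly anchored sigmoid", {
  for (p in list(stn_params(), gpe_params())) {
    for (nm in setdiff(names(p$gating), "b")) {  # b is a function of r, below
      g <- p$gating[[nm]]
      expect_equal(gate_inf(g, g$theta), 0.5)
      hi <- gate_inf(g, 1e4); lo <- gate_inf(g, -1e4)
      if (g$sigma > 0) expect_true(lo < 1e-10 && hi > 1 - 1e-10)
      else expect_true(hi < 1e-10 && lo > 1 - 1e-10)
      v <- seq(-100, 40, by = 5)
      d <- diff(gate_inf(g, v))
      expect_true(all(if (g$sigma > 0) d >= 0 else d <= 0))  # ties only at saturation
      vm <- seq(g$theta - 15, g$theta + 15, by = 1)
      dm <- diff(gate_inf(g, vm))
      expect_true(all(if (g$sigma > 0) dm > 0 else dm < 0))
    }
  }
  # STN s-gate half-activation at its printed threshold
  expect_equal(gate_inf(stn_params()$gating$s, -39), 0.5)
})

test_that("gating time constant is bounded by its asymptotes", {
  h <- stn_params()$gating$h  # tau0 = 1, tau1 = 500, negative tau slope
  expect_equal(gate_tau(h, -1e4), 501, tolerance = 1e-10)
  expect_equal(gate_tau(h, 1e4), 1, tolerance = 1e-10)
  v <- seq(-120, 40, by = 1)
  expect_true(all(gate_tau(h, v) >= 1 & gate_tau(h, v) <= 501))
  # GPe r-gate: voltage-independent 30 ms
  expect_equal(gate_tau(gpe_params()$gating$r, c(-100, -50, 0)), rep(30, 3))
  # pathological all-zero spec collapses to zero
  z <- gating_spec(theta = 0, sigma = 1, tau0 = 0, tau1 = 0)
  expect_equal(gate_tau(z, c(-50, 0, 50)), rep(0, 3))
})

test_that("STN b-gate is offset to vanish at r = 0 and stays in [0,1]", {
  expect_equal(b_inf(0), 0)
  r <- seq(0, 1, by = 0.01)
  b <- b_inf(r)
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(diff(b) > 0))
})

test_that("ionic currents match their closed forms at anchor points", {
  p <- stn_params()
  st <- cell_state(v = p$v_K, n = 0.3, h = 0.5, r = 0.2, Ca = 0.4)
  cur <- ionic_currents(p, st)
  expect_equal(cur[["I_K"]], 0)    # zero driving force at v = v_K
  expect_equal(cur[["I_ahp"]], 0)
  st0 <- cell_state(v = -50, n = 0.3, h = 0.5, r = 0.2, Ca = 0)
  expect_equal(ionic_currents(p, st0)[["I_ahp"]], 0)   # no calcium, no AHP
  st1 <- cell_state(v = -50, n = 0.3, h = 0.5, r = 0.2, Ca = p$k1)
  expect_equal(ionic_currents(p, st1)[["I_ahp"]],
               p$g_ahp * (-50 - p$v_K) * 0.5)          # half-saturation
  # GPe low-threshold calcium current uses r directly
  g <- gpe_params()
  stg <- cell_state(v = -50, n = 0.3, h = 0.5, r = 0.7, Ca = 0.1)
  curg <- ionic_currents(g, stg)
  a3 <- gate_inf(g$gating$a, -50)^3
  expect_equal(curg[["I_T"]], g$g_T * a3 * 0.7 * (-50 - g$v_Ca))
  bad <- g; bad$cell_kind <- "XX"
  expect_error(ionic_currents(bad, stg), "cell_kind")
})

test_that("state derivative vanishes at a constructed fixed point and has the stated signs", {
  p <- stn_params()
  v <- -58
  st <- steady_cell_state(p, v)
  cur <- ionic_currents(p, st)
  # cancel the membrane current balance with a matching injection
  d <- cell_derivative(p, st, I_stim = sum(cur))
  expect_equal(unname(d[c("n", "h", "r", "Ca")]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(d[["v"]]), 0, tolerance = 1e-10)
  # positive stimulation current depolarizes
  d0 <- cell_derivative(p, st)
  d1 <- cell_derivative(p, st, I_stim = 5)
  expect_gt(d1[["v"]], d0[["v"]])
  # excitatory synaptic input (negative I_syn term at v < v_syn) depolarizes
  d2 <- cell_derivative(p, st, I_syn = synaptic_current(v, 1e-3, 0, 0.3679))
  expect_gt(d2[["v"]], d0[["v"]])
  expect_error(cell_derivative(p, st, I_syn = NaN))
})

test_that("gates relax exponentially to steady state under voltage clamp", {
  p <- gpe_params()
  g <- p$gating$n
  v <- -45
  x0 <- 0.9
  tau <- gate_tau(g, v); xinf <- gate_inf(g, v)
  # closed form x(t) = xinf + (x0 - xinf) exp(-phi t / tau)
  f <- function(t, y, parms) list(g$phi * (gate_inf(g, v) - y) / gate_tau(g, v))
  sol <- deSolve::lsoda(c(x = x0), seq(0, 20, by = 1), f, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(sol[, "x"],
               xinf + (x0 - xinf) * exp(-g$phi * sol[, "time"] / tau),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("reference integration keeps gating variables inside [0,1]", {
  for (p in list(stn_params(), gpe_params())) {
    ref <- single_neuron_reference(p, 1500, dt_out = 0.1)
    gates <- ref$trace[, c("n", "h", "r")]
    expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
    expect_true(all(ref$trace[, "Ca"] >= -1e-12))
  }
})

test_that("engine single-neuron trajectory matches the reference solver within 1% in spike period", {
  for (kind in c("STN", "GPe")) {
    p <- if (kind == "STN") stn_params() else gpe_params()
    ref <- single_neuron_reference(p, 3000)
    eng <- run_single_neuron(kind, 3000)
    st <- eng$raster$time[eng$raster$time > 300]
    expect_gt(length(st), 2)
    period_eng <- mean(diff(st))
    expect_lt(abs(period_eng - ref$period) / ref$period, 0.01)
  }
})

test_that("halving engine tolerances moves single-neuron spike times by less than 0.1 ms", {
  a <- run_single_neuron("GPe", 1000, config = engine_config(seed = 1))
  b <- run_single_neuron("GPe", 1000,
                         config = engine_config(abs_tol = 5e-7, rel_tol = 5e-7, seed = 1))
  k <- min(nrow(a$raster), nrow(b$raster))
  expect_gt(k, 5)
  expect_lt(max(abs(a$raster$time[1:k] - b$raster$time[1:k])), 0.1 + 1e-9)
})

test_that("heterogenized parameters have the configured spread and non-negative conductances", {
  het <- heterogenize_params(stn_params(), 5000, seed = 42)
  expect_equal(mean(het$g_K), 45, tolerance = 0.02)
  expect_equal(stats::sd(het$g_K) / 45, 0.05, tolerance = 0.05)
  expect_equal(stats::sd(het$v_K) / 80, 0.05, tolerance = 0.05)
  expect_true(all(het[c("g_L", "g_K", "g_Na", "g_Ca", "g_ahp", "g_T")] >= 0))
  # reproducible under the seed
  expect_identical(het, heterogenize_params(stn_params(), 5000, seed = 42))
})
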