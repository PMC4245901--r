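# Synchrony observables: spike detection, phases, order parameters,
# moving averages, voxelized local order, ISI statistics.

test_that("spike detection finds suprathreshold local maxima at the right times", {
  dt <- 0.05
  tt <- seq(0, 500, by = dt)
  v <- 30 * sin(2 * pi * tt / 50) - 20          # peaks at 12.5 + k*50, max +10
  sp <- detect_spikes(v, dt, threshold = -10)
  expect_equal(length(sp), 10)
  expect_equal(sp, 12.5 + 0:9 * 50, tolerance = 0.2)
  # entirely subthreshold trace yields nothing
  expect_equal(detect_spikes(v - 50, dt, threshold = -10), numeric(0))
  # two maxima 0.05 ms apart merge into the larger one
  v2 <- rep(-70, 200)
  v2[100] <- 10; v2[101] <- 12
  sp2 <- detect_spikes(v2, dt, threshold = -10, min_gap = 0.1)
  expect_equal(length(sp2), 1)
  expect_equal(sp2, 100 * dt)
})

test_that("order parameter is 1 for coherence, 0 for antiphase, 1/sqrt(n) baseline", {
  expect_equal(order_parameter(rep(1.3, 50)), 1)
  expect_equal(order_parameter(c(0, pi)), 0, tolerance = 1e-12)
  expect_true(is.na(order_parameter(numeric(0))))
  set.seed(8)
  n <- 10000
  R2 <- replicate(120, order_parameter(runif(n, 0, 2 * pi))^2)
  expect_equal(sqrt(mean(R2)), 1 / sqrt(n), tolerance = 0.1)
})

test_that("spike phase interpolates linearly between spikes", {
  st <- c(0, 100)
  expect_equal(spike_phase(st, 50), pi)
  expect_equal(spike_phase(st, 0), 0)
  expect_equal(spike_phase(st, 25), pi / 2)
  expect_true(is.na(spike_phase(st, 150)))   # after last spike
  expect_true(is.na(spike_phase(st, -1)))    # before first spike
  expect_true(all(is.na(spike_phase(50, c(10, 60)))))  # single spike
  tt <- seq(0, 99.9, by = 0.1)
  ph <- spike_phase(st, tt)
  expect_true(all(diff(ph) > 0))
  expect_lt(max(ph), 2 * pi)
})

test_that("moving average is exact on constants, impulses and window-period sinusoids", {
  x <- rep(3.7, 500)
  expect_equal(moving_average(x, window = 100, dt = 1), x)
  imp <- c(rep(0, 2000), 1, rep(0, 2000))
  sm <- moving_average(imp, window = 1000, dt = 1)
  expect_equal(max(sm), 1 / 1001)  # window is forced odd: 1001 samples
  expect_equal(sum(sm > 0), 1001)
  tt <- seq_len(5000)
  s <- sin(2 * pi * tt / 1001)
  expect_lt(max(abs(moving_average(s, 1000, 1)[1500:3500])), 1e-3)  # sinc null
})

test_that("voxel-local order separates voxel-wise from global coherence", {
  set.seed(12)
  n <- 400
  pos <- place_neurons(stn_ellipsoid(), n, seed = 12)
  # fully coherent population: every neuron spikes at the same times
  st <- seq(0, 2000, by = 100)
  raster <- data.frame(id = rep(1:n, each = length(st)),
                       time = rep(st, n))
  lo <- local_order(pos, raster, t_range = c(100, 1900))
  expect_equal(lo$r1_bar, 1, tolerance = 1e-9)
  expect_equal(lo$sigma_r1, 0, tolerance = 1e-9)
  expect_true(all(lo$voxels$n >= 10))
  # one voxel holding everything equals the global time-averaged R
  times <- seq(100, 1900, by = 1)
  lo1 <- local_order(pos, raster, t_range = c(100, 1900), voxel_edge = 50)
  expect_equal(lo1$n_voxels, 1)
  expect_equal(lo1$r1_bar,
               mean(order_parameter_trace(raster, times, 1:n), na.rm = TRUE),
               tolerance = 1e-9)
  # two spatial halves in antiphase: global R ~ 0 but voxel-local r1 ~ 1
  left <- which(pos[, 2] < 0); right <- which(pos[, 2] >= 0)
  r2 <- rbind(
    data.frame(id = rep(left, each = length(st)), time = rep(st, length(left))),
    data.frame(id = rep(right, each = length(st)), time = rep(st + 50, length(right))))
  ts2 <- seq(200, 1800, by = 1)
  Rg <- mean(order_parameter_trace(r2, ts2, 1:n), na.rm = TRUE)
  lo2 <- local_order(pos, r2, t_range = c(200, 1800), voxel_edge = 2.0)
  expect_lt(Rg, 0.25)
  expect_gt(lo2$r1_bar, 0.95)
  expect_error(local_order(pos, raster, t_range = c(100, 1900), voxel_edge = 0.1),
               "voxel")
})

test_that("ISI statistics report pooled median, MD and rate", {
  raster <- data.frame(id = rep(1:5, each = 21), time = rep(seq(0, 2000, by = 100), 5))
  s <- isi_stats(raster)
  expect_equal(s$median, 100)
  expect_equal(s$md, 0)
  expect_equal(s$rate_hz, 10)
  # hand-computed pooled set
  r2 <- data.frame(id = rep(1, 6), time = cumsum(c(0, 80, 90, 100, 110, 120)))
  s2 <- isi_stats(r2)
  expect_equal(s2$median, 100)
  expect_equal(s2$md, 12)
  expect_equal(1000 / s2$median, 10)
  # a 261.2 ms median interval is a 3.8 Hz median rate
  expect_equal(1000 / 261.2, 3.8, tolerance = 0.01)
  expect_error(isi_stats(data.frame(id = 1, time = 5)), "interval")
  # histogram binning at 5 ms
  expect_equal(s2$hist$mid[1], 2.5)
  expect_equal(sum(s2$hist$count), 5)
})
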