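# Biphasic pulses, line-charge field profile, randomized CR scheduling
# and the composed per-neuron stimulation current.

test_that("biphasic pulses are charge balanced and correctly shaped", {
  sp <- pulse_spec(kappa = -3.3)
  expect_equal(sp$omega * (1 + sp$p_s), 1.8)  # total pulse duration (ms)
  tt <- seq(0, 3, by = 1e-4)
  p <- pulse_waveform(tt, sp, onsets = 0.5)
  expect_equal(sum(p) * 1e-4, 0, tolerance = 1e-6)        # zero net charge
  expect_equal(max(abs(p)), abs(sp$kappa))
  expect_equal(pulse_waveform(c(0.1, 2.5), sp, onsets = 0.5), c(0, 0))
  expect_equal(pulse_waveform(0.55, sp, onsets = 0.5), sp$kappa)
  expect_equal(pulse_waveform(1.0, sp, onsets = 0.5), -sp$kappa / sp$p_s)
  expect_error(pulse_waveform(1, sp, onsets = c(0, 1)), "overlap")
  expect_error(pulse_spec(kappa = -1, omega = 2, p_s = 8, T_p = 7.69), "duration")
})

test_that("field profile matches the line-charge form and its asymptotics", {
  expect_equal(field_profile(0.7), 1 / (0.7 * 1.5 * sqrt(1 + 4 * (0.7 / 1.5)^2)))
  expect_equal(field_profile(0.7), 0.696, tolerance = 1e-3)
  expect_true(field_profile(0.7) > field_profile(1.4) &&
              field_profile(1.4) > field_profile(2.8))
  d <- seq(0.7, 20, by = 0.01)
  expect_true(all(diff(field_profile(d)) < 0))
  expect_equal(field_profile(10) / field_profile(20), 4, tolerance = 0.01)
  expect_error(field_profile(0.3), "d_min")
})

test_that("CR sequence partitions each ON cycle into one burst per contact", {
  sch <- cr_schedule(seed = 21)
  sq <- cr_sequence(sch, horizon = 10 * 625)
  # 4 complete pulses fit one 31.25 ms slot at T_p = 7.69 ms
  first <- sq[sq$cycle == 1 & sq$onset < 31.25, ]
  expect_equal(nrow(first), 4)
  expect_equal(diff(first$onset), rep(7.69, 3))
  expect_equal(length(unique(first$contact)), 1)
  # each ON cycle activates each contact exactly once (CR property)
  per_cycle <- split(sq, sq$cycle)
  for (cyc in per_cycle) {
    slots <- floor((cyc$onset %% 625) %% 125 / 31.25)
    expect_setequal(unique(cyc$contact), 1:4)
    expect_equal(length(unique(paste(cyc$contact, slots))), 4)
  }
  # OFF cycles are empty: nothing in [375, 625) of each pattern
  expect_true(all(sq$onset %% 625 < 375 - 1.8 + 31.25 * 0))
  expect_true(all((sq$onset %% 625) < 3 * 125))
  expect_identical(sq, cr_sequence(sch, horizon = 10 * 625))
})

test_that("randomization never repeats the closing contact as the next opener", {
  sch <- cr_schedule(seed = 33)
  sq <- cr_sequence(sch, horizon = 2000 * 125)  # hundreds of ON cycles
  per_cycle <- split(sq, sq$cycle)
  openers <- vapply(per_cycle, function(x) x$contact[which.min(x$onset)], 1L)
  closers <- vapply(per_cycle, function(x) x$contact[which.max(x$onset)], 1L)
  n <- length(openers)
  expect_gt(n, 100)
  expect_true(all(closers[-n] != openers[-1]))
  # permutations vary across cycles
  expect_gt(length(unique(vapply(per_cycle, function(x)
    paste(x$contact[order(x$onset)][c(1, 5, 9, 13)], collapse = ""), ""))), 4)
})

test_that("per-neuron stimulation current composes field, indicator and pulse", {
  el <- electrode_spec()
  sch <- cr_schedule(seed = 2)
  pu <- pulse_spec(kappa = -2)
  sq <- cr_sequence(sch, horizon = 625, pulse = pu)
  # OFF epoch: no current anywhere
  pos <- matrix(c(0, 0, 1, 0, 2, 1), ncol = 3, byrow = TRUE)
  expect_equal(stim_current(pos, 500, sq, pu, el), c(0, 0))
  # during the first cathodal phase, current scales with the field profile
  t1 <- sq$onset[1] + 0.1
  j <- sq$contact[1]
  cc <- contact_positions(el)[j, ]
  p1 <- matrix(cc + c(0.7, 0, 0), 1)
  p2 <- matrix(cc + c(2.1, 0, 0), 1)
  I1 <- stim_current(p1, t1, sq, pu, el)
  I2 <- stim_current(p2, t1, sq, pu, el)
  expect_equal(I1 / I2, field_profile(0.7) / field_profile(2.1))
  # two neurons equidistant from the active contact get identical input
  p3 <- matrix(cc + c(0, 0, 0.7), 1)
  expect_equal(stim_current(p3, t1, sq, pu, el), I1)
  # gain scales linearly
  expect_equal(stim_current(p1, t1, sq, pu, el, gain = 2.5), 2.5 * I1)
})

test_that("integrated engine stimulation keeps charge balance over whole pulses", {
  # waveform sampled at 10 us over one full ON cycle integrates to ~0
  sch <- cr_schedule(seed = 5)
  pu <- pulse_spec(kappa = -4)
  sq <- cr_sequence(sch, horizon = 125, pulse = pu)
  tt <- seq(0.005, 125, by = 0.01)  # midpoint sampling avoids phase edges
  el <- electrode_spec()
  p <- matrix(c(0.8, 0.4, 0.2), 1)
  I <- vapply(tt, function(t) stim_current(p, t, sq, pu, el), numeric(1))
  q_single <- abs(pu$kappa) * pu$omega * max(field_profile(distance_to_contact(p, el, 1)))
  expect_lt(abs(sum(I) * 0.01), 1e-10 * q_single + 1e-10)
})
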