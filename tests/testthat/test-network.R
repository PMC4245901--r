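# Connectivity builder: distance profile, out-degrees, block structure,
# weight statistics, reproducibility.

test_that("distance probability evaluates the exponential decay", {
  expect_equal(distance_probability(0, 0.5), 1)
  expect_equal(round(distance_probability(0.7, 0.63), 2), 0.33)  # GPe dendritic range
  expect_equal(distance_probability(0.543, 0.5), exp(-0.543 / 0.5))
  expect_lt(abs(distance_probability(0.543, 0.5) - 0.337), 1e-3)  # STN range, ~33%
  expect_error(distance_probability(0.5, 0))
})

test_that("intra-nucleus wiring has exact out-degree, no self-edges, distance bias", {
  set.seed(5)
  n <- 200
  pos <- place_neurons(stn_ellipsoid(), n, seed = 5)
  k <- 14  # 7% of 200
  e <- connect_intranucleus(pos, k, c_d = 0.5, seed = 9)
  expect_equal(nrow(e), n * k)
  expect_true(all(table(e[, "pre"]) == k))
  expect_true(all(e[, "pre"] != e[, "post"]))
  # no duplicated ordered pairs
  expect_false(any(duplicated(e)))
  expect_identical(e, connect_intranucleus(pos, k, c_d = 0.5, seed = 9))
  # distance bias: resampling oracle. base R sample() performs the same
  # successive weighted sampling without replacement; the edge-distance
  # distributions must agree.
  d_mat <- as.matrix(dist(pos))
  set.seed(77)
  d_oracle <- unlist(lapply(seq_len(n), function(i) {
    w <- exp(-d_mat[i, ] / 0.5); w[i] <- 0
    d_mat[i, sample.int(n, k, prob = w)]
  }))
  d_edges <- d_mat[cbind(e[, "pre"], e[, "post"])]
  expect_equal(mean(d_edges), mean(d_oracle), tolerance = 0.05)
  expect_equal(stats::quantile(d_edges, c(0.25, 0.5, 0.75)),
               stats::quantile(d_oracle, c(0.25, 0.5, 0.75)), tolerance = 0.08)
  # and much shorter than unbiased pairing
  expect_lt(mean(d_edges), 0.75 * mean(d_mat[d_mat > 0]))
  expect_error(connect_intranucleus(pos, n, c_d = 0.5), "out_degree")
})

test_that("inter-nucleus wiring is uniform with exact out-degree", {
  e <- connect_internucleus(150, 300, 6, seed = 2)
  expect_equal(nrow(e), 900)
  expect_true(all(table(e[, "pre"]) == 6))
  expect_true(all(e[, "post"] >= 1 & e[, "post"] <= 300))
  expect_false(any(duplicated(e)))
  expect_equal(nrow(connect_internucleus(10, 20, 0)), 0)
  # uniform targeting: chi-square on target counts
  e2 <- connect_internucleus(2000, 50, 10, seed = 3)
  cnt <- tabulate(e2[, "post"], 50)
  chi <- sum((cnt - 400)^2 / 400)
  expect_lt(chi, 49 + 4 * sqrt(2 * 49))  # ~4 sd above the chi^2_49 mean
})

test_that("initial weights are Gaussian with clipping", {
  expect_equal(draw_weights(5, 3e-3, 0), rep(3e-3, 5))
  w <- draw_weights(20000, 18e-3, 0.1e-3, w_max = 20e-3, seed = 1)
  expect_lt(abs(mean(w) - 18e-3), 3 * 0.1e-3 / sqrt(20000))
  expect_true(all(w >= 0 & w <= 20e-3))
  neg <- draw_weights(2000, 0.5, 10, seed = 2)
  expect_true(all(neg >= 0))
  expect_gt(mean(neg == 0), 0.2)  # mass below zero is clipped to zero
})

test_that("the built network respects the block structure and scales linearly", {
  cfg <- network_config(n_stn = 300, n_gpe = 200)
  net <- build_network(cfg, seed = 4)
  expect_equal(nrow(net$edges$ss), 300 * round(0.07 * 300))
  expect_equal(nrow(net$edges$gg), 200 * round(0.01 * 200))
  expect_equal(nrow(net$edges$sg), 300 * round(0.02 * 200))
  expect_equal(nrow(net$edges$gs), 200 * round(0.02 * 300))
  # typed edge audit: ids stay within their populations
  expect_true(all(net$edges$ss$pre <= 300 & net$edges$ss$post <= 300))
  expect_true(all(net$edges$gg$pre <= 200 & net$edges$gg$post <= 200))
  expect_true(all(net$edges$sg$pre <= 300 & net$edges$sg$post <= 200))
  expect_true(all(net$edges$gs$pre <= 200 & net$edges$gs$post <= 300))
  expect_true(all(net$edges$ss$pre != net$edges$ss$post))
  # bit-for-bit reproducibility under the master seed
  net2 <- build_network(cfg, seed = 4)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$positions, net2$positions)
  # doubling the population doubles per-class edge counts via fractions
  net3 <- build_network(network_config(n_stn = 600, n_gpe = 400), seed = 4)
  expect_equal(nrow(net3$edges$ss) / nrow(net$edges$ss), 4)  # n * (p n)
  expect_equal(nrow(net3$edges$sg) / nrow(net$edges$sg), 4)
})

test_that("synapse class table carries the stated constants", {
  cls <- synapse_classes()
  expect_equal(cls$v_syn[cls$name == "gg"], -80)
  expect_equal(cls$v_syn[cls$name == "gs"], -100)
  expect_equal(cls$tau_syn[cls$name == "gs"], 3.3)
  expect_equal(cls$tau_syn[cls$name == "ss"], 1.0)
  expect_equal(unique(cls$delay[cls$name != "noise"]), 4.0)
  expect_true(all(cls$plastic == (cls$name == "ss")))
  et <- edge_table(build_network(network_config(n_stn = 100, n_gpe = 100), seed = 1))
  expect_setequal(unique(et$class), c("ss", "sg", "gs", "gg"))
  expect_true(all(et$weight >= 0))
})
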