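test_that("the generator is deterministic for a fixed seed", {
  cfg <- simulation_config(n_sites = 250, seed = 99)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$truth, b$truth)
  c <- simulate_events(simulation_config(n_sites = 250, seed = 100))
  expect_false(identical(a$events$sf, c$events$sf))
})

test_that("with zero noise reference SF sits exactly on the generating line", {
  cfg <- simulation_config(
    n_sites = 500, sf_noise_scale = 0,
    order_proportions = c(1, 0, 0, 0),
    disturbance_mix = c(reference = 1, stress = 0, ambient = 0),
    seed = 101)
  sim <- simulate_events(cfg, compute_truth = FALSE)
  ev <- sim$events
  tr <- cfg$sf_quantile_truth
  line <- pmin(pmax(tr$intercept[1] + tr$slope[1] * ev$bankfull_width_m,
                    0.5), 99.5)
  expect_lt(max(abs(ev$sf - line)), 1e-9)
})

test_that("the generating line is the reference 75th percentile in expectation", {
  cfg <- simulation_config(
    n_sites = 4000,
    disturbance_mix = c(reference = 1, stress = 0, ambient = 0),
    seed = 102)
  sim <- simulate_events(cfg, compute_truth = FALSE)
  ev <- sim$events
  tr <- cfg$sf_quantile_truth
  for (od in 1:4) {
    sel <- ev$order == od
    line <- tr$intercept[od] + tr$slope[od] * ev$bankfull_width_m[sel]
    cover <- mean(ev$sf[sel] <= line)
    expect_lt(abs(cover - 0.75), 0.035)
  }
  # truth records the generating lines exactly, no re-estimation
  sim2 <- simulate_events(simulation_config(n_sites = 50, seed = 103))
  expect_identical(sim2$truth$sf_quantile,
                   simulation_config(n_sites = 50, seed = 103)$sf_quantile_truth)
})

test_that("stress events are drawn from an upward-shifted SF distribution", {
  sim <- sim_small(104, n = 4000)
  ev <- sim$events
  expect_gt(median(ev$sf[ev$disturbance == "stress"]),
            median(ev$sf[ev$disturbance == "reference"]))
})

test_that("a zero-slope taxon pool decouples FSBI from SF", {
  pool <- default_taxon_pool()
  pool$occ_slope <- 0
  cfg <- simulation_config(n_sites = 1000, taxon_pool = pool, seed = 105)
  sim <- simulate_events(cfg, compute_truth = FALSE)
  rho <- cor(sim$events$sf, sim$events$fsbi, method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("the FSBI response is wedge-shaped under the sensitive-dominated pool", {
  sim <- sim_small(106, n = 5000)
  ev <- sim$events
  v_low <- var(ev$fsbi[ev$sf < 10])
  v_high <- var(ev$fsbi[ev$sf > 60])
  expect_gt(v_low, v_high)
})

test_that("pebble counts reproduce event SF in expectation", {
  ev100 <- data.frame(event_id = "full", sf = 100)
  pc <- simulate_pebble_counts(ev100, 150, seed = 107)
  expect_equal(sum(pc$count[pc$size_class != "<2.5"]), 0)
  expect_equal(sum(pc$count), 450)
  expect_equal(length(unique(pc$transect_id)), 3)

  ev0 <- data.frame(event_id = "none", sf = 0)
  pc0 <- simulate_pebble_counts(ev0, 150, seed = 108)
  expect_equal(sum(pc0$count[pc0$size_class == "<2.5"]), 0)

  ev20 <- data.frame(event_id = sprintf("r%03d", 1:200), sf = 20)
  pc20 <- simulate_pebble_counts(ev20, 150, seed = 109)
  sf_hat <- compute_sf(pc20)$sf_percent
  expect_lt(abs(mean(sf_hat) - 20), 2)
})

test_that("order-stratified weights are extent over stratum sample size", {
  ev <- data.frame(order = rep(c(1, 2), each = 10))
  w <- simulate_weights(ev, "order_stratified",
                        order_extent = c(100, 300, 1, 1))
  expect_equal(w, rep(c(10, 30), each = 10))
  # weighted stratum shares recover extent shares among sampled strata
  shares <- as.numeric(tapply(w, ev$order, sum)) / sum(w)
  expect_equal(shares, c(100, 300) / 400)
  expect_equal(simulate_weights(ev, "equal"), rep(1, 20))
  expect_error(simulate_weights(ev[0, , drop = FALSE], "order_stratified"),
               "empty stratum")
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulation_config(class_proportions = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(simulation_config(disturbance_mix = c(0.5, 0.5, 0.1)),
               "summing to 1")
  pool <- default_taxon_pool(); pool$score[1] <- -2
  expect_error(simulation_config(taxon_pool = pool), ">= 0")
  pool <- default_taxon_pool(); pool$occ_slope[1] <- 0.05
  expect_error(simulation_config(taxon_pool = pool), "sensitive")
  expect_error(simulation_config(taxon_pool = default_taxon_pool()[0, ]),
               "non-empty")
})
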