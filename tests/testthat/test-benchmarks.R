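make_events <- function(sim) sim$events

test_that("benchmark derivation populates cells and records provenance", {
  sim <- sim_small(51, n = 2500)
  bset <- suppressWarnings(derive_benchmark_set(sim$events,
                                                subsample_seed = 51))
  expect_s3_class(bset, "benchmark_set")
  expect_equal(nrow(bset$sr), 12)
  expect_true(any(bset$sr$available))
  expect_equal(bset$meta$tau, 0.75)
  expect_equal(bset$meta$percentile_method, "type7")
  expect_match(bset$meta$dataset_hash, "^[0-9a-f]+$")
  # diagnostics identity: chi-square equals null minus residual deviance
  for (key in names(bset$sr_models)) {
    m <- bset$sr_models[[key]]
    row <- bset$sr[paste(bset$sr$site_class, bset$sr$order, sep = ".") == key, ]
    expect_equal(row$chi_square, m$null_deviance - m$residual_deviance)
  }
})

test_that("duplicated stream segments contribute one reference event each", {
  sim <- sim_small(52, n = 300)
  ev <- sim$events
  dup <- ev[1, ]
  dup$event_id <- "EV-DUP"
  dup$disturbance <- "reference"
  ev$disturbance[1] <- "reference"
  dup$comid <- ev$comid[1]
  ev2 <- rbind(ev, dup)
  bset <- suppressWarnings(derive_benchmark_set(ev2, subsample_seed = 9))
  expect_equal(bset$meta$n_events, nrow(ev2) - 1L)
  expect_error(suppressWarnings(derive_benchmark_set(ev2)),
               "subsample_seed")
})

test_that("an empty reference set yields unavailable cells without crashing", {
  sim <- sim_small(53, n = 300)
  ev <- sim$events
  ev$disturbance <- "ambient"
  w <- capture_warnings(bset <- derive_benchmark_set(ev, subsample_seed = 1))
  expect_true(any(grepl("unavailable", w)))
  expect_true(all(vapply(bset$quantile_models, is.null, logical(1))))
  expect_true(all(is.na(bset$fsbi_ref)))
  expect_false(any(bset$sr$available))
})

test_that("a cell with a single-label response is marked unavailable", {
  sim <- sim_small(54, n = 1200)
  ev <- sim$events
  # force every mountains order-1 event to be clearly better than reference
  sel <- ev$site_class == "mountains" & ev$order == 1
  ev$fsbi[sel] <- 400
  bset <- suppressWarnings(derive_benchmark_set(ev, subsample_seed = 2))
  row <- bset$sr[bset$sr$site_class == "mountains" & bset$sr$order == 1, ]
  expect_false(row$available)
  expect_match(row$note, "single-label")
})

test_that("benchmark sets survive a JSON round trip byte-identically", {
  sim <- sim_small(55, n = 1500)
  bset <- suppressWarnings(derive_benchmark_set(sim$events,
                                                subsample_seed = 3))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_benchmark_set(bset, f1)
  write_benchmark_set(bset, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_benchmark_set(f1)
  expect_equal(back$fsbi_ref, bset$fsbi_ref)
  for (od in as.character(1:4)) {
    if (is.null(bset$quantile_models[[od]])) next
    expect_equal(back$quantile_models[[od]]$intercept,
                 bset$quantile_models[[od]]$intercept)
    expect_equal(back$quantile_models[[od]]$slope,
                 bset$quantile_models[[od]]$slope)
  }
  expect_equal(back$sr$sr50, bset$sr$sr50)
  # reconstructed models predict identically
  for (key in names(back$sr_models))
    expect_equal(predict_probability(back$sr_models[[key]], 30),
                 predict_probability(bset$sr_models[[key]], 30))
})

test_that("exported coefficient tables carry one row per order and cell", {
  bset <- idaho_benchmark_set()
  t3 <- export_sf_ref_table(bset)
  expect_equal(t3$order, 1:4)
  expect_match(t3$equation[1], "-3.22255")
  t4 <- export_sr_table(bset)
  expect_equal(nrow(t4), 12)
  expect_true(all(c("sr50", "sr75", "odds_ratio_ci") %in% names(t4)))
})
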