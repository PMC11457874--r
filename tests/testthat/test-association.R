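test_that("condition flags use achievement at equality, exceedance strictly", {
  bset <- idaho_benchmark_set()
  sf_ref_5m <- predict_sf_ref(bset$quantile_models[["1"]], 5)  # 31.61798
  ev <- data.frame(
    event_id = c("at_ref", "above", "bio_at_ref", "both_poor"),
    site_class = "mountains", order = 1, bankfull_width_m = 5,
    sf = c(sf_ref_5m, sf_ref_5m + 0.001, 10, 60),
    fsbi = c(200, 200, 140, 100))
  fl <- condition_flags(ev, bset, bio_indicator = "fsbi")
  expect_equal(fl$sf_status, c("good", "poor", "good", "poor"))
  expect_equal(fl$bio_status, c("good", "good", "good", "poor"))
})

test_that("alternative indicators use supplied benchmarks", {
  bset <- idaho_benchmark_set()
  ev <- data.frame(event_id = c("a", "b"), site_class = "foothills",
                   order = 2, bankfull_width_m = 4, sf = c(10, 10),
                   smi2 = c(60, 40))
  fl <- condition_flags(ev, bset, bio_indicator = "smi2",
                        bio_benchmark = 52)
  expect_equal(fl$bio_status, c("good", "poor"))
  expect_error(condition_flags(ev, bset, bio_indicator = "smi2"),
               "bio_benchmark")
  percls <- condition_flags(ev, bset, bio_indicator = "smi2",
                            bio_benchmark = c(mountains = 54,
                                              foothills = 52, ppbv = 52))
  expect_equal(percls$bio_status, c("good", "poor"))
})

test_that("relative risk matches the enumeration oracle on a known table", {
  fl <- flags_from_cells(30, 10, 20, 40)
  rr <- relative_risk(fl)
  expect_equal(rr$rr, 2.25, tolerance = 1e-12)
  expect_equal(rr$rr, oracle_rr(30, 10, 20, 40), tolerance = 1e-12)
  expect_equal(unname(rr$cells),c(30, 10, 20, 40))
})

test_that("equal conditional probabilities give RR = 1", {
  fl <- flags_from_cells(10, 30, 5, 15)
  expect_equal(relative_risk(fl)$rr, 1)
})

test_that("RR and its interval are invariant to weight rescaling", {
  set.seed(61)
  fl <- flags_from_cells(17, 23, 11, 49)
  fl$weight <- runif(nrow(fl), 0.5, 4)
  rr1 <- relative_risk(fl)
  fl$weight <- fl$weight * 7.3
  rr2 <- relative_risk(fl)
  expect_equal(rr1$rr, rr2$rr, tolerance = 1e-12)
  expect_equal(rr1$ci, rr2$ci, tolerance = 1e-12)
  expect_lte(rr1$ci[["low"]], rr1$rr)
  expect_gte(rr1$ci[["high"]], rr1$rr)
})

test_that("unweighted RR equals weighted RR with equal weights", {
  fl <- flags_from_cells(8, 12, 6, 24)
  rr1 <- relative_risk(fl)
  fl$weight <- rep(2.5, nrow(fl))
  expect_equal(relative_risk(fl)$rr, rr1$rr)
})

test_that("undefined relative-risk configurations error", {
  expect_error(relative_risk(flags_from_cells(3, 2, 0, 10)),
               "zero denominator")
  expect_error(relative_risk(flags_from_cells(0, 0, 3, 7)),
               "non-empty")
  bad <- flags_from_cells(3, 2, 2, 3); bad$weight <- c(0, rep(1, 9))
  expect_error(relative_risk(bad), "positive")
})

test_that("false-positive rates match direct enumeration on a crafted set", {
  bset <- idaho_benchmark_set()
  ref <- predict_sf_ref(bset$quantile_models[["1"]], 5)
  # 10 mountains order-1 reference events: 3 SF failures, 2 FSBI failures,
  # 1 overlap
  ev <- data.frame(
    event_id = sprintf("r%02d", 1:10),
    site_class = "mountains", order = 1, bankfull_width_m = 5,
    sf = c(ref + 5, ref + 8, ref + 2, rep(ref - 10, 7)),
    fsbi = c(100, 200, 200, 120, rep(200, 6)),
    disturbance = "reference")
  fp <- false_positive_rates(ev, bset)
  expect_equal(fp$fp_sf, 30)
  expect_equal(fp$fp_fsbi, 20)
  expect_equal(fp$fp_framework, 10)
  expect_equal(fp$n, 10)
})

test_that("all reference events achieving both benchmarks give zero rates", {
  bset <- idaho_benchmark_set()
  ev <- data.frame(event_id = as.character(1:12), site_class = "foothills",
                   order = 2, bankfull_width_m = 3, sf = 5, fsbi = 300,
                   disturbance = "reference")
  fp <- false_positive_rates(ev, bset)
  expect_equal(c(fp$fp_sf, fp$fp_fsbi, fp$fp_framework), c(0, 0, 0))
})
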