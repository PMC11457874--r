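demo_tab <- data.frame(taxon = c("A", "B", "C"), score = c(10, 5, 0))

test_that("FSBI is the occurrence-only sum of taxon scores", {
  expect_equal(score_sample(character(), demo_tab), 0)
  expect_equal(score_sample(c("A", "B"), demo_tab), 15)
  expect_equal(score_sample(c("A", "A", "B"), demo_tab), 15)  # duplicates collapse
  expect_equal(score_sample(c("a ", "  B"), demo_tab), 15)    # normalization
  expect_equal(score_sample(c("A", "B", "C"), demo_tab), 15)  # zero scores allowed
})

test_that("unknown taxa follow the on_missing policy", {
  expect_equal(score_sample(c("A", "Zzz"), demo_tab), 10)
  expect_warning(score_sample(c("A", "Zzz"), demo_tab, on_missing = "warn"),
                 "not in score table")
  expect_error(score_sample(c("A", "Zzz"), demo_tab, on_missing = "error"),
               "zzz")
})

test_that("score tables are validated", {
  expect_error(as_score_table(data.frame(taxon = "A", score = -1)), ">= 0")
  expect_error(as_score_table(data.frame(taxon = c("A", "a "),
                                         score = c(1, 2))), "duplicate")
  expect_error(as_score_table(data.frame(taxon = character(),
                                         score = numeric())), "empty")
})

test_that("FSBI is additive over disjoint taxon sets and monotone", {
  tab <- fsbi_demo_scores()
  set.seed(21)
  for (i in 1:10) {
    pick <- sample(nrow(tab), 14)
    s1 <- tab$taxon[pick[1:7]]; s2 <- tab$taxon[pick[8:14]]
    expect_equal(score_sample(c(s1, s2), tab),
                 score_sample(s1, tab) + score_sample(s2, tab))
  }
  base <- tab$taxon[1:5]
  extra <- tab$taxon[tab$score > 0][10]
  expect_gte(score_sample(c(base, extra), tab), score_sample(base, tab))
})

test_that("score_events matches per-sample scoring", {
  occ <- data.frame(event_id = c("e1", "e1", "e2"),
                    taxon = c("A", "B", "B"))
  res <- score_events(occ, demo_tab)
  expect_equal(res$fsbi[res$event_id == "e1"], 15)
  expect_equal(res$fsbi[res$event_id == "e2"], 5)
  expect_equal(res$n_taxa, c(2L, 1L))
})

test_that("taxon tolerance is the type-7 75th percentile of SF at occurrence", {
  ev <- data.frame(event_id = as.character(1:7),
                   sf = c(10, 10, 10, 0, 10, 20, 30))
  occ <- rbind(
    data.frame(event_id = c("1", "2", "3"), taxon = "Constant"),
    data.frame(event_id = c("4", "5", "6", "7"), taxon = "Spread"))
  res <- suppressWarnings(derive_taxon_tolerance(ev, occ, min_events = 3))
  expect_equal(res$sf_p75[res$taxon == "constant"], 10)
  expect_equal(res$sf_p75[res$taxon == "spread"], 22.5)  # type-7 interpolation

  single <- derive_taxon_tolerance(ev[1, ],
                                   data.frame(event_id = "1", taxon = "Solo"),
                                   min_events = 1)
  expect_equal(single$sf_p75, 10)

  expect_warning(
    out <- derive_taxon_tolerance(ev, occ, min_events = 5), "omitted")
  expect_false("constant" %in% out$taxon)
})

test_that("simulated FSBI values stay in the plausible 0-350 band", {
  sim <- sim_small(301, n = 800)
  expect_true(all(sim$events$fsbi >= 0))
  expect_true(all(sim$events$fsbi <= 350))
  # rescoring the emitted occurrences with the demo table reproduces the
  # generator's FSBI column
  rescored <- score_events(sim$occurrences, fsbi_demo_scores())
  m <- match(sim$events$event_id, rescored$event_id)
  fsbi <- ifelse(is.na(m), 0, rescored$fsbi[m])
  expect_equal(fsbi, sim$events$fsbi)
})
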